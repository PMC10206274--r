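#' Combine two haplotype populations with the same genome
#' @param a,b `hap_pop` objects over identical loci.
#' @return a `hap_pop` holding both sets of animals.
#' @export
hap_bind <- function(a, b) {
  stopifnot(length(a$haplo) == length(b$haplo))
  out <- a
  out$haplo <- lapply(seq_along(a$haplo),
                      function(chr) rbind(a$haplo[[chr]], b$haplo[[chr]]))
  out$ids <- c(a$ids, b$ids)
  out
}

#' Subset a haplotype population by animal id
#' @param pop a `hap_pop`.
#' @param ids animal ids to keep (order preserved).
#' @export
hap_subset <- function(pop, ids) {
  rows <- match(ids, pop$ids)
  if (anyNA(rows)) stopf("unknown animal id(s) in hap_subset")
  hrows <- as.vector(rbind(2L * rows - 1L, 2L * rows))
  out <- pop
  out$haplo <- lapply(pop$haplo, function(h) h[hrows, , drop = FALSE])
  out$ids <- ids
  out
}

#' Single meiosis
#'
#' Produces one gamete from a parent. Crossover counts per chromosome are
#' Poisson with mean equal to the chromosome genetic length in Morgans
#' (about 30/39 M at full scale), positions uniform on the genetic map, no
#' interference and no mutation.
#'
#' @param pop `hap_pop` holding the parent.
#' @param parent_id the parent's animal id.
#' @param seed integer seed.
#' @return list of per-chromosome integer allele vectors.
#' @export
meiosis <- function(pop, parent_id, seed = 1L) {
  row <- match(parent_id, pop$ids)
  if (is.na(row)) stopf("unknown parent id %s", parent_id)
  set.seed(seed)
  lapply(seq_along(pop$haplo), function(chr) {
    H <- pop$haplo[[chr]][c(2L * row - 1L, 2L * row), , drop = FALSE]
    drop(meiosis_batch_cpp(H, pop$positions_M[[chr]],
                           pop$map$chr_length_M, 0L))
  })
}

#' Create offspring for a set of matings
#'
#' Each mating (one dam, her allocated sire) produces a fixed family of
#' offspring by independent meioses: by default 9 females and 4 males, the
#' family structure that yields 9,720 female and 4,320 male selection
#' candidates (14,040 in total) from 1,080 dams per cycle at full scale.
#'
#' @param pop `hap_pop` containing all sires and dams.
#' @param matings data.frame with columns `sire`, `dam` (animal ids); one
#'   row per dam.
#' @param n_female,n_male offspring per mating by sex.
#' @param birth_time birth time stamped into the pedigree rows.
#' @param start_id first id for the new animals (consecutive after that).
#' @param seed integer seed.
#' @return list with `pop` (offspring `hap_pop`) and `pedigree`
#'   (data.frame id, sire, dam, sex, birth).
#' @export
make_offspring <- function(pop, matings, n_female = 9L, n_male = 4L,
                           birth_time = 0, start_id = 1L, seed = 1L) {
  stopifnot(is.data.frame(matings), all(c("sire", "dam") %in% names(matings)))
  n_per <- n_female + n_male
  n_off <- nrow(matings) * n_per
  if (n_off == 0L) {
    return(list(pop = NULL,
                pedigree = data.frame(id = integer(), sire = integer(),
                                      dam = integer(), sex = character(),
                                      birth = numeric())))
  }
  sire_rows <- match(matings$sire, pop$ids)
  dam_rows <- match(matings$dam, pop$ids)
  if (anyNA(sire_rows) || anyNA(dam_rows)) stopf("unknown parent id in matings")
  off_sire_row <- rep(sire_rows, each = n_per)
  off_dam_row <- rep(dam_rows, each = n_per)
  set.seed(derive_seed(seed, "meiosis", round(birth_time * 2)))
  haplo <- vector("list", length(pop$haplo))
  for (chr in seq_along(pop$haplo)) {
    gp <- pop$positions_M[[chr]]
    gs <- meiosis_batch_cpp(pop$haplo[[chr]], gp, pop$map$chr_length_M,
                            off_sire_row - 1L)
    gd <- meiosis_batch_cpp(pop$haplo[[chr]], gp, pop$map$chr_length_M,
                            off_dam_row - 1L)
    h <- matrix(0L, 2L * n_off, ncol(pop$haplo[[chr]]))
    h[seq(1L, 2L * n_off, by = 2L), ] <- gs
    h[seq(2L, 2L * n_off, by = 2L), ] <- gd
    haplo[[chr]] <- h
  }
  ids <- seq.int(start_id, length.out = n_off)
  off <- structure(list(haplo = haplo, positions_bp = pop$positions_bp,
                        positions_M = pop$positions_M, ids = ids,
                        map = pop$map), class = "hap_pop")
  sex <- rep(c(rep("F", n_female), rep("M", n_male)), nrow(matings))
  ped <- data.frame(id = ids,
                    sire = rep(matings$sire, each = n_per),
                    dam = rep(matings$dam, each = n_per),
                    sex = sex, birth = birth_time)
  list(pop = off, pedigree = ped)
}

#' Empty pedigree table
#' @export
new_pedigree <- function() {
  data.frame(id = integer(), sire = integer(), dam = integer(),
             sex = character(), birth = numeric())
}

#' Founder pedigree rows (unknown parents, coded 0)
#' @param ids founder animal ids.
#' @param sex sexes ("M"/"F").
#' @param birth birth time (default 0).
#' @export
founder_pedigree <- function(ids, sex, birth = 0) {
  data.frame(id = ids, sire = 0L, dam = 0L, sex = sex, birth = birth)
}
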