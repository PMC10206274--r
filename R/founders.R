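#' Simulate coalescent sites for a sample of haplotypes
#'
#' Low-level wrapper around the single-site Kingman coalescent with a
#' piecewise-constant effective size. Sites are mutually independent (free
#' recombination between retained sites).
#'
#' @param n_hap number of sampled haplotypes (>= 2).
#' @param n_sites number of sites (columns).
#' @param demog a [demography()] object.
#' @param conditional if `TRUE` each site carries exactly one mutation placed
#'   proportionally to branch length, so every column is segregating. If
#'   `FALSE`, a site mutates with probability `1 - exp(-mu * tree length)`
#'   and monomorphic columns are kept (used for neutral-diversity checks,
#'   where the expected pairwise diversity per site is `4 * Ne * mu`).
#' @param mu per-site per-generation mutation rate (only used when
#'   `conditional = FALSE`).
#' @param seed integer seed.
#' @return integer matrix `n_hap x n_sites` of 0/1 alleles (1 = derived /
#'   alternative allele).
#' @export
coalescent_sites <- function(n_hap, n_sites, demog, conditional = TRUE,
                             mu = 0, seed = 1L) {
  stopifnot(inherits(demog, "demography"), n_hap >= 2, n_sites >= 1)
  set.seed(seed)
  coalescent_sites_cpp(as.integer(n_hap), as.integer(n_sites),
                       demog$epoch_start, demog$epoch_Ne, conditional, mu)
}

#' Simulate base-population haplotypes
#'
#' Generates phased bi-allelic haplotypes for `n_individuals` founders under
#' the stated demography, retaining `sites_per_chr` segregating sites per
#' chromosome (2,250 at full scale, 87,750 genome-wide). Physical positions
#' are drawn uniformly per chromosome and genetic positions follow from the
#' constant recombination rate.
#'
#' @param map a [genome_map()].
#' @param demog a [demography()].
#' @param n_individuals number of diploid founders (>= 2).
#' @param sites_per_chr retained segregating sites per chromosome.
#' @param seed integer seed; the same seed yields byte-identical haplotypes.
#' @return an object of class `hap_pop`: list with `haplo` (per-chromosome
#'   integer matrices of two rows per animal), `positions_bp`,
#'   `positions_M`, `ids`, and `map`.
#' @export
simulate_founders <- function(map, demog, n_individuals, sites_per_chr = 2250L,
                              seed = 1L) {
  stopifnot(inherits(map, "genome_map"), n_individuals >= 2)
  n_hap <- 2L * as.integer(n_individuals)
  haplo <- vector("list", map$n_chromosomes)
  pos_bp <- vector("list", map$n_chromosomes)
  for (chr in seq_len(map$n_chromosomes)) {
    g <- coalescent_sites(n_hap, sites_per_chr, demog, conditional = TRUE,
                          seed = derive_seed(seed, "founders", chr))
    ac <- colSums(g)
    seg <- ac > 0L & ac < n_hap
    if (!all(seg)) {
      stopf("chromosome %d: only %d of %d retained sites are segregating",
            chr, sum(seg), sites_per_chr)
    }
    set.seed(derive_seed(seed, "positions", chr))
    p <- sort(sample.int(as.integer(map$chr_length_bp) - 1L, sites_per_chr))
    haplo[[chr]] <- g
    pos_bp[[chr]] <- p
  }
  structure(list(
    haplo = haplo,
    positions_bp = pos_bp,
    positions_M = lapply(pos_bp, function(p) p * map$recombination_rate),
    ids = seq_len(n_individuals),
    map = map
  ), class = "hap_pop")
}

#' @export
print.hap_pop <- function(x, ...) {
  cat(sprintf("<hap_pop> %d animals, %d chromosomes, %s loci\n",
              length(x$ids), length(x$haplo),
              format(sum(vapply(x$haplo, ncol, 1L)), big.mark = ",")))
  invisible(x)
}

n_loci_per_chr <- function(pop) vapply(pop$haplo, ncol, integer(1))

#' Partition retained loci into QTL, SNP and neutral sets
#'
#' Draws disjoint uniform-random index sets per chromosome: at full scale
#' 250 QTL + 1,000 SNP markers + 1,000 neutral monitoring loci out of the
#' 2,250 retained sites (9,750 / 39,000 / 39,000 genome-wide). No overlap
#' between the three classes.
#'
#' @param pop a `hap_pop`.
#' @param counts_per_chr integer vector `c(n_qtl, n_snp, n_neutral)`.
#' @param seed integer seed.
#' @return object of class `loci_partition`: per-chromosome sorted index
#'   vectors `qtl`, `snp`, `neutral`.
#' @export
partition_loci <- function(pop, counts_per_chr = c(250L, 1000L, 1000L),
                           seed = 1L) {
  stopifnot(inherits(pop, "hap_pop"), length(counts_per_chr) == 3)
  counts_per_chr <- as.integer(counts_per_chr)
  nl <- n_loci_per_chr(pop)
  if (any(sum(counts_per_chr) > nl)) {
    stopf("requested %d loci per chromosome but only %d retained sites",
          sum(counts_per_chr), min(nl))
  }
  qtl <- snp <- neutral <- vector("list", length(nl))
  for (chr in seq_along(nl)) {
    set.seed(derive_seed(seed, "partition", chr))
    idx <- sample.int(nl[chr], sum(counts_per_chr))
    qtl[[chr]] <- sort(idx[seq_len(counts_per_chr[1])])
    snp[[chr]] <- sort(idx[counts_per_chr[1] + seq_len(counts_per_chr[2])])
    neutral[[chr]] <- sort(idx[counts_per_chr[1] + counts_per_chr[2] +
                                 seq_len(counts_per_chr[3])])
  }
  structure(list(qtl = qtl, snp = snp, neutral = neutral,
                 counts_per_chr = counts_per_chr),
            class = "loci_partition")
}

#' Allele frequencies (of the alternative allele) at selected loci
#'
#' @param pop a `hap_pop`.
#' @param idx_list per-chromosome locus indices (e.g. `partition$qtl`), or
#'   `NULL` for all loci.
#' @return numeric vector of frequencies, chromosome-major order.
#' @export
allele_freqs <- function(pop, idx_list = NULL) {
  unlist(lapply(seq_along(pop$haplo), function(chr) {
    h <- pop$haplo[[chr]]
    if (!is.null(idx_list)) h <- h[, idx_list[[chr]], drop = FALSE]
    colMeans(h)
  }), use.names = FALSE)
}

#' Genotype dosages (0/1/2) at selected loci
#'
#' @inheritParams allele_freqs
#' @param ids animal ids to extract (default all).
#' @return integer matrix animals x loci with rownames set to ids.
#' @export
dosages <- function(pop, idx_list = NULL, ids = NULL) {
  rows <- if (is.null(ids)) seq_along(pop$ids) else match(ids, pop$ids)
  if (anyNA(rows)) stopf("unknown animal id(s) requested")
  out <- do.call(cbind, lapply(seq_along(pop$haplo), function(chr) {
    h <- pop$haplo[[chr]]
    if (!is.null(idx_list)) h <- h[, idx_list[[chr]], drop = FALSE]
    h[2L * rows - 1L, , drop = FALSE] + h[2L * rows, , drop = FALSE]
  }))
  rownames(out) <- if (is.null(ids)) pop$ids[rows] else ids
  out
}

#' Observed heterozygosity at selected loci
#'
#' Mean over animals of the per-animal fraction of heterozygous loci.
#' @inheritParams dosages
#' @export
observed_heterozygosity <- function(pop, idx_list = NULL, ids = NULL) {
  d <- dosages(pop, idx_list, ids)
  mean(d == 1L)
}
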