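#' Base variance components for the three egg-production traits
#'
#' Three purely additive traits (early, mid, late egg production) with base
#' heritabilities 0.18 / 0.22 / 0.25 and genetic correlations 0.75 (T1-T2),
#' 0.70 (T2-T3) and 0.60 (T1-T3), at base phenotypic variance 1 per trait.
#' Residual covariances are exactly zero (diagonal residual structure); all
#' cross-trait signal is genetic.
#'
#' @param h2 length-3 vector of heritabilities.
#' @param rg genetic correlations `c(r12, r23, r13)`.
#' @return list with `genetic_cov` (3x3), `residual_cov` (diagonal 3x3),
#'   `h2`, and the default index weights.
#' @export
trait_params <- function(h2 = c(0.18, 0.22, 0.25),
                         rg = c(0.75, 0.70, 0.60)) {
  stopifnot(length(h2) == 3, all(h2 > 0 & h2 < 1), length(rg) == 3)
  sa <- sqrt(h2)
  G <- diag(h2)
  G[1, 2] <- G[2, 1] <- rg[1] * sa[1] * sa[2]
  G[2, 3] <- G[3, 2] <- rg[2] * sa[2] * sa[3]
  G[1, 3] <- G[3, 1] <- rg[3] * sa[1] * sa[3]
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stopf("genetic covariance implied by h2/rg is not positive definite")
  }
  list(genetic_cov = G, residual_cov = diag(1 - h2), h2 = h2,
       index_weights = c(0.20, 0.35, 0.45))
}

#' Sample QTL effects and rescale to a target founder genic covariance
#'
#' Per-QTL effects for the three traits are drawn multivariate normal and
#' then linearly transformed so that the founder-population genic covariance
#' `2 * sum_j p_j (1 - p_j) alpha_j alpha_j'` equals `target_cov` exactly.
#'
#' @param partition a [partition_loci()] result.
#' @param pop founder `hap_pop` (supplies the QTL allele frequencies).
#' @param target_cov 3x3 target genetic covariance (or all-zero for null
#'   traits).
#' @param seed integer seed.
#' @return object of class `trait_arch`: `effects` (n_qtl x 3, chromosome-
#'   major QTL order), `genetic_cov`, `residual_cov`, `index_weights`,
#'   `qtl_freq` (founder frequencies).
#' @export
sample_effects <- function(partition, pop, target_cov = NULL, seed = 1L) {
  tp <- trait_params()
  if (is.null(target_cov)) target_cov <- tp$genetic_cov
  p <- allele_freqs(pop, partition$qtl)
  nq <- length(p)
  if (all(target_cov == 0)) {
    eff <- matrix(0, nq, 3)
  } else {
    if (any(p == 0 | p == 1)) {
      stopf("%d monomorphic QTL: cannot scale effects", sum(p == 0 | p == 1))
    }
    if (nq < 3) stopf("need at least 3 QTL to match a 3x3 covariance")
    set.seed(derive_seed(seed, "effects"))
    raw <- matrix(rnorm(nq * 3), nq, 3)
    w <- 2 * p * (1 - p)
    M <- crossprod(raw, raw * w)       # 2 sum p(1-p) a a'
    B <- backsolve(chol(M), chol(target_cov), transpose = FALSE)
    # chol(M) is upper-triangular U with M = U'U; B = U^{-1} chol(target)
    eff <- raw %*% B
  }
  structure(list(effects = eff, genetic_cov = target_cov,
                 residual_cov = tp$residual_cov,
                 index_weights = tp$index_weights, qtl_freq = p),
            class = "trait_arch")
}

#' True breeding values from QTL dosages
#'
#' `tbv_t(animal) = sum_j dosage_j(animal) * alpha_{j,t}`; purely additive,
#' dosage coded 0/1/2 for the alternative allele.
#'
#' @param pop a `hap_pop`.
#' @param partition loci partition providing the QTL indices.
#' @param arch a `trait_arch`.
#' @param ids animals to score (default all).
#' @return numeric matrix animals x 3 traits, rownames = ids.
#' @export
true_genetic_values <- function(pop, partition, arch, ids = NULL) {
  d <- dosages(pop, partition$qtl, ids)
  out <- d %*% arch$effects
  colnames(out) <- c("T1", "T2", "T3")
  out
}

#' Genic variance under linkage equilibrium
#'
#' `2 * sum_j p_j (1 - p_j) alpha_j^2` per trait; for a selection index the
#' per-locus effect is the weighted sum of trait effects. Fixed loci
#' contribute zero and the value is invariant to swapping allele labels
#' (p -> 1 - p with alpha -> -alpha).
#'
#' @param freqs per-QTL alternative-allele frequencies.
#' @param effects n_qtl x n_traits matrix (or vector for one trait).
#' @param index_weights optional weight vector; when given, a single genic
#'   variance for the weighted index is returned in addition to the
#'   per-trait values.
#' @return named numeric vector of genic variances (per trait, plus
#'   `index` when weights are supplied).
#' @export
genic_variance <- function(freqs, effects, index_weights = NULL) {
  effects <- as.matrix(effects)
  stopifnot(length(freqs) == nrow(effects), all(freqs >= 0 & freqs <= 1))
  w <- 2 * freqs * (1 - freqs)
  out <- colSums(w * effects^2)
  names(out) <- if (is.null(colnames(effects)))
    paste0("T", seq_len(ncol(effects))) else colnames(effects)
  if (!is.null(index_weights)) {
    a <- drop(effects %*% index_weights)
    out <- c(out, index = sum(w * a^2))
  }
  out
}

#' Simulate phenotypes with the recording schedule
#'
#' Adds independent per-trait residuals (diagonal residual covariance) to the
#' true values and stamps each record with the time from which it enters the
#' evaluations. Only females are phenotyped: early (T1) and mid (T2) egg
#' production are recorded before selection age, so they are available when
#' a female is a selection candidate; late production (T3) is recorded at
#' about 100 weeks and only for selected dams, entering the data
#' `t3_lag` years after selection.
#'
#' @param tbv matrix animals x 3 of true values (rownames = ids).
#' @param arch `trait_arch` (for residual variances).
#' @param sex character vector "M"/"F" per animal.
#' @param birth_time numeric vector of birth times (years).
#' @param candidate_time time at which the animals are selection candidates
#'   (T1/T2 available from then, females only).
#' @param seed integer seed.
#' @return data.frame `animal, trait, value, available_from` (T1/T2 records
#'   for females; T3 is drawn later via [record_t3()]).
#' @export
simulate_phenotypes <- function(tbv, arch, sex, birth_time, candidate_time,
                                seed = 1L) {
  f <- which(sex == "F")
  if (!length(f)) {
    return(data.frame(animal = integer(), trait = integer(),
                      value = numeric(), available_from = numeric()))
  }
  set.seed(derive_seed(seed, "pheno"))
  se <- sqrt(diag(arch$residual_cov))
  ids <- as.integer(rownames(tbv))
  recs <- lapply(1:2, function(t) {
    data.frame(animal = ids[f], trait = t,
               value = tbv[f, t] + rnorm(length(f), 0, se[t]),
               available_from = rep(candidate_time, length(f)))
  })
  do.call(rbind, recs)
}

#' Record late egg production for selected dams
#'
#' @param tbv true-value matrix for the selected dams (rownames = ids).
#' @param arch `trait_arch`.
#' @param selection_time time the dams were selected.
#' @param t3_lag years between selection and the record entering the data
#'   (default 1: measured at about 100 weeks of age).
#' @param seed integer seed.
#' @return data.frame of T3 records.
#' @export
record_t3 <- function(tbv, arch, selection_time, t3_lag = 1, seed = 1L) {
  set.seed(derive_seed(seed, "t3"))
  se3 <- sqrt(arch$residual_cov[3, 3])
  ids <- as.integer(rownames(tbv))
  data.frame(animal = ids, trait = 3L,
             value = tbv[, 3] + rnorm(length(ids), 0, se3),
             available_from = rep(selection_time + t3_lag, length(ids)))
}
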