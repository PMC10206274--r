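#' Solve the three-trait mixed-model equations (BLUP / ssGBLUP)
#'
#' Henderson's mixed-model equations for `y_t = X_t b_t + Z_t a_t + e_t`
#' with a single overall mean per trait, diagonal residual covariance
#' (missing records per trait allowed) and `Var(a) = G0 x K` where `K` is
#' the pedigree relationship A (BLUP) or the combined matrix H (ssGBLUP).
#' Variance components are taken as known from the base-population
#' parameters. The system is solved directly with a sparse Cholesky
#' factorisation; for single-step, `H^{-1} = A^{-1} + [0 0; 0 G_b^{-1} -
#' A22^{-1}]` where `G_b` is the genomic matrix blended with A22
#' (`blend * G + (1 - blend) * A22`) plus a small ridge, which keeps G
#' invertible when markers are fewer than genotyped animals.
#'
#' @param ped pedigree data.frame (`id, sire, dam`, sorted).
#' @param records data.frame `animal, trait (1..3), value`; only records
#'   already available should be passed.
#' @param arch `trait_arch` supplying genetic and residual covariances.
#' @param geno optional genotype matrix (rownames = genotyped ids) to use
#'   single-step H; `NULL` or zero rows gives pedigree BLUP.
#' @param blend weight on G in the G/A22 blend.
#' @param ridge diagonal stabilisation added to the blended G.
#' @param tune rescale G to the A22 base (match mean diagonal and mean
#'   off-diagonal) before blending; without it, genotyped and non-genotyped
#'   animals sit on different bases and pooled accuracy degrades.
#' @param F optional precomputed inbreeding coefficients.
#' @return `ebv_table` data.frame: `id, T1, T2, T3, index`.
#' @export
solve_mme <- function(ped, records, arch, geno = NULL,
                      blend = 0.95, ridge = 1e-6, tune = TRUE, F = NULL) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- as.character(ped$id)
  G0 <- arch$genetic_cov
  se2 <- diag(arch$residual_cov)
  if (nrow(records) == 0L) stopf("no phenotype records supplied")
  Kinv <- build_A_inverse(ped, F = F)
  if (!is.null(geno) && nrow(geno) > 0L) {
    gids <- rownames(geno)
    pg <- pedigree_closure(ped, gids)
    Fg <- if (is.null(F)) NULL else F[match(pg$id, ped$id)]
    A22 <- build_A22(pg, gids, F = Fg)
    G <- build_G(geno)
    if (tune && nrow(geno) > 1L) G <- tune_G_to_A22(G, A22)
    Gb <- blend * G + (1 - blend) * A22
    diag(Gb) <- diag(Gb) + ridge
    delta <- solve(Gb) - solve(A22)
    k <- idx[gids]
    ng <- length(k)
    Kinv <- Kinv + Matrix::sparseMatrix(
      i = rep(k, times = ng), j = rep(k, each = ng),
      x = as.vector(delta), dims = dim(Kinv))
  }
  G0inv <- solve(G0)
  blocks <- vector("list", 3L)
  rhs_a <- numeric(3L * n)
  rhs_b <- numeric(3L)
  nrec <- numeric(3L)
  cnt <- matrix(0, n, 3L)
  ysum <- matrix(0, n, 3L)
  for (t in 1:3) {
    rt <- records[records$trait == t, , drop = FALSE]
    if (nrow(rt)) {
      a <- idx[as.character(rt$animal)]
      if (anyNA(a)) stopf("record for unknown animal")
      cnt[, t] <- tabulate(a, nbins = n)
      ysum[, t] <- unname(tapply(rt$value, factor(a, levels = seq_len(n)),
                                 sum, default = 0))
      ysum[is.na(ysum[, t]), t] <- 0
      nrec[t] <- nrow(rt)
      rhs_b[t] <- sum(rt$value) / se2[t]
    }
  }
  # LHS ordering: [b1 b2 b3 | a(T1) a(T2) a(T3)]
  LHS_aa <- Matrix::kronecker(G0inv, Kinv) +
    Matrix::Diagonal(x = as.vector(sweep(cnt, 2, se2, "/")))
  # traits without records keep a unit pivot pinning their mean at zero
  LHS_bb <- Matrix::Diagonal(x = ifelse(nrec > 0, nrec / se2, 1))
  ba <- Matrix::sparseMatrix(
    i = rep(1:3, each = n), j = seq_len(3L * n),
    x = as.vector(sweep(cnt, 2, se2, "/")), dims = c(3L, 3L * n))
  LHS <- rbind(cbind(LHS_bb, ba), cbind(Matrix::t(ba), LHS_aa))
  rhs <- c(rhs_b, as.vector(sweep(ysum, 2, se2, "/")))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(LHS), LDL = FALSE,
                         super = TRUE, perm = TRUE)
  sol <- as.vector(Matrix::solve(ch, rhs))
  a <- matrix(sol[-(1:3)], n, 3L)
  out <- data.frame(id = ped$id, T1 = a[, 1], T2 = a[, 2], T3 = a[, 3])
  out$index <- selection_index(out, arch$index_weights)
  class(out) <- c("ebv_table", class(out))
  out
}

#' Tune a genomic relationship matrix to the pedigree base
#'
#' Affine adjustment `a + b * G` chosen so the mean diagonal and the mean
#' off-diagonal of G match those of A22 over the genotyped animals.
#'
#' @param G,A22 relationship matrices over the same animals.
#' @export
tune_G_to_A22 <- function(G, A22) {
  dG <- mean(diag(G)); dA <- mean(diag(A22))
  oG <- (sum(G) - sum(diag(G))) / (length(G) - nrow(G))
  oA <- (sum(A22) - sum(diag(A22))) / (length(A22) - nrow(A22))
  if (abs(dG - oG) < 1e-12) return(G)
  b <- (dA - oA) / (dG - oG)
  a <- dA - b * dG
  out <- a + b * G
  attr(out, "p") <- attr(G, "p")
  attr(out, "denom") <- attr(G, "denom")
  out
}

#' Selection index from estimated breeding values
#'
#' Weighted sum of the three trait EBVs; default weights 0.20 / 0.35 / 0.45
#' put most emphasis on the traits measured later in life.
#'
#' @param ebv `ebv_table` or matrix/data.frame with columns T1, T2, T3.
#' @param weights length-3 weights (sum to 1 by convention).
#' @return numeric vector, one index value per animal.
#' @export
selection_index <- function(ebv, weights = c(0.20, 0.35, 0.45)) {
  m <- as.matrix(ebv[, c("T1", "T2", "T3")])
  drop(m %*% weights)
}

#' Accuracy of selection
#'
#' Pearson correlation between the index of estimated breeding values and
#' the index of true genetic values over a cohort; undefined (NA) when
#' either side has zero variance.
#'
#' @param ebv_index numeric vector of index EBVs for the cohort.
#' @param tbv_index numeric vector of index true values (same animals).
#' @export
accuracy <- function(ebv_index, tbv_index) {
  stopifnot(length(ebv_index) == length(tbv_index))
  if (length(ebv_index) < 2) return(NA_real_)
  if (stats::sd(ebv_index) == 0 || stats::sd(tbv_index) == 0) return(NA_real_)
  stats::cor(ebv_index, tbv_index)
}
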