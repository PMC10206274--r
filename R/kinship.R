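ped_recode <- function(ped) {
  # map ids to 1..n in pedigree order; parents must appear before offspring
  idx <- seq_len(nrow(ped))
  names(idx) <- as.character(ped$id)
  s <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  d <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  if (anyNA(s) || anyNA(d)) stopf("pedigree contains unknown parent ids")
  list(sire = as.integer(s), dam = as.integer(d), ids = ped$id)
}

#' Pedigree inbreeding coefficients (Meuwissen & Luo algorithm)
#'
#' @param ped pedigree data.frame (`id, sire, dam`, parents before
#'   offspring; 0 = unknown parent).
#' @return named numeric vector of F, one per animal.
#' @export
inbreeding_meuwissen_luo <- function(ped) {
  pr <- ped_recode(ped)
  F <- inbreeding_ml_cpp(pr$sire, pr$dam)
  names(F) <- as.character(pr$ids)
  F
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Builds A over a subset of animals, recursing through all their ancestors
#' (the pedigree is never truncated). Intended for moderate subsets; large
#' evaluations use the sparse inverse instead.
#'
#' @param ped pedigree data.frame.
#' @param subset animal ids to report (default: all).
#' @return dense matrix with dimnames = ids.
#' @export
build_A <- function(ped, subset = NULL) {
  pr <- ped_recode(ped)
  A <- a_dense_cpp(pr$sire, pr$dam)
  dimnames(A) <- list(as.character(pr$ids), as.character(pr$ids))
  if (!is.null(subset)) {
    k <- match(as.character(subset), rownames(A))
    if (anyNA(k)) stopf("subset ids missing from pedigree")
    A <- A[k, k, drop = FALSE]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for via Meuwissen-Luo F.
#' @param ped pedigree data.frame.
#' @param F optional precomputed inbreeding coefficients.
#' @return a `dgCMatrix` with dimnames = ids.
#' @export
build_A_inverse <- function(ped, F = NULL) {
  pr <- ped_recode(ped)
  if (is.null(F)) F <- inbreeding_ml_cpp(pr$sire, pr$dam)
  tr <- a_inverse_triplets_cpp(pr$sire, pr$dam, as.numeric(F))
  n <- nrow(ped)
  M <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
  dimnames(M) <- list(as.character(pr$ids), as.character(pr$ids))
  M
}

#' Submatrix of A for a large pedigree (Colleau's indirect method)
#'
#' Computes `A[rows, cols]` in O(n) per column without forming A, using the
#' decomposition A = T D T'.
#'
#' @param ped pedigree data.frame.
#' @param rows,cols animal ids.
#' @param F optional precomputed inbreeding coefficients.
#' @export
A_submatrix <- function(ped, rows, cols = rows, F = NULL) {
  pr <- ped_recode(ped)
  if (is.null(F)) F <- inbreeding_ml_cpp(pr$sire, pr$dam)
  ri <- match(as.character(rows), as.character(pr$ids))
  ci <- match(as.character(cols), as.character(pr$ids))
  if (anyNA(ri) || anyNA(ci)) stopf("ids missing from pedigree")
  out <- a_submatrix_cpp(pr$sire, pr$dam, as.numeric(F), ri, ci)
  dimnames(out) <- list(as.character(rows), as.character(cols))
  out
}

#' Ancestor closure of a set of animals
#'
#' Returns the pedigree restricted to the given animals and all their
#' ancestors (order preserved). Animals outside the closure carry no
#' information for a mixed-model evaluation when they have no records and
#' no genotype, so evaluations can prune them exactly.
#'
#' @param ped pedigree data.frame.
#' @param ids animal ids to keep.
#' @export
pedigree_closure <- function(ped, ids) {
  n <- nrow(ped)
  keep <- logical(n)
  keep[match(ids, ped$id)] <- TRUE
  idx <- seq_len(n); names(idx) <- as.character(ped$id)
  sire_i <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  dam_i <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  for (i in n:1) {
    if (keep[i]) {
      if (sire_i[i] > 0) keep[sire_i[i]] <- TRUE
      if (dam_i[i] > 0) keep[dam_i[i]] <- TRUE
    }
  }
  ped[keep, , drop = FALSE]
}

#' Genomic relationship matrix
#'
#' `G = W W' / (2 sum_j p_j (1 - p_j))` with `W` the genotype matrix
#' (0/1/2, alternative-allele dosage) centred by `2 p_j`. By default the
#' `p_j` are the frequencies observed in the genotyped set itself.
#'
#' @param geno genotype matrix animals x markers, rownames = ids.
#' @param freqs optional fixed centering frequencies.
#' @return dense symmetric matrix with attributes `p` and `denom`.
#' @export
build_G <- function(geno, freqs = NULL) {
  p <- freqs %||% (colMeans(geno) / 2)
  poly <- p > 0 & p < 1
  if (!any(poly)) stopf("all markers monomorphic in the genotyped set")
  denom <- 2 * sum(p * (1 - p))
  W <- sweep(geno, 2, 2 * p)
  G <- tcrossprod(W) / denom
  attr(G, "p") <- p
  attr(G, "denom") <- denom
  G
}

#' Combined pedigree-genomic relationship matrix
#'
#' `H = A + [0 0; 0 G - A22]` where `A22` is A restricted to the genotyped
#' animals. With no genotyped animals H equals A; with all animals
#' genotyped it equals G.
#'
#' @param A dense pedigree relationship matrix (dimnames = ids).
#' @param G genomic relationship matrix over the genotyped ids.
#' @param genotyped_ids ids of the genotyped animals (subset of A's index).
#' @export
build_H <- function(A, G, genotyped_ids) {
  H <- A
  if (!length(genotyped_ids)) return(H)
  k <- match(as.character(genotyped_ids), rownames(A))
  if (anyNA(k)) stopf("genotyped ids missing from A")
  H[k, k] <- G
  H
}

#' Diagnostic correlation between G and A22
#'
#' Reported only (never halts a run): correlation between the corresponding
#' entries of the genomic and pedigree relationship matrices over the
#' genotyped animals. The convention (diagonal, off-diagonal, or all
#' entries) is selectable because reference software does not pin it down.
#'
#' @param G,A22 matrices over the same genotyped animals.
#' @param which entries to correlate.
#' @export
diag_cor_G_A22 <- function(G, A22, which = c("all", "diagonal", "offdiag")) {
  which <- match.arg(which)
  stopifnot(all(dim(G) == dim(A22)))
  if (which == "diagonal") {
    g <- diag(G); a <- diag(A22)
  } else if (which == "offdiag") {
    lo <- lower.tri(G)
    g <- G[lo]; a <- A22[lo]
  } else {
    lo <- lower.tri(G, diag = TRUE)
    g <- G[lo]; a <- A22[lo]
  }
  stats::cor(g, a)
}

#' A22 over the genotyped animals from a large pedigree
#' @param ped pedigree data.frame.
#' @param genotyped_ids ids of genotyped animals.
#' @param F optional inbreeding coefficients.
#' @export
build_A22 <- function(ped, genotyped_ids, F = NULL) {
  A_submatrix(ped, genotyped_ids, genotyped_ids, F)
}
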