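# Shared fixtures, built in code.

tiny_map <- function(n_chr = 2L) {
  genome_map(n_chromosomes = n_chr,
             total_genetic_length_M = 30 / 39 * n_chr,
             total_physical_length_bp = 1.2e9 / 39 * n_chr)
}

tiny_pop <- function(n = 20L, n_chr = 2L, sites = 50L, seed = 1L) {
  simulate_founders(tiny_map(n_chr), demography(), n,
                    sites_per_chr = sites, seed = seed)
}

# random valid pedigree: `n_founders` unrelated animals then random matings
random_pedigree <- function(n, n_founders = 10L, seed = 1L) {
  set.seed(seed)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  sire <- dam <- integer(n)
  for (i in seq_len(n)[-seq_len(n_founders)]) {
    sire[i] <- sample(which(sex[seq_len(i - 1L)] == "M"), 1L)
    dam[i] <- sample(which(sex[seq_len(i - 1L)] == "F"), 1L)
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam, sex = sex,
             birth = seq_len(n))
}

# independent recursive kinship oracle (memoised path-counting recursion)
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  memo <- matrix(NA_real_, n, n)
  a <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == j) {
      1 + 0.5 * a(ped$sire[i], ped$dam[i])
    } else {
      if (i < j) { tmp <- i; i2 <- j; j2 <- tmp } else { i2 <- i; j2 <- j }
      # i2 is the younger animal
      0.5 * (a(ped$sire[i2], j2) + a(ped$dam[i2], j2))
    }
    memo[i, j] <<- v; memo[j, i] <<- v
    v
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) out[i, j] <- out[j, i] <- a(i, j)
  dimnames(out) <- list(as.character(ped$id), as.character(ped$id))
  out
}

toy_arch <- function(effects, qtl_freq = NULL) {
  tp <- trait_params()
  structure(list(effects = effects, genetic_cov = tp$genetic_cov,
                 residual_cov = tp$residual_cov,
                 index_weights = tp$index_weights, qtl_freq = qtl_freq),
            class = "trait_arch")
}

dense_mme_oracle <- function(ped, recs, arch, K = NULL, Kinv = NULL) {
  # textbook dense Henderson equations, trait-major animal blocks
  n <- nrow(ped)
  if (is.null(K)) K <- build_A(ped)
  G0i <- solve(arch$genetic_cov)
  se2 <- diag(arch$residual_cov)
  if (is.null(Kinv)) Kinv <- solve(K)
  LHS <- matrix(0, 3 + 3 * n, 3 + 3 * n)
  rhs <- numeric(3 + 3 * n)
  for (t in 1:3) {
    rt <- recs[recs$trait == t, , drop = FALSE]
    ai <- 3 + (t - 1) * n + seq_len(n)
    if (nrow(rt)) {
      Z <- matrix(0, nrow(rt), n)
      Z[cbind(seq_len(nrow(rt)), match(rt$animal, ped$id))] <- 1
      X <- matrix(1, nrow(rt), 1)
      LHS[t, t] <- LHS[t, t] + crossprod(X) / se2[t]
      LHS[t, ai] <- LHS[t, ai] + crossprod(X, Z) / se2[t]
      LHS[ai, t] <- LHS[ai, t] + crossprod(Z, X) / se2[t]
      LHS[ai, ai] <- LHS[ai, ai] + crossprod(Z) / se2[t]
      rhs[t] <- sum(rt$value) / se2[t]
      rhs[ai] <- crossprod(Z, rt$value) / se2[t]
    } else {
      LHS[t, t] <- 1  # pin the unused mean at zero; EBVs are unaffected
    }
  }
  for (t1 in 1:3) for (t2 in 1:3) {
    i1 <- 3 + (t1 - 1) * n + seq_len(n); i2 <- 3 + (t2 - 1) * n + seq_len(n)
    LHS[i1, i2] <- LHS[i1, i2] + G0i[t1, t2] * Kinv
  }
  sol <- solve(LHS, rhs)
  matrix(sol[-(1:3)], n, 3)
}

toy_problem <- function(n_sires = 2, window = NULL, seed = 3) {
  set.seed(seed)
  A <- diag(10)
  A[1, 2] <- A[2, 1] <- 0.5
  dimnames(A) <- list(1:10, 1:10)
  a <- setNames(c(1.0, 0.9, 0.5, 0.4, 0.3, 0.2, rep(0.1, 4)), 1:10)
  if (is.null(window)) ocs_problem(1:6, 7:10, a, A, n_sires = n_sires)
  else ocs_problem(1:6, 7:10, a, A, n_sires = NULL, sire_window = window)
}

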