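test_that("A has textbook values on simple pedigrees", {
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2),
                    sex = c("M", "F", "M"), birth = c(0, 0, 1))
  A <- build_A(ped)
  expect_equal(unname(diag(A)), rep(1, 3))
  expect_equal(A["1", "3"], 0.5)
  expect_equal(A["1", "2"], 0)
  # full-sib mating: offspring inbreeding 0.25
  ped5 <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                     dam = c(0, 0, 2, 2, 4),
                     sex = c("M", "F", "M", "F", "M"), birth = 0:4)
  expect_equal(unname(build_A(ped5)[5, 5]), 1.25)
  expect_equal(unname(inbreeding_meuwissen_luo(ped5)["5"]), 0.25)
})

test_that("tabular A equals the recursive oracle on random 50-animal pedigrees",
{
  for (s in 1:3) {
    ped <- random_pedigree(50, seed = s)
    expect_equal(build_A(ped), kinship_oracle(ped), tolerance = 1e-12)
  }
})

test_that("Meuwissen-Luo F equals diag(A) - 1 on a 200-animal pedigree", {
  ped <- random_pedigree(200, seed = 99)
  A <- build_A(ped)
  F <- inbreeding_meuwissen_luo(ped)
  expect_equal(unname(F), unname(diag(A) - 1), tolerance = 1e-12)
  expect_true(all(F[ped$sire == 0] == 0))
})

test_that("sparse A-inverse and Colleau submatrices agree with dense A", {
  ped <- random_pedigree(120, seed = 3)
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped)
  expect_lt(max(abs(as.matrix(A %*% Ainv) - diag(120))), 1e-10)
  rows <- c(5, 30, 77, 120); cols <- c(1, 60, 119)
  As <- A_submatrix(ped, rows, cols)
  expect_equal(As, A[as.character(rows), as.character(cols)],
               tolerance = 1e-12)
  # ancestor closure keeps submatrices identical
  pc <- pedigree_closure(ped, rows)
  F <- inbreeding_meuwissen_luo(ped)
  As2 <- A_submatrix(pc, rows, rows, F = unname(F[as.character(pc$id)]))
  expect_equal(As2, A[as.character(rows), as.character(rows)],
               tolerance = 1e-12)
})

test_that("G reproduces the printed-formula toy and a brute-force oracle", {
  geno <- rbind(`1` = c(0, 2), `2` = c(2, 0))
  G <- build_G(geno, freqs = c(0.5, 0.5))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical genotypes -> all entries equal
  geno2 <- matrix(rep(c(0, 1, 2, 1), each = 3), 3, 4,
                  dimnames = list(1:3, NULL))
  G2 <- build_G(geno2)
  expect_true(max(G2) - min(G2) < 1e-12)
  # random toy vs naive double loop with observed frequencies
  set.seed(21)
  geno3 <- matrix(sample(0:2, 20 * 100, replace = TRUE), 20, 100,
                  dimnames = list(1:20, NULL))
  G3 <- build_G(geno3)
  p <- colMeans(geno3) / 2
  denom <- 2 * sum(p * (1 - p))
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    oracle[i, j] <- sum((geno3[i, ] - 2 * p) * (geno3[j, ] - 2 * p)) / denom
  }
  expect_equal(unname(G3), oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(build_G(matrix(2, 3, 4, dimnames = list(1:3, NULL))),
               "monomorphic")
})

test_that("H block identities hold", {
  ped <- random_pedigree(10, n_founders = 4L, seed = 8)
  A <- build_A(ped)
  set.seed(4)
  geno <- matrix(sample(0:2, 10 * 30, replace = TRUE), 10, 30,
                 dimnames = list(ped$id, NULL))
  # no genotyped animals -> H = A
  expect_identical(build_H(A, matrix(0, 0, 0), integer(0)), A)
  # all genotyped -> H = G
  G <- build_G(geno)
  expect_equal(unname(build_H(A, G, ped$id)), unname(G),
               ignore_attr = TRUE)
  # mixed: direct block assembly oracle
  gids <- c(2, 5, 9)
  Gg <- build_G(geno[as.character(gids), ])
  H <- build_H(A, Gg, gids)
  k <- match(as.character(gids), rownames(A))
  oracle <- A
  oracle[k, k] <- A[k, k] + (Gg - A[k, k])
  expect_equal(H, oracle, tolerance = 1e-12)
  # H restricted to non-genotyped animals equals A there
  nk <- setdiff(seq_len(10), k)
  expect_identical(H[nk, nk], A[nk, nk])
  expect_identical(H, t(H))
})

test_that("G/A22 diagnostic correlation behaves and never halts", {
  # pedigree with inbreeding so the A22 diagonal is not constant
  ped <- data.frame(id = 1:12,
                    sire = c(0, 0, 1, 1, 3, 3, 5, 5, 7, 7, 9, 9),
                    dam = c(0, 0, 2, 2, 4, 4, 6, 6, 8, 8, 10, 10),
                    sex = rep(c("M", "F"), 6), birth = 0:11)
  A22 <- build_A(ped, subset = 5:12)
  expect_equal(diag_cor_G_A22(A22, A22), 1.0)
  expect_equal(diag_cor_G_A22(-A22 + 2, A22), -1.0)
  set.seed(9)
  Gr <- A22 + matrix(rnorm(64, sd = 0.1), 8)
  Gr <- (Gr + t(Gr)) / 2
  lo <- lower.tri(Gr, diag = TRUE)
  expect_equal(diag_cor_G_A22(Gr, A22, "all"), cor(Gr[lo], A22[lo]))
  expect_equal(diag_cor_G_A22(Gr, A22, "diagonal"),
               cor(diag(Gr), diag(A22)))
})

test_that("mean off-diagonal of G is near zero with own-cohort centering", {
  pop <- tiny_pop(n = 80, n_chr = 2, sites = 150, seed = 13)
  part <- partition_loci(pop, c(10, 100, 40), seed = 1)
  geno <- dosages(pop, part$snp)
  G <- build_G(geno)
  offd <- G[lower.tri(G)]
  expect_lt(abs(mean(offd)), 0.02)
})
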