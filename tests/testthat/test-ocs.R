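test_that("truncation selection picks the top-n with deterministic ties", {
  ids <- 1:8
  sex <- c("M", "M", "M", "M", "F", "F", "F", "F")
  idx <- c(0.2, 0.9, 0.9, 0.1, 0.5, 0.7, 0.5, 0.3)
  sel <- truncation_select(ids, sex, idx, n_females = 2, n_males = 2)
  expect_identical(sel$males, c(2L, 3L))      # tie 2 vs 3 -> smaller id first
  expect_identical(sel$females, c(6L, 5L))    # tie 5 vs 7 -> smaller id
  expect_error(truncation_select(ids, sex, idx, 5, 1), "insufficient")
  # oracle: sort-then-cut with the stated tie rule
  set.seed(4)
  idx2 <- sample(round(runif(8), 1))
  sel2 <- truncation_select(ids, sex, idx2, 2, 2)
  om <- order(-idx2[1:4], ids[1:4])[1:2]
  expect_identical(sel2$males, ids[1:4][om])
})

test_that("random mating deals equal quotas and is seed-stable", {
  plan <- random_mating(sires = 1:120, dams = 1000 + 1:1080, seed = 5)
  expect_true(all(table(plan$sire) == 9))
  expect_setequal(plan$dam, 1000 + 1:1080)
  expect_identical(plan, random_mating(1:120, 1000 + 1:1080, seed = 5))
  p1 <- random_mating(1, 2:10, seed = 1)
  expect_true(all(p1$sire == 1))
  expect_error(random_mating(1:7, 1:10), "multiple")
})

test_that("min-inbreeding mating matches exhaustive assignment on 2x4 toys", {
  # sires 1,2; dams 3:6; sire 1 related to dam 3
  ids <- 1:6
  A <- diag(6); A[1, 3] <- A[3, 1] <- 0.5; A[2, 5] <- A[5, 2] <- 0.25
  dimnames(A) <- list(ids, ids)
  plan <- min_inbreeding_matings(1:2, 3:6, A, seed = 2, iters = 500)
  # exhaustive: all ways to give each sire 2 dams
  combos <- utils::combn(3:6, 2)
  best <- Inf
  for (k in seq_len(ncol(combos))) {
    d1 <- combos[, k]; d2 <- setdiff(3:6, d1)
    val <- mean(c(A[1, d1], A[2, d2]) / 2)
    best <- min(best, val)
  }
  expect_equal(attr(plan, "mean_pair_coancestry"), best, tolerance = 1e-12)
  # never worse than the random plan it starts from
  rnd <- random_mating(1:2, 3:6, seed = 2)
  rnd_val <- mean(A[cbind(rnd$sire, rnd$dam)] / 2)
  expect_lte(attr(plan, "mean_pair_coancestry"), rnd_val)
  # unrelated candidates: any plan is optimal with mean progeny F = 0
  A0 <- diag(6); dimnames(A0) <- list(ids, ids)
  p0 <- min_inbreeding_matings(1:2, 3:6, A0, seed = 3)
  expect_equal(attr(p0, "mean_pair_coancestry"), 0)
})

test_that("coancestry statistics implement the printed formulas", {
  # A = I, uniform x over n -> cbar_{t+1} = 1/n
  n <- 8; m <- 4
  A <- diag(n)
  x <- rep(1 / n, n)
  st <- coancestry_stats(x, A, m)
  expect_equal(st$cbar_t1, 1 / n)
  expect_equal(st$cbar_t, n / (4 * m^2))
  expect_equal(st$dC, (st$cbar_t1 - st$cbar_t) / (1 - st$cbar_t))
  # dC = 0.0125 -> Ne = 40; dC = 0.01 -> Ne = 50
  expect_equal(1 / (2 * 0.0125), 40)
  st2 <- list(dC = 0.01)
  expect_equal(1 / (2 * st2$dC), 50)
  # random toy equals a direct formula oracle
  set.seed(6)
  M <- crossprod(matrix(rnorm(49), 7)) / 7 + diag(7) * 0.5
  xr <- runif(7); xr <- xr / sum(xr)
  so <- coancestry_stats(xr, M, 3)
  expect_equal(so$cbar_t1, drop(t(xr) %*% M %*% xr))
  expect_equal(so$cbar_t, sum(M) / 36)
})

test_that("frontier endpoints: truncation gain at 0, min coancestry at 90", {
  prob <- toy_problem(n_sires = 2)
  ep <- frontier_endpoints(prob, seed = 1)
  # 0 degrees: top-2 males (1, 2) at equal quotas of the 4 matings
  expect_equal(unname(ep$max_gain$counts[1:2]), c(2L, 2L))
  expect_equal(ep$max_gain$gain,
               (2 * 1.0 + 2 * 0.9) / 8 + 4 * 0.1 / 8)
  # 90 degrees minimizes x'Ax among 2-sire solutions: exhaustive oracle
  counts_grid <- list()
  for (i in 1:5) for (j in (i + 1):6) for (ci in 1:3) {
    cnt <- integer(6); cnt[i] <- ci; cnt[j] <- 4 - ci
    counts_grid[[length(counts_grid) + 1]] <- cnt
  }
  co <- vapply(counts_grid,
               function(cn) ocsim:::ocs_eval(cn, prob)[["coancestry"]],
               numeric(1))
  expect_equal(ep$min_coancestry$coancestry, min(co), tolerance = 1e-12)
})

test_that("solve_ocs matches exhaustive search of the penalized objective", {
  prob <- toy_problem(n_sires = 2)
  ep <- frontier_endpoints(prob, seed = 1)
  counts_grid <- list()
  for (i in 1:5) for (j in (i + 1):6) for (ci in 1:3) {
    cnt <- integer(6); cnt[i] <- ci; cnt[j] <- 4 - ci
    counts_grid[[length(counts_grid) + 1]] <- cnt
  }
  for (th in c(15, 45, 75)) {
    fits <- vapply(counts_grid, function(cn)
      frontier_fitness(ocsim:::ocs_eval(cn, prob), ep, th), numeric(1))
    best <- max(fits)
    sol <- solve_ocs(prob, th, seed = 4, endpoints = ep)
    got <- frontier_fitness(c(gain = sol$gain, coancestry = sol$coancestry),
                            ep, th)
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("solutions respect bounds, windows and endpoint contracts", {
  prob <- toy_problem(window = c(2, 5))
  ep <- frontier_endpoints(prob, seed = 2)
  s0 <- solve_ocs(prob, 0, seed = 3, endpoints = ep)
  s90 <- solve_ocs(prob, 90, seed = 3, endpoints = ep)
  expect_lt(abs(s0$gain - ep$max_gain$gain), 0.01 * abs(ep$max_gain$gain))
  expect_lt(abs(s90$coancestry - ep$min_coancestry$coancestry),
            0.01 * abs(ep$min_coancestry$coancestry) + 1e-12)
  for (th in c(20, 50, 80)) {
    s <- solve_ocs(prob, th, seed = 5, endpoints = ep)
    expect_gte(s$sires_used, 2)
    expect_lte(s$sires_used, 5)
    expect_true(all(s$counts <= prob$cap))
    expect_equal(sum(s$counts), prob$m)
  }
  # determinism given seed
  sA <- solve_ocs(prob, 35, seed = 11, endpoints = ep)
  sB <- solve_ocs(prob, 35, seed = 11, endpoints = ep)
  expect_identical(sA$counts, sB$counts)
})

test_that("degenerate frontier returns the common solution with a warning", {
  A <- diag(6); dimnames(A) <- list(1:6, 1:6)
  a <- setNames(rep(1, 6), 1:6)   # equal index values
  prob <- ocs_problem(1:2, 3:6, a, A, n_sires = 2)
  ep <- frontier_endpoints(prob, seed = 1)
  if (abs(ep$max_gain$gain - ep$min_coancestry$gain) < 1e-12 &&
      abs(ep$max_gain$coancestry - ep$min_coancestry$coancestry) < 1e-12) {
    expect_warning(solve_ocs(prob, 45, seed = 1, endpoints = ep),
                   "coincide")
  } else {
    succeed("endpoints differ on this toy; degeneracy covered elsewhere")
  }
})

test_that("frontier is monotone over a degree grid on a simulated problem", {
  # mid-size problem from a simulated pedigree
  set.seed(14)
  ped <- random_pedigree(300, n_founders = 30, seed = 15)
  males <- ped$id[ped$sex == "M" & ped$id > 200]
  females <- ped$id[ped$sex == "F" & ped$id > 200]
  males <- head(males, 40); females <- head(females, 36)
  A <- build_A(ped, subset = c(males, females))
  a <- setNames(rnorm(length(c(males, females))),
                c(males, females))
  prob <- ocs_problem(males, females, a, A, n_sires = 8)
  ep <- frontier_endpoints(prob, seed = 21,
                           control = list(generations = 150L))
  grid <- c(5, 25, 45, 65, 85)
  sols <- lapply(grid, function(th)
    solve_ocs(prob, th, seed = 22, endpoints = ep,
              control = list(generations = 150L)))
  gains <- vapply(sols, `[[`, numeric(1), "gain")
  dCs <- vapply(sols, `[[`, numeric(1), "dC")
  expect_true(all(diff(gains) <= 1e-9))
  expect_true(all(diff(dCs) <= 1e-9))
})
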