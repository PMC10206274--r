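#' Truncation selection by index
#'
#' Top-n per sex by index value; ties broken deterministically by animal id
#' (smaller id first).
#'
#' @param ids animal ids.
#' @param sex "M"/"F" per animal.
#' @param index index values per animal.
#' @param n_females,n_males numbers to select.
#' @return list with `females` and `males` (ids, in descending index order).
#' @export
truncation_select <- function(ids, sex, index, n_females, n_males) {
  pick <- function(keep, n) {
    if (sum(keep) < n) stopf("insufficient candidates: need %d, have %d",
                             n, sum(keep))
    o <- order(-index[keep], ids[keep])
    ids[keep][o][seq_len(n)]
  }
  list(females = pick(sex == "F", n_females),
       males = pick(sex == "M", n_males))
}

#' Random mating with equal sire contributions
#'
#' Dams are permuted and dealt to sires in equal blocks (27 dams per sire in
#' the 40-sire programme, 9 in the 120-sire programme).
#'
#' @param sires,dams selected ids.
#' @param seed integer seed.
#' @return data.frame `sire, dam`, one row per mating (each dam once).
#' @export
random_mating <- function(sires, dams, seed = 1L) {
  q <- length(dams) / length(sires)
  if (q != round(q)) stopf("dams (%d) not a multiple of sires (%d)",
                           length(dams), length(sires))
  set.seed(derive_seed(seed, "mating"))
  data.frame(sire = rep(sires, each = q), dam = sample(dams))
}

#' Mating plan from optimized sire mating counts
#'
#' Random pairing of the optimized contributions: dams are permuted and
#' dealt to sires according to their mating counts.
#' @param counts named integer vector (names = sire ids) summing to the
#'   number of dams.
#' @param dams dam ids.
#' @param seed integer seed.
#' @export
counts_to_matings <- function(counts, dams, seed = 1L) {
  counts <- counts[counts > 0]
  if (sum(counts) != length(dams)) stopf("counts must sum to number of dams")
  set.seed(derive_seed(seed, "pairing"))
  data.frame(sire = rep(as.integer(names(counts)), counts),
             dam = sample(dams))
}

plan_mean_coancestry <- function(plan, A) {
  mean(A[cbind(match(as.character(plan$sire), rownames(A)),
               match(as.character(plan$dam), colnames(A)))] / 2)
}

#' Mate allocation minimizing progeny inbreeding
#'
#' Keeps the truncation-selected parents and their equal quotas, but
#' searches over dam-to-sire assignments to minimize the mean coancestry of
#' the mated pairs (the expected progeny inbreeding). A seeded hill-climb
#' over pairwise dam swaps is used; the objective never increases, so the
#' returned plan is never worse than the random starting plan.
#'
#' @param sires,dams selected ids (dams a multiple of sires).
#' @param A relationship matrix over sires and dams (dimnames = ids).
#' @param seed integer seed.
#' @param iters number of candidate swaps.
#' @return data.frame `sire, dam` with attribute `mean_pair_coancestry`.
#' @export
min_inbreeding_matings <- function(sires, dams, A, seed = 1L, iters = 2000L) {
  plan <- random_mating(sires, dams, seed)
  si <- match(as.character(plan$sire), rownames(A))
  di <- match(as.character(plan$dam), colnames(A))
  if (anyNA(si) || anyNA(di)) stopf("plan ids missing from A")
  cost <- A[cbind(si, di)] / 2
  n <- nrow(plan)
  set.seed(derive_seed(seed, "minF"))
  prop <- matrix(sample.int(n, 2L * iters, replace = TRUE), ncol = 2L)
  for (k in seq_len(iters)) {
    i <- prop[k, 1]; j <- prop[k, 2]
    if (i == j) next
    new_i <- A[si[i], di[j]] / 2
    new_j <- A[si[j], di[i]] / 2
    if (new_i + new_j < cost[i] + cost[j]) {
      tmp <- di[i]; di[i] <- di[j]; di[j] <- tmp
      cost[i] <- new_i; cost[j] <- new_j
    }
  }
  out <- data.frame(sire = plan$sire, dam = as.integer(colnames(A)[di]))
  attr(out, "mean_pair_coancestry") <- mean(cost)
  out
}

#' Define an optimal-contribution problem
#'
#' Contributions are represented as integer mating counts on the male side
#' (a dam is one mating), so a solution is directly realizable as a mating
#' plan. Females are fixed at the truncation-selected dams with equal
#' contributions `1/(2m)`; the optimization runs on males only, but the
#' full relationship matrix (male-male, male-female and female-female
#' blocks) enters the group coancestry, which accounts for the female
#' selection already made.
#'
#' @param male_ids candidate male ids.
#' @param female_ids selected dam ids (defines `m`, the number of matings).
#' @param a index values named by id (males and females).
#' @param A pedigree relationship matrix over all candidates (dimnames ids).
#' @param n_sires fixed number of sires, or `NULL` for a sire window.
#' @param sire_window allowed range of the number of sires when
#'   `n_sires = NULL` (default 20-200).
#' @param bound per-candidate contribution bound (0.5).
#' @return object of class `ocs_problem`.
#' @export
ocs_problem <- function(male_ids, female_ids, a, A, n_sires = NULL,
                        sire_window = c(20L, 200L), bound = 0.5) {
  male_ids <- as.integer(male_ids); female_ids <- as.integer(female_ids)
  mi <- match(as.character(male_ids), rownames(A))
  fi <- match(as.character(female_ids), rownames(A))
  if (anyNA(mi) || anyNA(fi)) stopf("candidate ids missing from A")
  m <- length(female_ids)
  a_m <- a[as.character(male_ids)]; a_f <- a[as.character(female_ids)]
  if (anyNA(a_m) || anyNA(a_f)) stopf("index values missing for candidates")
  xf <- rep(1 / (2 * m), m)
  A_mm <- A[mi, mi, drop = FALSE]
  A_mf <- A[mi, fi, drop = FALSE]
  cff <- drop(crossprod(xf, A[fi, fi, drop = FALSE] %*% xf))
  v <- drop(A_mf %*% xf)
  if (!is.null(n_sires)) {
    n_sires <- as.integer(n_sires)
    if (n_sires > length(male_ids)) stopf("fewer male candidates than sires")
    sire_window <- c(n_sires, n_sires)
  }
  structure(list(
    male_ids = male_ids, female_ids = female_ids, m = m,
    a_m = unname(a_m), gain_f = sum(a_f * xf),
    A_mm = A_mm, v = v, cff = cff, A_full = A, mi = mi, fi = fi,
    n_sires = n_sires, sire_window = as.integer(sire_window),
    bound = bound, cap = max(1L, floor(bound * 2 * m))
  ), class = "ocs_problem")
}

# gain and group coancestry of a male mating-count vector (length = males)
ocs_eval <- function(counts, prob) {
  s <- which(counts > 0L)
  xm <- counts[s] / (2 * prob$m)
  gain <- sum(xm * prob$a_m[s]) + prob$gain_f
  coan <- drop(crossprod(xm, prob$A_mm[s, s, drop = FALSE] %*% xm)) +
    2 * sum(xm * prob$v[s]) + prob$cff
  c(gain = gain, coancestry = coan)
}

ocs_solution <- function(counts, prob) {
  ev <- ocs_eval(counts, prob)
  x <- c(counts / (2 * prob$m), rep(1 / (2 * prob$m), prob$m))
  names(x) <- c(prob$male_ids, prob$female_ids)
  st <- coancestry_stats_from_problem(ev[["coancestry"]], prob)
  structure(list(
    counts = stats::setNames(counts, prob$male_ids),
    x = x, gain = ev[["gain"]], coancestry = ev[["coancestry"]],
    dC = st$dC, Ne = st$Ne, sires_used = sum(counts > 0L)
  ), class = "ocs_solution")
}

coancestry_stats_from_problem <- function(cbar_t1, prob) {
  cbar_t <- sum(prob$A_full[c(prob$mi, prob$fi), c(prob$mi, prob$fi)]) /
    (4 * prob$m^2)
  dC <- (cbar_t1 - cbar_t) / (1 - cbar_t)
  list(cbar_t = cbar_t, cbar_t1 = cbar_t1, dC = dC,
       Ne = if (dC > 0) 1 / (2 * dC) else NA_real_)
}

#' Group-coancestry statistics of a contribution vector
#'
#' Implements the printed formulas: `cbar_{t+1} = x'Ax`,
#' `cbar_t = 1'A1/(4m^2)`, `dC = (cbar_{t+1} - cbar_t)/(1 - cbar_t)` and
#' `Ne = 1/(2 dC)` (reported only when `dC > 0`).
#'
#' @param x contribution vector (sums to 1 over both sexes).
#' @param A relationship matrix over the same candidates.
#' @param m number of matings.
#' @export
coancestry_stats <- function(x, A, m) {
  stopifnot(length(x) == nrow(A))
  cbar_t1 <- drop(crossprod(x, A %*% x))
  cbar_t <- sum(A) / (4 * m^2)
  if (cbar_t >= 1) stopf("current group coancestry >= 1")
  dC <- (cbar_t1 - cbar_t) / (1 - cbar_t)
  list(cbar_t = cbar_t, cbar_t1 = cbar_t1, dC = dC,
       Ne = if (dC > 0) 1 / (2 * dC) else NA_real_)
}

# equal-contribution truncation solution with s sires
truncation_counts <- function(prob, s) {
  counts <- integer(length(prob$male_ids))
  o <- order(-prob$a_m, prob$male_ids)
  top <- o[seq_len(s)]
  base <- prob$m %/% s
  counts[top] <- base
  extra <- prob$m - base * s
  if (extra > 0) counts[top[seq_len(extra)]] <- counts[top[seq_len(extra)]] + 1L
  counts
}

#' Frontier endpoints of an OCS problem
#'
#' The maximum-gain (0 degree) endpoint follows the operational definition
#' that 0 degrees equals truncation selection: the top sires by index at
#' their equal quotas (at the lower end of the sire window when the sire
#' count is free, since fewer sires concentrate more gain). The minimum-
#' coancestry (90 degree) endpoint is found by the evolutionary algorithm
#' minimizing `x'Ax` alone.
#'
#' @param prob an [ocs_problem()].
#' @param seed integer seed.
#' @param control EA control list, see [solve_ocs()].
#' @return list with `max_gain` and `min_coancestry` `ocs_solution`s.
#' @export
frontier_endpoints <- function(prob, seed = 1L, control = list()) {
  c0 <- truncation_counts(prob, prob$sire_window[1])
  e0 <- ocs_solution(c0, prob)
  # warm starts: truncation and the widest equal spread the window allows
  spread <- truncation_counts(prob, min(prob$sire_window[2],
                                        length(prob$male_ids)))
  c90 <- ea_optimize(prob, fitness = function(ev, counts) -ev[["coancestry"]],
                     seed = derive_seed(seed, "ep90"), control = control,
                     init = list(c0, spread))
  e90 <- ocs_solution(c90, prob)
  list(max_gain = e0, min_coancestry = e90)
}

# ---- evolutionary algorithm over male mating-count vectors ----------------

ea_random_counts <- function(prob) {
  s <- if (!is.null(prob$n_sires)) prob$n_sires else
    sample(seq(prob$sire_window[1], min(prob$sire_window[2],
                                        length(prob$male_ids))), 1L)
  counts <- integer(length(prob$male_ids))
  pick <- sample.int(length(prob$male_ids), s)
  base <- prob$m %/% s
  counts[pick] <- base
  extra <- prob$m - base * s
  if (extra > 0) counts[pick[seq_len(extra)]] <-
      counts[pick[seq_len(extra)]] + 1L
  counts
}

ea_feasible <- function(counts, prob) {
  s <- sum(counts > 0L)
  s >= prob$sire_window[1] &&
    s <= min(prob$sire_window[2], length(prob$male_ids)) &&
    max(counts) <= prob$cap && sum(counts) == prob$m
}

ea_mutate <- function(counts, prob) {
  used <- which(counts > 0L)
  op <- sample.int(3L, 1L)
  if (op == 1L && length(used) >= 2L) {
    # transfer matings between two used sires (keep both used)
    ij <- sample(used, 2L)
    k <- sample.int(counts[ij[1]], 1L)
    if (counts[ij[1]] - k < 1L) k <- counts[ij[1]] - 1L
    if (k > 0 && counts[ij[2]] + k <= prob$cap) {
      counts[ij[1]] <- counts[ij[1]] - k
      counts[ij[2]] <- counts[ij[2]] + k
    }
  } else if (op == 2L) {
    # swap a used sire for an unused male
    un <- which(counts == 0L)
    if (length(un) && length(used)) {
      i <- sample(used, 1L); j <- if (length(un) == 1L) un else sample(un, 1L)
      counts[j] <- counts[i]; counts[i] <- 0L
    }
  } else {
    # grow or shrink the support by one sire when the window allows it
    s <- length(used)
    un <- which(counts == 0L)
    if (runif(1) < 0.5 && s < min(prob$sire_window[2],
                                  length(prob$male_ids)) && length(un)) {
      j <- if (length(un) == 1L) un else sample(un, 1L)
      i <- if (s == 1L) used else sample(used, 1L)
      if (counts[i] > 1L) {
        k <- sample.int(counts[i] - 1L, 1L)
        counts[i] <- counts[i] - k; counts[j] <- k
      }
    } else if (s > prob$sire_window[1] && s >= 2L) {
      i <- sample(used, 1L); j <- sample(setdiff(used, i), 1L)
      if (counts[j] + counts[i] <= prob$cap) {
        counts[j] <- counts[j] + counts[i]; counts[i] <- 0L
      }
    }
  }
  counts
}

ea_cross <- function(p1, p2, prob) {
  child <- ifelse(runif(length(p1)) < 0.5, p1, p2)
  if (sum(child) == 0L) return(ea_random_counts(prob))
  diff <- sum(child) - prob$m
  used <- which(child > 0L)
  while (diff != 0L && length(used)) {
    i <- if (length(used) == 1L) used else sample(used, 1L)
    if (diff > 0L) {
      d <- min(child[i] - 0L, diff); child[i] <- child[i] - d; diff <- diff - d
    } else {
      d <- min(prob$cap - child[i], -diff)
      child[i] <- child[i] + d; diff <- diff + d
    }
    used <- which(child > 0L)
  }
  # repair the support size into the allowed window
  hi <- min(prob$sire_window[2], length(prob$male_ids))
  lo <- prob$sire_window[1]
  target <- min(max(sum(child > 0L), lo), hi)
  repeat {
    used <- which(child > 0L)
    if (length(used) <= target) break
    i <- used[which.min(child[used])]
    recv <- used[used != i & child[used] + child[i] <= prob$cap]
    if (!length(recv)) break
    j <- if (length(recv) == 1L) recv else sample(recv, 1L)
    child[j] <- child[j] + child[i]; child[i] <- 0L
  }
  repeat {
    used <- which(child > 0L); un <- which(child == 0L)
    if (!length(used) || length(used) >= target || !length(un)) break
    i <- used[which.max(child[used])]
    if (child[i] < 2L) break
    j <- if (length(un) == 1L) un else sample(un, 1L)
    k <- child[i] %/% 2L
    child[i] <- child[i] - k; child[j] <- k
  }
  child
}

ea_optimize <- function(prob, fitness, seed, control = list(),
                        init = list()) {
  ct <- utils::modifyList(list(mu = 30L, lambda = 120L, generations = 250L,
                               stagnation = 60L), control)
  set.seed(seed)
  pop <- replicate(ct$mu, ea_random_counts(prob), simplify = FALSE)
  init <- Filter(function(cn) ea_feasible(cn, prob), init)
  if (length(init)) pop[seq_along(init)] <- init
  fit <- vapply(pop, function(c) {
    if (!ea_feasible(c, prob)) return(-Inf)
    fitness(ocs_eval(c, prob), c)
  }, numeric(1))
  best <- pop[[which.max(fit)]]; best_fit <- max(fit); stag <- 0L
  for (g in seq_len(ct$generations)) {
    kids <- vector("list", ct$lambda)
    for (k in seq_len(ct$lambda)) {
      if (runif(1) < 0.3 && ct$mu >= 2L) {
        ij <- sample.int(ct$mu, 2L)
        child <- ea_cross(pop[[ij[1]]], pop[[ij[2]]], prob)
      } else {
        child <- pop[[sample.int(ct$mu, 1L)]]
      }
      kids[[k]] <- ea_mutate(child, prob)
    }
    kfit <- vapply(kids, function(c) {
      if (!ea_feasible(c, prob)) return(-Inf)
      fitness(ocs_eval(c, prob), c)
    }, numeric(1))
    all_pop <- c(pop, kids); all_fit <- c(fit, kfit)
    keep <- order(all_fit, decreasing = TRUE)[seq_len(ct$mu)]
    pop <- all_pop[keep]; fit <- all_fit[keep]
    if (fit[1] > best_fit + 1e-12) {
      best_fit <- fit[1]; best <- pop[[1]]; stag <- 0L
    } else stag <- stag + 1L
    if (stag >= ct$stagnation) break
  }
  best
}

#' Normalized frontier fitness of a candidate solution
#'
#' Gain and coancestry are rescaled to \[0, 1\] between the two endpoint
#' solutions; the solution angle is `atan2(normalized coancestry reduction,
#' normalized gain)` in degrees. The fitness is the projection of the
#' normalized point onto the target direction minus a penalty proportional
#' to the deviation of the angle from the target degrees; points outside
#' the endpoint box (more gain than the 0-degree endpoint, or more
#' coancestry than it) are rejected. This is the package's operational
#' reading of the trigonometric-penalty construction, documented as such.
#'
#' @param ev named vector `gain`, `coancestry` of the candidate.
#' @param endpoints output of [frontier_endpoints()].
#' @param degrees target trigonometric penalty degrees in \[0, 90\].
#' @param penalty penalty weight per 90 degrees of deviation.
#' @export
frontier_fitness <- function(ev, endpoints, degrees, penalty = 5) {
  g0 <- endpoints$max_gain$gain; g90 <- endpoints$min_coancestry$gain
  c0 <- endpoints$max_gain$coancestry
  c90 <- endpoints$min_coancestry$coancestry
  if (abs(g0 - g90) < 1e-12 || abs(c0 - c90) < 1e-12) {
    return(-abs(ev[["coancestry"]] - c90))   # degenerate frontier
  }
  gt <- (ev[["gain"]] - g90) / (g0 - g90)
  ct <- (c0 - ev[["coancestry"]]) / (c0 - c90)
  if (gt > 1 + 1e-9 || ct < -1e-9) return(-Inf)
  ang <- atan2(max(ct, 0), max(gt, 0)) * 180 / pi
  th <- degrees * pi / 180
  gt * cos(th) + ct * sin(th) - penalty * abs(ang - degrees) / 90
}

#' Optimal contribution selection at a target penalty degree
#'
#' Evolutionary search over male mating-count vectors maximizing
#' [frontier_fitness()] at the target degrees, subject to the per-candidate
#' contribution bound and the sire-count constraint (fixed count, or the
#' 20-200 window with infeasible solutions rejected outright). 0 degrees
#' reproduces the truncation endpoint, 90 degrees the minimum-coancestry
#' endpoint; across a degree grid gain and the rate of coancestry are
#' non-increasing.
#'
#' @param prob an [ocs_problem()].
#' @param degrees target degrees in \[0, 90\].
#' @param seed integer seed (the solution is deterministic given the seed).
#' @param control list overriding EA defaults `mu`, `lambda`, `generations`,
#'   `stagnation`.
#' @param endpoints optional precomputed [frontier_endpoints()].
#' @return an `ocs_solution`: counts, contributions `x`, gain `x'a`, group
#'   coancestry `x'Ax`, `dC`, implied `Ne`, and `sires_used`.
#' @export
solve_ocs <- function(prob, degrees, seed = 1L, control = list(),
                      endpoints = NULL) {
  stopifnot(degrees >= 0, degrees <= 90)
  if (is.null(endpoints)) endpoints <- frontier_endpoints(prob, seed, control)
  e0 <- endpoints$max_gain; e90 <- endpoints$min_coancestry
  if (abs(e0$gain - e90$gain) < 1e-12 &&
      abs(e0$coancestry - e90$coancestry) < 1e-12) {
    out <- e0; out$degenerate <- TRUE
    warning("frontier endpoints coincide; returning the common solution")
    return(out)
  }
  if (degrees == 0) return(e0)
  if (degrees == 90) return(e90)
  fit <- function(ev, counts) frontier_fitness(ev, endpoints, degrees)
  best <- ea_optimize(prob, fit, derive_seed(seed, "theta", degrees), control,
                      init = list(as.integer(unname(e0$counts)),
                                  as.integer(unname(e90$counts))))
  # keep whichever of EA result / endpoints scores best (elitism across runs)
  cand <- list(best, e0$counts %+z% prob, e90$counts %+z% prob)
  sc <- vapply(cand, function(c) frontier_fitness(ocs_eval(c, prob),
                                                  endpoints, degrees),
               numeric(1))
  ocs_solution(cand[[which.max(sc)]], prob)
}

# strip names helper: endpoint counts back to bare integer vector
`%+z%` <- function(counts, prob) as.integer(unname(counts))
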