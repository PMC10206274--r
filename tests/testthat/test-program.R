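tiny_cfg <- function(scenario, ...) {
  args <- utils::modifyList(
    list(scenario = scenario, n_dams = 36L, n_sires = 6L,
         n_founders = 100L, burn_in_years = 2L, eval_years = 2L,
         n_chr = 2L, sites_per_chr = 120L,
         loci_counts = c(10L, 50L, 50L),
         sire_window = c(2L, 10L),
         ea_control = list(mu = 10L, lambda = 30L,
                           generations = 30L, stagnation = 15L)),
    list(...))
  do.call(reduced_config, args)
}

test_that("conventional scheduler: counts, records and L are exact", {
  cfg <- tiny_cfg("PTS")
  res <- run_program(cfg, seed = 5)
  # one record per year, candidates = dams x family
  expect_identical(nrow(res$records), cfg$burn_in_years + cfg$eval_years)
  expect_true(all(res$records$time == 1:4))
  expect_true(all(res$records$n_candidates[-1] == 36 * 13))
  per_year <- table(res$ped$birth[res$ped$birth > 0])
  expect_true(all(per_year == 36 * 13))
  expect_equal(res$L, 1.0)
  expect_true(all(res$records$sires_used == 6))
})

test_that("genomic scheduler: two rounds a year, 0.75-year interval", {
  cfg <- tiny_cfg("GTS", eval_years = 3L)
  res <- run_program(cfg, seed = 5)
  ev <- res$records$time[res$records$time > cfg$burn_in_years]
  expect_equal(ev, seq(3, 5.5, by = 0.5))
  # two batches of candidates per year (28,080 at full scale)
  yr <- floor(ev)
  expect_true(all(table(yr) == 2))
  expect_equal(res$L, 0.75)
  # genomic scenarios never see a phenotype before availability:
  # records available at the last round <= records in store
  st <- res$state
  avail <- ocsim:::state_records_available(st, st$time)
  expect_true(all(avail$available_from <= st$time + 1e-9))
  expect_lt(nrow(avail), nrow(st$rec_df) + 1)
})

test_that("genotyping policy counts follow the stated caps", {
  # traced toy timeline via the exported policy function
  hist <- list()
  for (r in 1:6) hist[[r]] <- list(time = r, sires = r * 1e5 + 1:6,
                                   dams = r * 1e6 + 1:36)
  males <- 1:144
  # round 1 of the genomic phase: no genotyped prior parents
  expect_length(genotyping_policy(males, list(), 4, integer(0)), 144)
  # steady state: males + 4 rounds of (sires + dams)
  g <- genotyping_policy(males, hist, 4,
                         genotyped_pool = unlist(lapply(hist, function(h)
                           c(h$sires, h$dams))))
  expect_length(g, 144 + 4 * 42)
  # full-scale arithmetic of the caps
  expect_identical(4320 + 4 * (40 + 1080), 8800)
  expect_identical(4320 + 4 * (120 + 1080), 9120)
})

test_that("policy set size is reported by the genomic scheduler", {
  cfg <- tiny_cfg("GTS", eval_years = 4L)
  res <- run_program(cfg, seed = 7)
  ng <- res$records$n_genotyped[res$records$time > cfg$burn_in_years]
  cap <- 36 * 4 + 4 * (6 + 36)
  expect_equal(max(ng), cap)
  expect_true(all(diff(ng) >= 0))       # fills up, then saturates
  expect_true(all(ng <= cap))
})

test_that("scenarios share the burn-in and diverge only afterwards", {
  cfg1 <- tiny_cfg("GTS")
  cfg2 <- tiny_cfg("GTSMF")
  bi <- run_burnin(cfg1, seed = 9)
  r1 <- run_program(cfg1, seed = 9, burnin = bi)
  r2 <- run_program(cfg2, seed = 9, burnin = bi)
  t0 <- cfg1$burn_in_years
  b1 <- r1$records[r1$records$time <= t0, ]
  b2 <- r2$records[r2$records$time <= t0, ]
  expect_equal(b1, b2)
  # pedigree identical through burn-in cohorts
  p1 <- r1$ped[r1$ped$birth <= t0, ]; p2 <- r2$ped[r2$ped$birth <= t0, ]
  expect_identical(p1, p2)
  # divergence after burn-in (min-inbreeding mating reshuffles pairs)
  a1 <- r1$ped[r1$ped$birth > t0 + 0.9, ]
  a2 <- r2$ped[r2$ped$birth > t0 + 0.9, ]
  expect_false(identical(a1$sire, a2$sire) && identical(a1$dam, a2$dam))
})

test_that("GTSMF with unrelated candidates reduces to a GTS-style plan", {
  # all-unrelated selected parents: any assignment has zero progeny F
  A <- diag(42); dimnames(A) <- list(1:42, 1:42)
  plan <- min_inbreeding_matings(1:6, 7:42, A, seed = 3)
  expect_equal(attr(plan, "mean_pair_coancestry"), 0)
  expect_true(all(table(plan$sire) == 6))
})

test_that("run_replicates derives seeds, combines records and summarizes", {
  cfg <- tiny_cfg("PTS")
  out <- run_replicates(cfg, n = 2, master_seed = 4)
  expect_identical(length(out$seeds), 2L)
  expect_false(out$seeds[1] == out$seeds[2])
  expect_true(all(out$summary$replicate == 1:2))
  expect_true(all(c("gain", "Ne_snp") %in% out$mean_sd$metric))
  expect_identical(nrow(out$records), 2L * nrow(out$records[
    out$records$replicate == 1, ]))
  # determinism of the whole pipeline
  out2 <- run_replicates(cfg, n = 2, master_seed = 4)
  expect_equal(out$summary$gain, out2$summary$gain)
})

test_that("config files round-trip, reject unknown keys, default when empty", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario: GTS", "n_sires: 40", "n_dams: 1080",
               "scale: full"), path)
  cfg <- load_config(path)
  expect_identical(cfg$scenario, "GTS")
  expect_identical(cfg$n_sires, 40L)
  expect_identical(cfg$n_chr, 39L)       # full-scale genome defaults
  writeLines("typo_key: 3", path)
  expect_error(load_config(path), "typo_key")
  writeLines(character(0), path)
  cfg0 <- load_config(path)
  expect_identical(cfg0$n_dams, 108L)    # reduced defaults
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"scenario": "GOCS", "degrees": 65, "scale": "reduced"}', jpath)
  cfgj <- load_config(jpath)
  expect_identical(cfgj$scenario, "GOCS")
  expect_equal(cfgj$degrees, 65)
  expect_identical(cfgj$n_dams, 108L)
  # manifest is valid JSON and reproducible metadata
  mpath <- withr::local_tempfile(fileext = ".json")
  write_manifest(mpath, cfgj, 4, c(11L, 12L))
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  expect_identical(m$master_seed, 4L)
  expect_identical(m$config$scenario, "GOCS")
})
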