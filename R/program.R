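#' Scenario configuration
#'
#' Assembles and validates the configuration of one breeding scenario.
#' Scenarios: `PTS` (conventional truncation on pedigree BLUP, one round a
#' year), `GTS` (genomic truncation on ssGBLUP, two rounds a year), `GTSMF`
#' (GTS plus minimum-progeny-inbreeding mate allocation), `GOCS` (genomic
#' optimal contributions at a fixed sire count), `UGOCS` (free sire count
#' within a window), and `RANDOM` (random index; negative control used to
#' validate Ne estimates). Burn-in is always conventional truncation with
#' the scenario's sire count.
#'
#' @param scenario one of PTS, GTS, GTSMF, GOCS, UGOCS, RANDOM.
#' @param n_sires sires per round (40 or 120 at full scale).
#' @param degrees trigonometric penalty degrees (GOCS/UGOCS only).
#' @param n_dams dams per round.
#' @param family offspring per dam by sex, `c(F = 9, M = 4)`.
#' @param n_founders base-population size.
#' @param burn_in_years,eval_years phase lengths in years.
#' @param n_chr,sites_per_chr,loci_counts genome scale (QTL/SNP/neutral per
#'   chromosome).
#' @param generations_back genotyping policy depth (selection rounds).
#' @param t3_lag years between dam selection and the late-production record
#'   entering the data.
#' @param sire_window allowed sire-count range for UGOCS.
#' @param schedule `"conventional"` or `"genomic"`; defaults by scenario
#'   (RANDOM defaults to conventional so its Ne validates against Wright's
#'   discrete-generation formula, but can be run on the genomic schedule).
#' @param ea_control evolutionary-algorithm control overrides.
#' @param genomic_eval set `FALSE` to skip breeding-value estimation (only
#'   sensible for RANDOM).
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("PTS", "GTS", "GTSMF", "GOCS",
                                         "UGOCS", "RANDOM"),
                            n_sires = 120L, degrees = 45,
                            n_dams = 1080L, family = c(F = 9L, M = 4L),
                            n_founders = 2500L,
                            burn_in_years = 10L, eval_years = 20L,
                            n_chr = 39L, sites_per_chr = 2250L,
                            loci_counts = c(250L, 1000L, 1000L),
                            generations_back = 4L, t3_lag = 1,
                            sire_window = c(20L, 200L),
                            schedule = NULL, ea_control = list(),
                            genomic_eval = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(schedule)) {
    schedule <- if (scenario %in% c("PTS", "RANDOM")) "conventional"
    else "genomic"
  }
  schedule <- match.arg(schedule, c("conventional", "genomic"))
  if (is.null(genomic_eval)) genomic_eval <- scenario != "RANDOM"
  if (n_dams %% n_sires != 0 && scenario %in% c("PTS", "GTS", "GTSMF")) {
    stopf("n_dams (%d) must be a multiple of n_sires (%d) for equal quotas",
          n_dams, n_sires)
  }
  stopifnot(sum(loci_counts) <= sites_per_chr, n_founders >= 2,
            degrees >= 0, degrees <= 90, length(family) == 2)
  structure(list(scenario = scenario, schedule = schedule,
                 n_sires = as.integer(n_sires), degrees = degrees,
                 n_dams = as.integer(n_dams),
                 family = c(F = as.integer(family[["F"]]),
                            M = as.integer(family[["M"]])),
                 n_founders = as.integer(n_founders),
                 burn_in_years = as.integer(burn_in_years),
                 eval_years = as.integer(eval_years),
                 n_chr = as.integer(n_chr),
                 sites_per_chr = as.integer(sites_per_chr),
                 loci_counts = as.integer(loci_counts),
                 generations_back = as.integer(generations_back),
                 t3_lag = t3_lag, sire_window = as.integer(sire_window),
                 ea_control = ea_control, genomic_eval = genomic_eval),
            class = "scenario_config")
}

#' Reduced-scale configuration preset
#'
#' Proportional shrink used by the test-scale scenario comparisons:
#' 5 chromosomes with 750 retained sites each (75 QTL + 300 SNP + 300
#' neutral; 30 percent of the full per-chromosome density, a compute-budget
#' compromise), 108 dams, 12 sires (keeping the 1:9 ratio), 250 founders,
#' 5 burn-in and 10 evaluation years.
#'
#' @param ... overrides passed to [scenario_config()].
#' @export
reduced_config <- function(...) {
  args <- utils::modifyList(
    list(n_sires = 12L, n_dams = 108L, n_founders = 250L,
         burn_in_years = 5L, eval_years = 10L,
         n_chr = 5L, sites_per_chr = 750L,
         loci_counts = c(75L, 300L, 300L),
         sire_window = c(6L, 20L),
         ea_control = list(mu = 20L, lambda = 60L, generations = 80L,
                           stagnation = 30L)),
    list(...))
  do.call(scenario_config, args)
}

# ---- population state -----------------------------------------------------

new_state <- function(cfg, seed) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$map <- genome_map(n_chromosomes = cfg$n_chr)
  demog <- demography()
  founders <- simulate_founders(st$map, demog, cfg$n_founders,
                                sites_per_chr = cfg$sites_per_chr,
                                seed = derive_seed(seed, "founders"))
  st$partition <- partition_loci(founders, cfg$loci_counts,
                                 seed = derive_seed(seed, "partition"))
  st$arch <- sample_effects(st$partition, founders,
                            seed = derive_seed(seed, "effects"))
  set.seed(derive_seed(seed, "sex"))
  sex <- sample(rep(c("F", "M"), length.out = cfg$n_founders))
  st$ped <- founder_pedigree(founders$ids, sex, birth = 0)
  st$tbv <- true_genetic_values(founders, st$partition, st$arch)
  st$live <- founders             # haplotypes of recent cohorts
  st$live_birth <- rep(0, cfg$n_founders)
  st$rec_df <- NULL
  st$bank <- NULL                 # SNP dosages of genotyped animals
  st$sel_history <- list()        # per selection round: sires, dams, time
  st$year_records <- list()
  st$next_id <- cfg$n_founders + 1L
  st$time <- 0
  st$seed <- seed
  st
}

clone_state <- function(st) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(st)) assign(nm, get(nm, envir = st), envir = out)
  out
}

state_add_records <- function(st, new) {
  if (is.null(st$rec_df)) st$rec_df <- new
  else st$rec_df <- rbind(st$rec_df, new)
  invisible(st)
}

state_records_available <- function(st, time) {
  if (is.null(st$rec_df)) {
    return(data.frame(animal = integer(), trait = integer(),
                      value = numeric(), available_from = numeric()))
  }
  st$rec_df[st$rec_df$available_from <= time + 1e-9, , drop = FALSE]
}

cohort_ids <- function(st, birth, sex = NULL) {
  k <- abs(st$ped$birth - birth) < 1e-9
  if (!is.null(sex)) k <- k & st$ped$sex == sex
  st$ped$id[k]
}

# youngest cohort of a sex with age >= min_age at `time` (transition fallback)
candidate_cohort <- function(st, time, sex, min_age) {
  births <- unique(st$ped$birth[st$ped$sex == sex])
  ok <- births[time - births >= min_age - 1e-9]
  if (!length(ok)) stopf("no %s cohort of age >= %s at time %s",
                         sex, min_age, time)
  cohort_ids(st, max(ok), sex)
}

#' Genotyping policy
#'
#' The genotyped set passed to one genomic evaluation: the current male
#' selection candidates plus the selected sires and dams of the previous
#' `generations_back` selection rounds. At steady state this caps at
#' 4,320 + 4 x (n_sires + 1,080): 8,800 genotypes in the 40-sire programme
#' and 9,120 in the 120-sire programme.
#'
#' @param male_candidates ids of the current male candidates.
#' @param sel_history list of past selection rounds (`sires`, `dams`).
#' @param generations_back number of past rounds whose parents remain in
#'   the reference.
#' @param genotyped_pool ids for which genotypes exist (past parents without
#'   a genotype -- e.g. burn-in parents at the transition -- are dropped);
#'   `NULL` keeps everyone.
#' @return integer vector of genotyped ids.
#' @export
genotyping_policy <- function(male_candidates, sel_history,
                              generations_back = 4L,
                              genotyped_pool = NULL) {
  past <- tail(sel_history, generations_back)
  prior <- unique(unlist(lapply(past, function(h) c(h$sires, h$dams))))
  if (!is.null(genotyped_pool)) prior <- intersect(prior, genotyped_pool)
  unique(c(male_candidates, prior))
}

# add animals' SNP dosages to the genotype bank (no-op for known ids)
bank_add <- function(st, ids) {
  ids <- setdiff(ids, as.integer(rownames(st$bank)))
  if (!length(ids)) return(invisible())
  g <- dosages(st$live, st$partition$snp, ids)
  st$bank <- rbind(st$bank, g)
  invisible()
}

# ---- one selection round --------------------------------------------------

run_round <- function(st, time, genomic) {
  cfg <- st$cfg
  dam_cand <- candidate_cohort(st, time, "F", 1)
  sire_cand <- if (genomic) candidate_cohort(st, time, "M", 0.5)
  else candidate_cohort(st, time, "M", 1)
  cand <- c(dam_cand, sire_cand)
  n_genotyped <- 0L
  # the pedigree has not changed since the end of the previous round
  Fpre <- if (!is.null(st$Fped) && length(st$Fped) == nrow(st$ped)) st$Fped
  else inbreeding_meuwissen_luo(st$ped)
  # breeding-value estimation
  rec <- state_records_available(st, time)
  random_index <- cfg$scenario == "RANDOM" || nrow(rec) == 0 ||
    !cfg$genomic_eval
  if (random_index) {
    set.seed(derive_seed(st$seed, "randidx", round(time * 2)))
    idx <- stats::setNames(runif(nrow(st$ped)), as.character(st$ped$id))
    if (genomic) {
      bank_add(st, sire_cand)
      gset <- genotyping_policy(sire_cand, st$sel_history,
                                cfg$generations_back,
                                as.integer(rownames(st$bank)))
      n_genotyped <- length(gset)
    }
    acc <- NA_real_
  } else {
    geno <- NULL
    if (genomic) {
      bank_add(st, sire_cand)
      gset <- genotyping_policy(sire_cand, st$sel_history,
                                cfg$generations_back,
                                as.integer(rownames(st$bank)))
      n_genotyped <- length(gset)
      geno <- st$bank[as.character(gset), , drop = FALSE]
    }
    # exact pruning: animals outside the ancestor closure of the data and
    # candidate sets carry no information for this evaluation
    need <- unique(c(rec$animal, cand, if (genomic) gset))
    ped_mme <- pedigree_closure(st$ped, need)
    F_mme <- unname(Fpre[as.character(ped_mme$id)])
    ebv <- solve_mme(ped_mme, rec, st$arch, geno = geno, F = F_mme)
    idx <- stats::setNames(ebv$index, as.character(ebv$id))
    tbv_idx <- drop(st$tbv[as.character(cand), ] %*% st$arch$index_weights)
    acc <- accuracy(idx[as.character(cand)], tbv_idx)
  }
  # selection
  sex <- stats::setNames(st$ped$sex, as.character(st$ped$id))
  sel_f <- truncation_select(cand, sex[as.character(cand)],
                             idx[as.character(cand)],
                             n_females = cfg$n_dams, n_males = 0)$females
  scen <- cfg$scenario
  seed_r <- derive_seed(st$seed, "round", round(time * 2))
  if (scen %in% c("PTS", "GTS", "RANDOM")) {
    sires <- truncation_select(cand, sex[as.character(cand)],
                               idx[as.character(cand)],
                               n_females = 0, n_males = cfg$n_sires)$males
    plan <- random_mating(sires, sel_f, seed = seed_r)
  } else if (scen == "GTSMF") {
    sires <- truncation_select(cand, sex[as.character(cand)],
                               idx[as.character(cand)],
                               n_females = 0, n_males = cfg$n_sires)$males
    sel_ids <- c(sires, sel_f)
    pc <- pedigree_closure(st$ped, sel_ids)
    Asel <- A_submatrix(pc, sel_ids, sel_ids,
                        F = unname(Fpre[as.character(pc$id)]))
    plan <- min_inbreeding_matings(sires, sel_f, Asel, seed = seed_r)
  } else { # GOCS / UGOCS
    cand_ids <- c(sire_cand, sel_f)
    pc <- pedigree_closure(st$ped, cand_ids)
    Ac <- A_submatrix(pc, cand_ids, cand_ids,
                      F = unname(Fpre[as.character(pc$id)]))
    prob <- ocs_problem(sire_cand, sel_f, idx, Ac,
                        n_sires = if (scen == "GOCS") cfg$n_sires else NULL,
                        sire_window = cfg$sire_window)
    sol <- solve_ocs(prob, cfg$degrees, seed = seed_r,
                     control = cfg$ea_control)
    plan <- counts_to_matings(sol$counts, sel_f, seed = seed_r)
    sires <- unique(plan$sire)
  }
  st$sel_history <- c(st$sel_history, list(list(time = time, sires = sires,
                                                dams = sel_f)))
  if (genomic) bank_add(st, sel_f)
  # late egg production for the selected dams
  state_add_records(st,
    record_t3(st$tbv[as.character(sel_f), , drop = FALSE], st$arch,
              selection_time = time, t3_lag = cfg$t3_lag,
              seed = derive_seed(st$seed, "t3", round(time * 2))))
  # offspring
  off <- make_offspring(st$live, plan, n_female = cfg$family[["F"]],
                        n_male = cfg$family[["M"]], birth_time = time,
                        start_id = st$next_id,
                        seed = derive_seed(st$seed, "off", round(time * 2)))
  st$next_id <- st$next_id + nrow(off$pedigree)
  st$ped <- rbind(st$ped, off$pedigree)
  tbv_off <- true_genetic_values(off$pop, st$partition, st$arch)
  st$tbv <- rbind(st$tbv, tbv_off)
  state_add_records(st,
    simulate_phenotypes(tbv_off, st$arch, off$pedigree$sex,
                        off$pedigree$birth, candidate_time = time + 1,
                        seed = derive_seed(st$seed, "ph", round(time * 2))))
  # cohort bookkeeping and pruning
  # parents of the next rounds are at most half a year (genomic) or one
  # round (conventional) older than the newest cohort: keep two cohorts
  st$live <- hap_bind(st$live, off$pop)
  st$live_birth <- c(st$live_birth, rep(time, length(off$pop$ids)))
  births <- sort(unique(st$live_birth), decreasing = TRUE)
  keep <- st$live_birth >= births[min(2L, length(births))]
  if (!all(keep)) {
    st$live <- hap_subset(st$live, st$live$ids[keep])
    st$live_birth <- st$live_birth[keep]
  }
  # year record for the newborn cohort (one dosage pass over all loci)
  Fped <- inbreeding_meuwissen_luo(st$ped)
  st$Fped <- Fped
  coh <- off$pop$ids
  tbv_i <- drop(tbv_off %*% st$arch$index_weights)
  d_all <- dosages(off$pop)
  nl <- vapply(off$pop$haplo, ncol, integer(1))
  offset <- c(0L, cumsum(nl))[seq_along(nl)]
  class_cols <- function(idx_list)
    unlist(lapply(seq_along(idx_list), function(chr) idx_list[[chr]] +
                    offset[chr]), use.names = FALSE)
  qc <- class_cols(st$partition$qtl)
  sc <- class_cols(st$partition$snp)
  nc <- class_cols(st$partition$neutral)
  qfreq <- colMeans(d_all[, qc, drop = FALSE]) / 2
  gv <- genic_variance(qfreq, st$arch$effects, st$arch$index_weights)
  rec_row <- data.frame(
    time = time,
    mean_tbv = mean(tbv_i), sd_tbv = stats::sd(tbv_i),
    genic_sd_index = sqrt(gv[["index"]]),
    genic_sd_T1 = sqrt(gv[["T1"]]), genic_sd_T2 = sqrt(gv[["T2"]]),
    genic_sd_T3 = sqrt(gv[["T3"]]),
    ho_qtl = mean(d_all[, qc, drop = FALSE] == 1L),
    ho_snp = mean(d_all[, sc, drop = FALSE] == 1L),
    ho_neutral = mean(d_all[, nc, drop = FALSE] == 1L),
    mean_F_ped = mean(Fped[as.character(coh)]),
    accuracy = acc, sires_used = length(sires),
    n_genotyped = n_genotyped, n_candidates = length(cand))
  st$year_records <- c(st$year_records, list(rec_row))
  st$time <- time
  invisible(st)
}

#' Run one conventional year
#'
#' One evaluation (pedigree BLUP), truncation selection of 1,080 dams and
#' the scenario's sires, random equal-contribution mating, and one new
#' candidate cohort; generation-interval contribution 1.0 years.
#'
#' @param st population state.
#' @param time the integer year.
#' @export
run_year_conventional <- function(st, time) run_round(st, time, genomic = FALSE)

#' Run one genomic year (two selection rounds)
#'
#' Rounds at `time` and `time + 0.5`. Sires are selected among half-year-old
#' genotyped males without own phenotypes, dams among one-year-old females
#' with early/mid records, which realizes the 0.75-year generation interval.
#'
#' @param st population state.
#' @param time the integer year.
#' @export
run_year_genomic <- function(st, time) {
  run_round(st, time, genomic = TRUE)
  run_round(st, time + 0.5, genomic = TRUE)
  invisible(st)
}

#' Run the burn-in phase
#'
#' Conventional truncation selection years 1..burn_in (the first year
#' selects at random because no phenotypes exist yet). The burn-in depends
#' only on the replicate seed and the sire count, so scenarios sharing a
#' seed share the burn-in exactly.
#'
#' @param cfg a [scenario_config()].
#' @param seed replicate seed.
#' @return a population state at the end of year `burn_in_years`.
#' @export
run_burnin <- function(cfg, seed) {
  bcfg <- cfg
  bcfg$scenario <- "PTS"; bcfg$schedule <- "conventional"
  bcfg$genomic_eval <- TRUE
  st <- new_state(bcfg, seed)
  for (t in seq_len(cfg$burn_in_years)) run_year_conventional(st, t)
  st
}

#' Run a complete breeding programme
#'
#' Burn-in (shared across scenarios given the same seed) followed by the
#' scenario's evaluation phase. Supply `burnin` to reuse a precomputed
#' burn-in state.
#'
#' @param cfg a [scenario_config()].
#' @param seed replicate seed.
#' @param burnin optional state returned by [run_burnin()] (left untouched).
#' @return list with `records` (one row per time point), `ped`, `L`
#'   (steady-state generation interval of the evaluation phase), `cfg`, and
#'   the final `state`.
#' @export
run_program <- function(cfg, seed, burnin = NULL) {
  st <- if (is.null(burnin)) run_burnin(cfg, seed) else clone_state(burnin)
  st$cfg <- cfg
  t0 <- cfg$burn_in_years
  if (cfg$schedule == "genomic") {
    for (t in t0 + seq_len(cfg$eval_years)) run_year_genomic(st, t)
  } else {
    for (t in t0 + seq_len(cfg$eval_years)) run_year_conventional(st, t)
  }
  records <- do.call(rbind, st$year_records)
  rownames(records) <- NULL
  # steady-state generation interval (transition year excluded)
  ev <- st$ped[st$ped$birth > t0 + 1.5 + 1e-9, , drop = FALSE]
  L <- if (nrow(ev)) as.numeric(generation_interval(st$ped, ev$id))
  else NA_real_
  list(records = records, ped = st$ped, L = L, cfg = cfg, state = st)
}
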