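#' Normalize a results series to the last burn-in year
#'
#' Applies the affine map that sets the mean genetic value of the reference
#' year (year 10 at full scale) to 0 and its standard deviation to 1; genic
#' standard deviations are scaled by the same factor. All reported gains are
#' therefore in units of year-10 genetic standard deviations.
#'
#' @param records data.frame of year records with columns `time`,
#'   `mean_tbv`, `sd_tbv`, and optionally `genic_sd_*` columns.
#' @param ref_year reference time point.
#' @return the records with columns `gain` (normalized mean) and scaled
#'   `genic_sd_*` columns.
#' @export
normalize_to_burnin <- function(records, ref_year = 10) {
  r <- records[records$time == ref_year, , drop = FALSE]
  if (nrow(r) != 1L) stopf("no unique record at reference year %s", ref_year)
  mu <- r$mean_tbv; s <- r$sd_tbv
  if (!is.finite(s) || s <= 0) stopf("zero SD at reference year")
  out <- records
  out$gain <- (records$mean_tbv - mu) / s
  for (cl in grep("^genic_sd", names(records), value = TRUE)) {
    out[[cl]] <- records[[cl]] / s
  }
  out
}

#' Conversion efficiency
#'
#' Ordinary least-squares slope of achieved genetic gain on lost genic
#' standard deviation (reference minus current): the genetic gain that
#' would be achieved if all the genic variance were consumed.
#'
#' @param gain normalized genetic gain per time point.
#' @param genic_sd genic standard deviation per time point (same scale).
#' @param ref_genic_sd genic SD at the reference time (default: first
#'   element).
#' @return the slope (a single number).
#' @export
conversion_efficiency <- function(gain, genic_sd, ref_genic_sd = genic_sd[1]) {
  lost <- ref_genic_sd - genic_sd
  if (length(unique(lost)) < 2) stopf("no variation in lost genic SD")
  unname(coef(stats::lm(gain ~ lost))[2])
}

#' Extrapolate gain to a stated fraction of genic variance lost
#'
#' @param slope conversion efficiency.
#' @param fraction fraction of genic variance lost (0.5 or 1).
#' @param ref_genic_sd genic SD at the reference point.
#' @return projected gain when that fraction of the genic variance is gone.
#' @export
extrapolate_gain <- function(slope, fraction, ref_genic_sd = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  slope * ref_genic_sd * (1 - sqrt(1 - fraction))
}

#' Genomic inbreeding from observed heterozygosity
#'
#' `F_t = 1 - Ho_t / Ho_ref`, with the conventional choice `Ho_ref = 1`
#' giving the raw `F_t = 1 - Ho_t` used in the reported series; computed
#' separately per loci class by the caller.
#'
#' @param ho vector of average observed heterozygosities per time point.
#' @export
inbreeding_from_heterozygosity <- function(ho) 1 - ho

#' Rate of inbreeding from an inbreeding series
#'
#' `dF = 1 - exp(beta)` where `beta` is the OLS coefficient of
#' `log(1 - F_t)` on time. The per-generation rate compounds the per-year
#' rate by the generation interval: `dF_gen = 1 - (1 - dF_year)^L`.
#'
#' @param F_t inbreeding coefficients per time point (all < 1).
#' @param time time points (years).
#' @return dF per unit of `time`.
#' @export
rate_of_inbreeding <- function(F_t, time = seq_along(F_t)) {
  if (any(F_t >= 1)) stopf("F = 1 in input: log(1 - F) undefined")
  beta <- unname(coef(stats::lm(log(1 - F_t) ~ time))[2])
  1 - exp(beta)
}

#' @rdname rate_of_inbreeding
#' @param dF_year per-year rate of inbreeding.
#' @param L generation interval in years.
#' @export
rate_per_generation <- function(dF_year, L) 1 - (1 - dF_year)^L

#' Effective population size
#'
#' `Ne = 1/(2 L dF_year)`; reported as missing when `dF_year <= 0`.
#'
#' @param dF_year per-year rate of inbreeding.
#' @param L generation interval in years.
#' @export
effective_population_size <- function(dF_year, L) {
  if (is.na(dF_year) || dF_year <= 0) return(NA_real_)
  1 / (2 * L * dF_year)
}

#' Wright's effective population size from parent counts
#'
#' `Ne = 4 Nm Nf / (Nm + Nf)`: 154 for 40 sires x 1,080 dams and 432 for
#' 120 sires (rounded to integers as reported).
#'
#' @param n_males,n_females numbers of sires and dams.
#' @export
wright_ne <- function(n_males, n_females) {
  stopifnot(n_males > 0, n_females > 0)
  4 * n_males * n_females / (n_males + n_females)
}

#' Generation interval from a pedigree
#'
#' Mean over both parents of offspring birth time minus parent birth time;
#' offspring with unknown parents are excluded (their count is attached as
#' an attribute). 1.00 years for the conventional scheduler, 0.75 for the
#' genomic schedulers at steady state.
#'
#' @param ped pedigree data.frame with `id, sire, dam, birth`.
#' @param offspring optional subset of offspring ids to average over.
#' @export
generation_interval <- function(ped, offspring = NULL) {
  p <- ped
  if (!is.null(offspring)) p <- ped[ped$id %in% offspring, , drop = FALSE]
  known <- p$sire != 0 & p$dam != 0
  bt <- ped$birth; names(bt) <- as.character(ped$id)
  ps <- bt[as.character(p$sire[known])]
  pd <- bt[as.character(p$dam[known])]
  L <- mean(c(p$birth[known] - ps, p$birth[known] - pd))
  attr(L, "excluded") <- sum(!known)
  L
}

#' Percentage change
#'
#' `((new - base)/base) * 100`.
#' @param new,base the two values (base nonzero).
#' @export
percentage_change <- function(new, base) {
  if (any(base == 0)) stopf("base value is zero")
  (new - base) / base * 100
}
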