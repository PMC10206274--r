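#' Genome map
#'
#' Describes the simulated genome: equally sized autosomes with a constant
#' recombination rate, so genetic position is physical position times the
#' recombination rate. Defaults follow the layer-chicken setting used
#' throughout the package: 39 autosomes, 30 Morgans and 1.2 Gb in total,
#' recombination rate 2.5e-8 per bp and mutation rate 5e-8 per bp (the
#' latter acts only in the base-population coalescent; later meioses are
#' mutation-free).
#'
#' @param n_chromosomes number of autosomes.
#' @param total_genetic_length_M total genetic map length in Morgans.
#' @param total_physical_length_bp total physical length in base pairs.
#' @param recombination_rate per-bp per-meiosis recombination rate.
#' @param mutation_rate per-bp per-generation mutation rate (base population
#'   only).
#' @return an object of class `genome_map`.
#' @export
genome_map <- function(n_chromosomes = 39,
                       total_genetic_length_M = 30,
                       total_physical_length_bp = 1.2e9,
                       recombination_rate = 2.5e-8,
                       mutation_rate = 5.0e-8) {
  stopifnot(n_chromosomes >= 1, total_genetic_length_M > 0,
            total_physical_length_bp > 0)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chr_length_M = total_genetic_length_M / n_chromosomes,
    chr_length_bp = total_physical_length_bp / n_chromosomes,
    recombination_rate = recombination_rate,
    mutation_rate = mutation_rate
  ), class = "genome_map")
}

#' Piecewise-constant demography
#'
#' The published demography states only the endpoints: a recent effective
#' size of 100 decreasing gradually from 500,000 at about one million
#' generations ago. The schedule in between is not printed, so the default
#' interpolates log-linearly through the anchor grid
#' \{0: 100, 1e4: 1e3, 1e5: 1e4, 1e6: 5e5\} and discretises each interval
#' into `steps_per_interval` constant-size epochs (geometric interpolation
#' in both time and size). The anchors stay configurable.
#'
#' @param anchors data.frame with columns `generations_ago` (non-decreasing,
#'   starting at 0) and `Ne` (positive).
#' @param steps_per_interval number of constant epochs per anchor interval.
#' @return object of class `demography` with epoch start times and sizes.
#' @export
demography <- function(anchors = NULL, steps_per_interval = 6L) {
  if (is.null(anchors)) {
    anchors <- data.frame(generations_ago = c(0, 1e4, 1e5, 1e6),
                          Ne = c(100, 1e3, 1e4, 5e5))
  }
  stopifnot(is.data.frame(anchors),
            all(c("generations_ago", "Ne") %in% names(anchors)),
            !is.unsorted(anchors$generations_ago),
            all(anchors$Ne > 0), anchors$generations_ago[1] == 0)
  if (nrow(anchors) == 1L) {
    ep <- data.frame(start = 0, Ne = anchors$Ne[1])
  } else {
    starts <- 0; sizes <- anchors$Ne[1]
    for (k in seq_len(nrow(anchors) - 1L)) {
      t0 <- max(anchors$generations_ago[k], 1)
      t1 <- anchors$generations_ago[k + 1L]
      tt <- exp(seq(log(t0), log(t1), length.out = steps_per_interval + 1L))
      tt <- tt[-length(tt)]
      nn <- exp(seq(log(anchors$Ne[k]), log(anchors$Ne[k + 1L]),
                    length.out = steps_per_interval + 1L))[-(steps_per_interval + 1L)]
      keep <- tt > max(starts)
      starts <- c(starts, tt[keep]); sizes <- c(sizes, nn[keep])
    }
    starts <- c(starts, anchors$generations_ago[nrow(anchors)])
    sizes <- c(sizes, anchors$Ne[nrow(anchors)])
    ep <- data.frame(start = starts, Ne = sizes)
  }
  structure(list(epoch_start = ep$start, epoch_Ne = ep$Ne, anchors = anchors),
            class = "demography")
}

#' Single-epoch demography of constant size
#' @param Ne constant diploid effective size.
#' @export
constant_demography <- function(Ne) {
  demography(data.frame(generations_ago = 0, Ne = Ne))
}
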