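#' Derive a child seed from a master seed and a stage label
#'
#' Counter-based scheme: every stochastic stage of a run draws its own seed
#' from the run's master seed plus a human-readable label, so replicates and
#' stages are independent and reruns are bit-reproducible. Result is kept
#' below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... further labels (strings or integers), e.g. replicate index,
#'   stage name, time point.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer((h + as.numeric(master) * 2654435761) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
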