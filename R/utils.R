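#' Derive a reproducible child seed from a master seed
#'
#' All randomized stages take an explicit integer seed. Hierarchical
#' sub-seeds (per patient, per repetition, per bootstrap replicate) are
#' derived from the master seed with a multiplicative hash so that, for
#' example, patient i's record stream does not depend on how many other
#' patients are generated.
#'
#' @param seed master integer seed.
#' @param ... one or more non-negative integer indices naming the stream.
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1L, all(idx >= 0))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (i in idx) {
    # 48271 is the MINSTD multiplier; keeps everything in exact doubles
    h <- (h * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(h)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' @noRd
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

`%||%` <- function(a, b) if (is.null(a)) b else a
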