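# Internal helpers shared across modules.

#' Derive a reproducible integer seed from a root seed and string labels
#'
#' A stable polynomial rolling hash over the concatenated labels, reduced
#' modulo 2^31 - 1. Used to give every bird/rendition/operation its own RNG
#' stream so that adding items to a dataset does not perturb existing ones.
#'
#' @param root integer root seed.
#' @param ... character or numeric labels identifying the stream.
#' @return a single integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(root, ...) {
  s <- paste(c(as.character(root), vapply(list(...), as.character, "")),
             collapse = "/")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rms <- function(x) sqrt(mean(x^2))

# Sample skewness / excess-free kurtosis (plain moment estimators; constant
# input yields 0 skewness by convention here so degenerate windows stay finite).
moment_skew <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}
moment_kurt <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^4) / s^4
}

#' Smoothed amplitude envelope of a waveform
#'
#' Rectifies the signal and applies a moving-average window. Used both when
#' gating inter-syllable silence and when examining envelope-level
#' time-irreversibility of synthetic motifs.
#'
#' @param x numeric samples.
#' @param rate_hz sampling rate in Hz.
#' @param smooth_ms moving-average window in milliseconds.
#' @return numeric vector, same length as `x`.
#' @export
amplitude_envelope <- function(x, rate_hz, smooth_ms = 5) {
  n <- max(1L, as.integer(round(smooth_ms / 1000 * rate_hz)))
  e <- abs(x)
  if (n > 1) {
    k <- rep(1 / n, n)
    e <- as.numeric(stats::filter(e, k, sides = 2))
    # moving average leaves NA at the edges; pad with nearest valid value
    idx <- which(!is.na(e))
    e[seq_len(idx[1] - 1)] <- e[idx[1]]
    e[seq.int(idx[length(idx)] + 1L, length.out = length(e) - idx[length(idx)])] <- e[idx[length(idx)]]
  }
  e
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop2 <- function(...) stop(..., call. = FALSE)
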