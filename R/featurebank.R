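# Time-series feature bank, part 1: waveform preprocessing, time
# irreversibility, autocorrelation, automutual information, spectral
# summaries, symbolic dynamics and permutation entropy.
#
# Degenerate inputs (constant series, zero denominators) yield NA_real_
# ("invalid markers") rather than errors, so that matrix-level filtering can
# drop the affected feature columns.

#' Preprocess a motif waveform
#'
#' Band-pass filters (2-pole Butterworth, forward only), optionally gates
#' inter-syllable silence with cosine edge ramps, and rescales to a target
#' RMS level.
#'
#' @param w a `motif_wav`.
#' @param band_hz two-element band edges in Hz, inside (0, rate/2).
#' @param target_rms_db target RMS in dB relative to full scale.
#' @param ramp_ms cosine ramp length at gated-segment edges (ms).
#' @param silence_gate zero out inter-syllable segments whose envelope falls
#'   below -35 dB of the envelope peak.
#' @return a preprocessed `motif_wav`.
#' @export
preprocess_waveform <- function(w, band_hz = c(250, 8000),
                                target_rms_db = -20, ramp_ms = 2,
                                silence_gate = FALSE) {
  stopifnot(inherits(w, "motif_wav"))
  nyq <- w$rate_hz / 2
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] >= nyq ||
      band_hz[1] >= band_hz[2])
    stop2("band corners must satisfy 0 < lo < hi < Nyquist")
  x <- w$samples
  if (all(x == 0)) stop2("degenerate all-zero waveform")
  bf <- signal::butter(1, band_hz / nyq, type = "pass")   # 2 poles total
  x <- as.numeric(signal::filter(bf, x))
  if (silence_gate) {
    env <- amplitude_envelope(x, w$rate_hz, smooth_ms = 5)
    keep <- env >= max(env) * 10^(-35 / 20)
    nr <- max(1L, as.integer(round(ramp_ms / 1000 * w$rate_hz)))
    gain <- as.numeric(keep)
    ramp_up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    # cosine fade-in/fade-out at the edges of every retained segment
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      L <- min(nr, (ends[i] - starts[i] + 1L) %/% 2L)
      if (L >= 1) {
        gain[starts[i] + seq_len(L) - 1L] <- ramp_up[seq_len(L)]
        gain[ends[i] - seq_len(L) + 1L] <- ramp_up[seq_len(L)]
      }
    }
    x <- x * gain
  }
  r <- rms(x)
  if (r == 0) stop2("silence-only waveform after gating")
  x <- x * (10^(target_rms_db / 20) / r)
  motif_waveform(x, w$rate_hz, w$bird_id, w$context, w$role, w$rendition_id)
}

# per-motif memoization used by extract_all so that shared intermediates
# (acf, quantile symbolizations) are computed once per motif
cache_get <- function(cache, key, compute) {
  if (is.null(cache)) return(compute())
  if (!exists(key, envir = cache, inherits = FALSE))
    assign(key, compute(), envir = cache)
  get(key, envir = cache, inherits = FALSE)
}

acf_vec <- function(x, max_lag, cache = NULL) {
  key <- paste0("acf", max_lag)
  cache_get(cache, key, function()
    as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf))
}

#' First zero crossing of the autocorrelation function
#'
#' @param x numeric series.
#' @param max_lag largest lag examined.
#' @param cache internal memoization environment (optional).
#' @return smallest lag with acf <= 0, or NA if none within `max_lag`.
#' @export
first_zero_acf <- function(x, max_lag = min(length(x) - 1L, 128L),
                           cache = NULL) {
  if (stats::sd(x) == 0) return(NA_real_)
  a <- acf_vec(x, max_lag, cache)[-1]
  i <- which(a <= 0)
  if (length(i) == 0) NA_real_ else as.numeric(i[1])
}

# equiprobable-quantile symbolization, memoized per (motif, n_bins)
symbols_of <- function(x, n_bins, cache = NULL) {
  cache_get(cache, paste0("sym", n_bins), function() {
    br <- stats::quantile(x, probs = seq_len(n_bins - 1) / n_bins,
                          names = FALSE)
    if (length(unique(br)) < n_bins - 1) return(NULL)
    findInterval(x, br) + 1L
  })
}

ami_from_symbols <- function(s, lag, n_bins) {
  n <- length(s)
  if (n - lag < 4 * n_bins) return(NA_real_)
  i1 <- s[seq_len(n - lag)]
  i2 <- s[seq.int(lag + 1L, n)]
  cnt <- tabulate(i1 + n_bins * (i2 - 1L), nbins = n_bins * n_bins)
  p <- cnt / sum(cnt)
  pi1 <- tabulate(i1, n_bins) / length(i1)
  pi2 <- tabulate(i2, n_bins) / length(i2)
  pe <- as.numeric(outer(pi1, pi2))
  nz <- p > 0 & pe > 0
  max(0, sum(p[nz] * log(p[nz] / pe[nz])))
}

# histogram (equiprobable-bin) automutual information in nats at one lag
ami_hist <- function(x, lag, n_bins = 8, cache = NULL) {
  s <- symbols_of(x, n_bins, cache)
  if (is.null(s)) return(NA_real_)
  ami_from_symbols(s, lag, n_bins)
}

#' First minimum of the automutual information function
#'
#' @param x numeric series.
#' @param max_lag largest lag examined.
#' @param n_bins histogram bins per margin.
#' @param cache internal memoization environment (optional).
#' @return smallest lag that is a local minimum of AMI, or NA.
#' @export
first_min_ami <- function(x, max_lag = 30, n_bins = 8, cache = NULL) {
  if (stats::sd(x) == 0) return(NA_real_)
  cache_get(cache, paste0("amimin", max_lag, "_", n_bins), function() {
    s <- symbols_of(x, n_bins, cache)
    if (is.null(s)) return(NA_real_)
    prev <- ami_from_symbols(s, 1, n_bins)
    if (is.na(prev)) return(NA_real_)
    before <- Inf
    best <- prev
    best_lag <- 1L
    for (lag in 2:max_lag) {
      cur <- ami_from_symbols(s, lag, n_bins)
      if (is.na(cur)) return(NA_real_)
      if (prev < before && prev < cur) return(as.numeric(lag - 1))
      if (cur < best) {
        best <- cur
        best_lag <- lag
      }
      before <- prev
      prev <- cur
    }
    # no local minimum inside the scan: fall back to the scanned argmin so
    # the data-driven lag stays defined for smoothly decaying AMI curves
    as.numeric(best_lag)
  })
}

#' Normalized third-order time-reversal asymmetry (CO_trev family)
#'
#' `mean((x[n-tau] - x[n])^3) / mean((x[n-tau] - x[n])^2)^(3/2)` over
#' `n = tau+1, ..., N`. Zero in expectation for time-reversible series; the
#' sign convention uses backward differences so that it shares directionality
#' with [dk_trev()].
#'
#' @param x numeric series.
#' @param tau positive integer lag, or `"acf_zero"` / `"ami_min"` to resolve
#'   the lag from the acf first zero crossing or the automutual-information
#'   first minimum.
#' @param cache internal memoization environment (optional).
#' @return a real value, or NA on degenerate input.
#' @export
co_trev <- function(x, tau = 1, cache = NULL) {
  if (is.character(tau)) {
    tau <- switch(match.arg(tau, c("acf_zero", "ami_min")),
                  acf_zero = first_zero_acf(x, cache = cache),
                  ami_min = first_min_ami(x, cache = cache))
    if (is.na(tau)) return(NA_real_)
  }
  tau <- as.integer(tau)
  n <- length(x)
  if (tau < 1 || n <= tau + 1) return(NA_real_)
  d <- x[seq_len(n - tau)] - x[seq.int(tau + 1L, n)]
  den <- mean(d^2)
  if (den == 0) return(NA_real_)
  mean(d^3) / den^1.5
}

#' Delay-embedding time-reversal asymmetry (DK_trev family)
#'
#' Builds the delay embedding with columns `(x_t, x_{t+tau}, x_{t+2 tau})`
#' for `t = 1, ..., N - (M-1) tau` and returns
#' `mean(a1 * a1 * a2 - a2 * a3 * a3)`.
#'
#' @param x numeric series.
#' @param tau positive integer lag.
#' @param M embedding dimension (3, the only supported value).
#' @return a real value, or NA when the series is too short.
#' @export
dk_trev <- function(x, tau = 1, M = 3) {
  stopifnot(M == 3)
  tau <- as.integer(tau)
  n <- length(x)
  nr <- n - (M - 1) * tau
  if (tau < 1 || nr < 1) return(NA_real_)
  a1 <- x[seq_len(nr)]
  a2 <- x[seq_len(nr) + tau]
  a3 <- x[seq_len(nr) + 2L * tau]
  mean(a1 * a1 * a2 - a2 * a3 * a3)
}

#' Autocorrelation features
#'
#' Biased-normalized autocorrelation (lag 0 equals 1) at the requested lags,
#' plus the first zero crossing.
#'
#' @param x numeric series.
#' @param lags integer lags.
#' @param max_lag cap for the zero-crossing scan.
#' @param cache internal memoization environment (optional).
#' @return named numeric: `acf_lag<l>` per lag and `acf_firstzero`.
#' @export
acf_features <- function(x, lags = c(1:10, 14, 21, 33),
                         max_lag = min(length(x) - 1L, 128L), cache = NULL) {
  out <- stats::setNames(rep(NA_real_, length(lags) + 1L),
                         c(paste0("acf_lag", lags), "acf_firstzero"))
  if (length(x) <= max(lags) || stats::sd(x) == 0) return(out)
  a <- acf_vec(x, max(max(lags), max_lag), cache)
  out[seq_along(lags)] <- a[lags + 1L]
  i <- which(a[-1] <= 0)
  out["acf_firstzero"] <- if (length(i)) as.numeric(i[1]) else NA_real_
  out
}

#' Automutual information features
#'
#' Histogram-estimated (equiprobable bins) automutual information in nats at
#' the given lags, the first-minimum lag, and the decay slope of lag-1 AMI
#' as Gaussian noise of increasing amplitude is added.
#'
#' @param x numeric series.
#' @param lags integer lags.
#' @param n_bins histogram bins per margin.
#' @param noise_levels noise RMS levels as multiples of `sd(x)`.
#' @param seed RNG seed for the added noise.
#' @param cache internal memoization environment (optional).
#' @return named numeric vector.
#' @export
ami_features <- function(x, lags = 1:5, n_bins = 8,
                         noise_levels = seq(0, 1, by = 0.25), seed = 1,
                         cache = NULL) {
  nm <- c(paste0("ami_lag", lags), "ami_firstmin", "ami_noise_slope")
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (length(x) < 4 * n_bins || stats::sd(x) == 0) return(out)
  for (i in seq_along(lags)) out[i] <- ami_hist(x, lags[i], n_bins, cache)
  out["ami_firstmin"] <- first_min_ami(x, n_bins = n_bins, cache = cache)
  s <- stats::sd(x)
  ami_n <- with_local_seed(seed, {
    vapply(noise_levels, function(lv)
      ami_hist(x + stats::rnorm(length(x), 0, lv * s), 1, n_bins), 0)
  })
  if (!anyNA(ami_n))
    out["ami_noise_slope"] <- unname(stats::coef(stats::lm(ami_n ~ noise_levels))[2])
  out
}

# one-sided PSD estimate; power normalized to unit sum
psd_estimate <- function(x, fs, method = c("welch", "fourier", "periodogram"),
                         window = c("hamming", "rectangular")) {
  method <- match.arg(method)
  window <- match.arg(window)
  n <- length(x)
  win_fun <- function(m) {
    if (window == "hamming") 0.54 - 0.46 * cos(2 * pi * seq_len(m) / (m + 1))
    else rep(1, m)
  }
  if (method == "welch") {
    seg <- min(1024L, 2^floor(log2(n)))
    hop <- seg %/% 2
    starts <- seq.int(1L, n - seg + 1L, by = hop)
    wv <- win_fun(seg)
    idx <- outer(seq_len(seg) - 1L, starts, "+")
    segs <- matrix(x[idx], nrow = seg)
    segs <- (segs - rep(colMeans(segs), each = seg)) * wv
    P <- rowMeans(Mod(stats::mvfft(segs))^2)
    m <- seg
  } else {
    xd <- x - mean(x)
    if (method == "periodogram") {           # linear detrend as well
      tt <- seq_along(xd)
      xd <- stats::lm.fit(cbind(1, tt), xd)$residuals
    }
    xw <- xd * win_fun(n)
    # zero-pad to the next power of two: awkward prime-factor lengths make
    # the mixed-radix FFT dramatically slower without changing the summaries
    m <- 2^ceiling(log2(n))
    if (m > n) xw <- c(xw, numeric(m - n))
    P <- Mod(stats::fft(xw))^2
  }
  half <- seq_len(m %/% 2 + 1L)
  freq <- (half - 1L) * fs / m
  p <- P[half]
  tot <- sum(p)
  if (tot == 0) return(NULL)
  list(freq = freq, power = p / tot)
}

#' Distributional summaries of a power spectral density
#'
#' Computes the one-sided PSD with the given method/window, treats the
#' normalized PSD as a distribution over frequency, and summarizes it:
#' cumulative-power quartile frequencies (q25, median, q75), IQR and
#' log(IQR), spectral centroid and peak frequency.
#'
#' @param x numeric series (length >= 64).
#' @param fs sampling rate in Hz.
#' @param method `"welch"`, `"fourier"`, or `"periodogram"`.
#' @param window `"hamming"` or `"rectangular"`.
#' @return named numeric vector (names prefixed by method/window).
#' @export
psd_summaries <- function(x, fs, method = "welch", window = "hamming") {
  pre <- sprintf("sp_%s_%s_", substr(method, 1, 4), substr(window, 1, 4))
  nm <- paste0(pre, c("median", "iqr", "logiqr", "centroid", "peak", "q25", "q75"))
  out <- stats::setNames(rep(NA_real_, 7L), nm)
  if (length(x) < 64 || all(x == 0)) return(out)
  ps <- psd_estimate(x, fs, method, window)
  if (is.null(ps)) return(out)
  cum <- cumsum(ps$power)
  qf <- function(q) ps$freq[which(cum >= q)[1]]
  q25 <- qf(0.25); q50 <- qf(0.5); q75 <- qf(0.75)
  iqr <- q75 - q25
  out[] <- c(q50, iqr, if (iqr > 0) log(iqr) else NA_real_,
             sum(ps$freq * ps$power), ps$freq[which.max(ps$power)], q25, q75)
  out
}

# coarse-grain into k equiprobable-quantile symbols; NULL if degenerate
coarse_grain <- function(x, k) {
  br <- stats::quantile(x, probs = seq_len(k - 1) / k, names = FALSE)
  if (length(unique(br)) < k - 1) return(NULL)
  findInterval(x, br) + 1L
}

#' Symbol transition matrix
#'
#' Coarse-grains `x` into `k` equiprobable symbols and returns the
#' row-stochastic matrix of transition probabilities between consecutive
#' symbols.
#'
#' @param x numeric series.
#' @param k alphabet size.
#' @return a `k x k` matrix with rows summing to 1, or NULL when `x` has too
#'   few distinct values for `k` quantile bins.
#' @export
transition_matrix <- function(x, k) {
  s <- if (length(unique(x)) <= k && all(x %in% seq_len(k))) as.integer(x)
       else coarse_grain(x, k)
  if (is.null(s)) return(NULL)
  n <- length(s)
  cnt <- matrix(tabulate(s[-n] + k * (s[-1] - 1L), nbins = k * k), k, k)
  rs <- rowSums(cnt)
  P <- cnt / ifelse(rs == 0, 1, rs)
  P[rs == 0, ] <- 1 / k
  P
}

#' Symbolic-dynamics features
#'
#' Binary (above/below mean) run statistics; per-alphabet transition-matrix
#' statistics; length-3 word statistics for the 3-letter alphabet; and the
#' slope of the joint transition entropy against alphabet size.
#'
#' @param x numeric series.
#' @param alphabet_sizes integer alphabet sizes (>= 2).
#' @return named numeric vector.
#' @export
symbolic_features <- function(x, alphabet_sizes = 2:5) {
  nm <- c("sb_bin_longest_above", "sb_bin_longest_below", "sb_bin_meanrun",
          as.vector(outer(c("maxoff", "minoff", "trace", "entropy"),
                          alphabet_sizes,
                          function(a, k) sprintf("sb_trans%d_%s", k, a))),
          "sb_motif3_entropy", "sb_motif3_maxfreq", "sb_trans_alpha_slope")
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  n <- length(x)
  if (n < 20 * max(alphabet_sizes) || stats::sd(x) == 0) return(out)
  # binary run statistics
  b <- x > mean(x)
  r <- rle(b)
  out["sb_bin_longest_above"] <- max(c(r$lengths[r$values], 0))
  out["sb_bin_longest_below"] <- max(c(r$lengths[!r$values], 0))
  out["sb_bin_meanrun"] <- mean(r$lengths)
  ent_joint <- rep(NA_real_, length(alphabet_sizes))
  for (j in seq_along(alphabet_sizes)) {
    k <- alphabet_sizes[j]
    s <- coarse_grain(x, k)
    if (is.null(s)) next
    P <- transition_matrix(s, k)
    pim <- tabulate(s, k) / n
    joint <- pim * P
    off <- P[row(P) != col(P)]
    out[sprintf("sb_trans%d_maxoff", k)] <- max(off)
    out[sprintf("sb_trans%d_minoff", k)] <- min(off)
    out[sprintf("sb_trans%d_trace", k)] <- sum(diag(P)) / k
    nz <- joint > 0
    ent_joint[j] <- -sum(joint[nz] * log(joint[nz]))
    out[sprintf("sb_trans%d_entropy", k)] <- ent_joint[j]
    if (k == 3) {
      w <- s[1:(n - 2)] + 3L * (s[2:(n - 1)] - 1L) + 9L * (s[3:n] - 1L)
      pw <- tabulate(w, 27) / (n - 2)
      nzw <- pw > 0
      out["sb_motif3_entropy"] <- -sum(pw[nzw] * log(pw[nzw]))
      out["sb_motif3_maxfreq"] <- max(pw)
    }
  }
  if (!anyNA(ent_joint))
    out["sb_trans_alpha_slope"] <-
      unname(stats::coef(stats::lm(ent_joint ~ alphabet_sizes))[2])
  out
}

# ordinal-pattern entropy at one (m, tau, scale); NA when too short
perm_entropy_one <- function(x, m, tau, scale = 1) {
  if (scale > 1) {
    nseg <- floor(length(x) / scale)
    if (nseg < 2) return(NA_real_)
    x <- colMeans(matrix(x[seq_len(nseg * scale)], nrow = scale))
  }
  n <- length(x)
  np <- n - (m - 1) * tau
  if (np < 10 * factorial(m) / 6) return(NA_real_)   # minimal sampling guard
  cols <- lapply(seq_len(m) - 1L, function(j) x[seq_len(np) + j * tau])
  npair <- m * (m - 1) / 2
  code <- integer(np)
  bit <- 1L
  for (a in seq_len(m - 1)) for (b in seq.int(a + 1L, m)) {
    code <- code + bit * (cols[[a]] <= cols[[b]])
    bit <- bit * 2L
  }
  cnt <- tabulate(code + 1L, nbins = 2^npair)
  p <- cnt[cnt > 0] / np
  -sum(p * log(p))
}

#' Permutation entropy (ordinal-pattern entropy), with multiscale variant
#'
#' Shannon entropy in nats of the ordinal patterns of order `m` at lag
#' `tau`; at scales > 1 the series is first coarse-grained by
#' non-overlapping means. Bounded by `log(factorial(m))`.
#'
#' @param x numeric series.
#' @param m pattern order.
#' @param tau lag.
#' @param scales integer coarse-graining scales.
#' @return named numeric, one value per scale.
#' @export
permutation_entropy <- function(x, m = 3, tau = 1, scales = 1) {
  out <- vapply(scales, function(s) perm_entropy_one(x, m, tau, s), 0)
  stats::setNames(out, sprintf("permen_m%d_tau%d_scale%d", m, tau, scales))
}
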