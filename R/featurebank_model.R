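# Time-series feature bank, part 2: autoregressive model fits, stationarity,
# walker simulation, local forecasting, difference statistics, iterated
# preprocessing comparison, and the approximate SAP-style spectral baseline.

#' Autoregressive model-fit features
#'
#' Least-squares AR(p) fits for each order: per-order SBC (Schwarz) and FPE
#' (Akaike final prediction error), the orders they select, the lag-1
#' coefficient and residual lag-1 autocorrelation of the SBC-best model, the
#' mean/sd of one-step RMSE across equal local segments (goodness-of-fit
#' robustness), and multi-step prediction RMSE per horizon with its slope.
#'
#' @param x numeric series.
#' @param orders AR orders to fit.
#' @param horizons prediction horizons for the multi-step RMSE.
#' @param n_segments number of equal local segments.
#' @return named numeric vector.
#' @export
ar_features <- function(x, orders = 1:8, horizons = c(1, 2, 5, 10),
                        n_segments = 5) {
  nm <- c(paste0("ar_sbc_p", orders), paste0("ar_fpe_p", orders),
          "ar_best_order_sbc", "ar_best_order_fpe", "ar_phi1",
          "ar_resid_ac1", "ar_seg_rmse_mean", "ar_seg_rmse_sd",
          paste0("ar_rmse_h", horizons), "ar_rmse_slope")
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  n <- length(x)
  pmax_ <- max(orders)
  if (n < 10 * pmax_ || stats::sd(x) == 0) return(out)
  x <- x - mean(x)
  E <- stats::embed(x, pmax_ + 1L)        # cols: x_t, x_{t-1}, ..., x_{t-pmax}
  y <- E[, 1]
  ne <- length(y)
  # shared normal equations: every order's fit is a leading submatrix solve,
  # and its residual variance follows from the quadratic form without ever
  # materializing per-order residuals
  G <- crossprod(E[, -1, drop = FALSE])
  Xy <- crossprod(E[, -1, drop = FALSE], y)
  yty <- sum(y * y)
  sig2 <- sbc <- fpe <- rep(NA_real_, length(orders))
  coefs <- vector("list", length(orders))
  for (j in seq_along(orders)) {
    p <- orders[j]
    cf <- tryCatch(solve(G[seq_len(p), seq_len(p), drop = FALSE],
                         Xy[seq_len(p)]),
                   error = function(e) NULL)
    if (is.null(cf)) next
    cf <- as.numeric(cf)
    rss <- yty - 2 * sum(cf * Xy[seq_len(p)]) +
      sum(cf * (G[seq_len(p), seq_len(p)] %*% cf))
    sig2[j] <- max(rss, 0) / ne
    sbc[j] <- ne * log(sig2[j]) + p * log(ne)
    fpe[j] <- sig2[j] * (ne + p + 1) / (ne - p - 1)
    coefs[[j]] <- cf
  }
  if (anyNA(sbc)) return(out)
  out[paste0("ar_sbc_p", orders)] <- sbc
  out[paste0("ar_fpe_p", orders)] <- fpe
  jb <- which.min(sbc)
  out["ar_best_order_sbc"] <- orders[jb]
  out["ar_best_order_fpe"] <- orders[which.min(fpe)]
  pb <- orders[jb]
  cf <- coefs[[jb]]
  out["ar_phi1"] <- cf[1]
  Xb <- E[, 1 + seq_len(pb), drop = FALSE]
  res <- as.numeric(y - Xb %*% cf)
  if (stats::sd(res) > 0)
    out["ar_resid_ac1"] <- stats::acf(res, lag.max = 1, plot = FALSE)$acf[2]
  # robustness across local segments: one-step RMSE of the global fit
  seg <- cut(seq_along(res), n_segments, labels = FALSE)
  seg_rmse <- vapply(split(res, seg), function(r) sqrt(mean(r^2)), 0)
  out["ar_seg_rmse_mean"] <- mean(seg_rmse)
  out["ar_seg_rmse_sd"] <- stats::sd(seg_rmse)
  # multi-step forecasts: iterate the AR recursion from every time origin
  hmax <- max(horizons)
  n0 <- nrow(E) - hmax
  if (n0 > 10) {
    L <- E[seq_len(n0), seq_len(pb), drop = FALSE]  # x_t ... x_{t-pb+1}
    rmse_h <- rep(NA_real_, length(horizons))
    t0 <- pmax_ + seq_len(n0)               # index of x_t in original series
    for (h in seq_len(hmax)) {
      pred <- as.numeric(L %*% cf)
      if (h %in% horizons)
        rmse_h[match(h, horizons)] <- sqrt(mean((x[t0 + h] - pred)^2))
      L <- cbind(pred, L[, seq_len(pb - 1L), drop = FALSE])
    }
    out[paste0("ar_rmse_h", horizons)] <- rmse_h
    out["ar_rmse_slope"] <- unname(stats::coef(stats::lm(rmse_h ~ horizons))[2])
  }
  out
}

#' Bootstrap stationarity and local/global comparison features
#'
#' Draws random contiguous windows and reports the spread (sd across
#' windows) of the window mean, sd, skewness and kurtosis; plus comparisons
#' of a central window's statistics to the whole-series statistics.
#' Location-type statistics (mean, median, skewness) are compared by
#' absolute difference on the global-sd scale; scale-type statistics (sd,
#' IQR, kurtosis) by ratio.
#'
#' @param x numeric series.
#' @param window_fraction window length as a fraction of the series.
#' @param n_boot number of random windows (>= 20).
#' @param seed RNG seed for window placement.
#' @return named numeric vector (names carry the window fraction).
#' @export
stationarity_features <- function(x, window_fraction = 0.1, n_boot = 100,
                                  seed = 1) {
  tag <- sprintf("w%02d", round(100 * window_fraction))
  nm <- c(sprintf("sy_spread_%s_%s", tag, c("mean", "sd", "skew", "kurt")),
          sprintf("sy_lg_%s", c("mean", "sd", "median", "iqr", "skew", "kurt")))
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  n <- length(x)
  wl <- max(20L, as.integer(floor(window_fraction * n)))
  if (wl > n) stop2("window longer than series")
  if (n_boot < 20) stop2("n_boot must be >= 20")
  starts <- with_local_seed(seed, sample.int(n - wl + 1L, n_boot, replace = TRUE))
  idx <- outer(seq_len(wl) - 1L, starts, "+")
  W <- matrix(x[idx], nrow = wl)
  mu <- colMeans(W)
  cen <- W - rep(mu, each = wl)
  cen2 <- cen * cen
  m2 <- colMeans(cen2)
  var_w <- m2 * wl / (wl - 1)
  sdw <- sqrt(var_w)
  sk <- ifelse(m2 > 0, colMeans(cen2 * cen) / sdw^3, 0)
  ku <- ifelse(m2 > 0, colMeans(cen2 * cen2) / var_w^2, 0)
  out[1:4] <- c(stats::sd(mu), stats::sd(sdw), stats::sd(sk), stats::sd(ku))
  # central window vs whole series
  s0 <- (n - wl) %/% 2L + 1L
  loc <- x[s0:(s0 + wl - 1L)]
  g_sd <- stats::sd(x); g_iqr <- stats::IQR(x)
  out["sy_lg_mean"] <- if (g_sd == 0) 0 else abs(mean(loc) - mean(x)) / g_sd
  out["sy_lg_sd"] <- if (g_sd == 0) 0 else stats::sd(loc) / g_sd
  out["sy_lg_median"] <- if (g_sd == 0) 0 else
    abs(stats::median(loc) - stats::median(x)) / g_sd
  out["sy_lg_iqr"] <- if (g_iqr == 0) NA_real_ else stats::IQR(loc) / g_iqr
  out["sy_lg_skew"] <- abs(moment_skew(loc) - moment_skew(x))
  out["sy_lg_kurt"] <- if (moment_kurt(x) == 0) NA_real_ else
    moment_kurt(loc) / moment_kurt(x)
  out
}

#' Walker-simulation features
#'
#' Simulates a hypothetical walker attracted to the series value at each
#' point, `w[t+1] = w[t] + attraction * (x[t] - w[t])` with `w[1] = x[1]`,
#' and summarizes the walker-input relationship.
#'
#' @param x numeric series.
#' @param attraction attraction strength in (0, 1].
#' @return named numeric: mean walker-input difference, walker/input
#'   variance ratio, and sign asymmetry of the difference.
#' @export
walker_features <- function(x, attraction = 0.5) {
  if (!(attraction > 0 && attraction <= 1)) stop2("attraction must be in (0, 1]")
  tag <- sprintf("a%02d", round(100 * attraction))
  n <- length(x)
  y <- as.numeric(stats::filter(attraction * x, 1 - attraction,
                                method = "recursive", init = x[1]))
  w <- c(x[1], y[seq_len(n - 1)])
  v <- stats::var(x)
  stats::setNames(
    c(mean(w - x), if (v > 0) stats::var(w) / v else NA_real_, mean(sign(w - x))),
    sprintf("walker_%s_%s", tag, c("meandiff", "varratio", "signasym")))
}

#' Local forecasting and surprise features
#'
#' Mean-forecast error: predict each point as the mean of the previous `L`
#' values for each window length, returning the RMSE per window length and
#' the best length. Surprise: coarse-grain into 3 quantile symbols, estimate
#' the next-symbol probability from the empirical distribution of the
#' preceding `memory` symbols (add-one smoothing), and return the mean
#' negative log-probability of the realized symbols.
#'
#' @param x numeric series.
#' @param train_windows window lengths for the mean forecast.
#' @param memory numbers of preceding symbols for the surprise estimator.
#' @return named numeric vector.
#' @export
forecast_features <- function(x, train_windows = c(1, 2, 3, 5, 8, 13, 21),
                              memory = c(5, 10)) {
  nm <- c(paste0("fc_rmse_L", train_windows), "fc_best_L",
          paste0("fc_surprise_m", memory))
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  n <- length(x)
  if (n <= max(train_windows) + 1) stop2("series shorter than training window")
  if (any(memory >= n)) stop2("memory must be < series length")
  cs <- c(0, cumsum(x))
  rmse <- vapply(train_windows, function(L) {
    t <- L:(n - 1)                           # predict x[t+1]
    pred <- (cs[t + 1L] - cs[t - L + 1L]) / L
    sqrt(mean((x[t + 1L] - pred)^2))
  }, 0)
  out[paste0("fc_rmse_L", train_windows)] <- rmse
  out["fc_best_L"] <- train_windows[which.min(rmse)]
  if (stats::sd(x) == 0) {
    out[paste0("fc_surprise_m", memory)] <- 0
    return(out)
  }
  s <- coarse_grain(x, 3)
  if (!is.null(s)) {
    cnt <- vapply(1:3, function(j) cumsum(s == j), numeric(n))
    for (m in memory) {
      t <- (m + 1L):n
      win <- cnt[t - 1L, , drop = FALSE] -
        rbind(matrix(0, 1, 3), cnt, deparse.level = 0)[t - m, , drop = FALSE]
      p <- (win[cbind(seq_along(t), s[t])] + 1) / (m + 3)
      out[paste0("fc_surprise_m", m)] <- mean(-log(p))
    }
  }
  out
}

#' Successive-difference (heart-rate-variability-style) features
#'
#' On the successive differences `d = diff(x)`: the fraction of |d|
#' exceeding each threshold (thresholds as multiples of `sd(x)`), the RMSSD
#' analogue `sqrt(mean(d^2))`, and `sd(d)`.
#'
#' @param x numeric series (length >= 3).
#' @param pnn_thresholds thresholds as multiples of the series sd.
#' @return named numeric vector.
#' @export
diffstats_hrv <- function(x, pnn_thresholds = c(0.1, 0.25, 0.5, 1, 2)) {
  stopifnot(length(x) >= 3)
  d <- diff(x)
  s <- stats::sd(x)
  pnn <- if (s == 0) rep(0, length(pnn_thresholds))
         else vapply(pnn_thresholds, function(th) mean(abs(d) > th * s), 0)
  stats::setNames(c(pnn, sqrt(mean(d^2)), stats::sd(d)),
                  c(sprintf("hrv_pnn%03d", round(100 * pnn_thresholds)),
                    "hrv_rmssd", "hrv_sd_diff"))
}

#' Iterated-differencing preprocessing comparison
#'
#' Applies successive differencing 1..3 times; after each iteration
#' recomputes a fixed probe set (sd, lag-1 acf, spectral median in
#' normalized frequency) and returns the slope of each probe statistic
#' across iterations.
#'
#' @param x numeric series (length >= 64).
#' @return list with `trajectory` (3 x 3 matrix, iterations x probes) and
#'   `slopes` (named numeric of length 3).
#' @export
iterated_preprocess_compare <- function(x) {
  stopifnot(length(x) >= 64)
  probes <- function(z) {
    s <- stats::sd(z)
    ac1 <- if (s == 0) NA_real_ else stats::acf(z, lag.max = 1, plot = FALSE)$acf[2]
    sm <- if (s == 0) NA_real_ else {
      ps <- psd_estimate(z, fs = 2, method = "fourier", window = "rectangular")
      if (is.null(ps)) NA_real_ else ps$freq[which(cumsum(ps$power) >= 0.5)[1]]
    }
    c(sd = s, ac1 = ac1, specmed = sm)
  }
  traj <- matrix(NA_real_, 3, 3, dimnames = list(NULL, c("sd", "ac1", "specmed")))
  z <- x
  for (i in 1:3) {
    z <- diff(z)
    if (length(z) < 4) break
    traj[i, ] <- probes(z)
  }
  it <- 1:3
  slope1 <- function(v) if (anyNA(v)) NA_real_ else
    unname(stats::coef(stats::lm(v ~ it))[2])
  list(trajectory = traj,
       slopes = c(pp_slope_sd = slope1(traj[, "sd"]),
                  pp_slope_ac1 = slope1(traj[, "ac1"]),
                  pp_slope_specmed = slope1(traj[, "specmed"])))
}

#' Approximate SAP-style 12-feature spectral baseline
#'
#' Frame-based approximations of the 12 default Sound Analysis Pro motif
#' features: mean pitch, mean amplitude, and the mean and variance of mean
#' frequency (spectral centroid), Wiener entropy, pitch goodness, frequency
#' modulation and amplitude modulation. Frames are 9.27 ms with a 1.36 ms
#' hop (SAP's published defaults). These are explicit approximations of the
#' SAP algorithms, not reimplementations.
#'
#' @param w a `motif_wav` (ideally preprocessed).
#' @param pitch_band pitch search band in Hz.
#' @return named numeric vector of 12 features.
#' @export
baseline_spectral_features <- function(w, pitch_band = c(250, 8000)) {
  stopifnot(inherits(w, "motif_wav"))
  nm <- paste0("sap_", c("mean_pitch", "mean_amplitude",
                         "mean_meanfreq", "var_meanfreq",
                         "mean_wiener", "var_wiener",
                         "mean_goodness", "var_goodness",
                         "mean_fm", "var_fm", "mean_am", "var_am"))
  out <- stats::setNames(rep(NA_real_, 12L), nm)
  x <- w$samples; fs <- w$rate_hz
  win <- as.integer(round(0.00927 * fs))
  hop <- max(1L, as.integer(round(0.00136 * fs)))
  n <- length(x)
  if (n < win + 2 * hop) return(out)
  starts <- seq.int(1L, n - win + 1L, by = hop)
  idx <- outer(seq_len(win) - 1L, starts, "+")
  F <- matrix(x[idx], nrow = win)
  amp <- sqrt(colMeans(F^2))
  hw <- 0.54 - 0.46 * cos(2 * pi * seq_len(win) / (win + 1))
  nfft <- 2^ceiling(log2(win))
  Fw <- rbind(F * hw, matrix(0, nfft - win, ncol(F)))
  S <- stats::mvfft(Fw)
  P <- Mod(S[seq_len(nfft %/% 2 + 1L), , drop = FALSE])^2
  freq <- (seq_len(nfft %/% 2 + 1L) - 1L) * fs / nfft
  band <- freq >= pitch_band[1] & freq <= pitch_band[2]
  Pb <- P[band, , drop = FALSE] + 1e-12 * max(P)
  fb <- freq[band]
  meanfreq <- colSums(fb * Pb) / colSums(Pb)
  wiener <- colMeans(log(Pb)) - log(colMeans(Pb))
  # pitch via per-frame autocorrelation (inverse FFT of the power spectrum)
  Pfull <- Mod(S)^2
  ac <- Re(stats::mvfft(Pfull, inverse = TRUE))
  lag_lo <- max(2L, as.integer(floor(fs / pitch_band[2])))
  lag_hi <- min(win - 1L, as.integer(ceiling(fs / pitch_band[1])))
  pitch <- goodness <- rep(NA_real_, ncol(F))
  if (lag_hi > lag_lo) {
    acl <- ac[(lag_lo:lag_hi) + 1L, , drop = FALSE]
    pk <- max.col(t(acl), ties.method = "first")
    lag <- lag_lo + pk - 1L
    # parabolic interpolation around the peak for sub-sample pitch precision
    i0 <- cbind(pk, seq_len(ncol(F)))
    ym <- acl[i0]
    yl <- ifelse(pk > 1, acl[cbind(pk - 1L, seq_len(ncol(F)))], ym)
    yr <- ifelse(pk < nrow(acl), acl[cbind(pk + 1L, seq_len(ncol(F)))], ym)
    den <- yl - 2 * ym + yr
    delta <- ifelse(abs(den) > 0, 0.5 * (yl - yr) / den, 0)
    delta[!is.finite(delta) | abs(delta) > 1] <- 0
    pitch <- fs / (lag + delta)
    goodness <- ym / pmax(ac[1, ], .Machine$double.eps)
  }
  voiced <- amp > 0.1 * max(amp)
  if (sum(voiced) < 3) return(out)
  fm <- abs(diff(meanfreq[voiced]))
  am <- diff(amp[voiced])
  out[] <- c(mean(pitch[voiced]), mean(amp[voiced]),
             mean(meanfreq[voiced]), stats::var(meanfreq[voiced]),
             mean(wiener[voiced]), stats::var(wiener[voiced]),
             mean(goodness[voiced]), stats::var(goodness[voiced]),
             mean(fm), stats::var(fm), mean(am), stats::var(am))
  out
}
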