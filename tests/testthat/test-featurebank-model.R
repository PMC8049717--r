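test_that("AR features recover the generating order and coefficient", {
  set.seed(31)
  x <- as.numeric(stats::filter(rnorm(3000), c(0.6, -0.3),
                                method = "recursive"))
  af <- ar_features(x)
  expect_equal(unname(af["ar_best_order_sbc"]), 2)
  expect_equal(unname(af["ar_phi1"]), 0.6, tolerance = 0.05)
  # residual RMSE grows with forecast horizon for a mean-reverting process
  expect_gt(unname(af["ar_rmse_h10"]), unname(af["ar_rmse_h1"]))
})

test_that("stationarity features separate stationary from drifting series", {
  set.seed(32)
  stat <- rnorm(2000)
  drift <- rnorm(2000) + seq(0, 6, length.out = 2000)
  s1 <- stationarity_features(stat, 0.1, seed = 1)
  s2 <- stationarity_features(drift, 0.1, seed = 1)
  expect_gt(unname(s2["sy_spread_w10_mean"]),
            3 * unname(s1["sy_spread_w10_mean"]))
  expect_identical(s1, stationarity_features(stat, 0.1, seed = 1))
})

test_that("walker features respond to attraction strength", {
  set.seed(33)
  x <- rnorm(1000)
  w_weak <- walker_features(x, 0.1)
  w_strong <- walker_features(x, 0.9)
  expect_true(all(is.finite(c(w_weak, w_strong))))
  expect_false(identical(w_weak, w_strong))
})

test_that("difference statistics count threshold crossings correctly", {
  x <- c(0, 1, 0, 1, 0)   # |diffs| all 1; sd(x) ~ 0.5477
  h <- diffstats_hrv(x, pnn_thresholds = c(0.1, 2))
  expect_equal(unname(h["hrv_pnn010"]), 1)   # 1 > 0.1 * sd
  expect_equal(unname(h["hrv_pnn200"]), 0)   # 1 < 2 * sd
  expect_equal(unname(h["hrv_rmssd"]), 1)
})

test_that("forecast features are exact on a constant series", {
  f <- forecast_features(rep(2, 300))
  expect_true(all(f[grep("rmse", names(f))] == 0 | is.na(f[grep("rmse", names(f))])))
})

test_that("baseline spectral features track pitch", {
  fs <- 44100
  t <- seq_len(fs %/% 2) / fs
  x <- 0.5 * sin(2 * pi * 700 * t) + 0.25 * sin(2 * pi * 1400 * t)
  sap <- baseline_spectral_features(motif_waveform(x, fs, "b", "courtship"))
  expect_equal(unname(sap["sap_mean_pitch"]), 700, tolerance = 25)
  expect_true(all(is.finite(sap)))
})
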