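test_that("co_trev and dk_trev reproduce the worked examples exactly", {
  expect_identical(co_trev(c(1, 2, 3), 1), -1.0)
  expect_identical(co_trev(c(1, 2, 1, 2, 1), 1), 0.0)
  expect_identical(dk_trev(c(1, 2, 3, 4), 1), -26.0)
})

test_that("irreversibility statistics match brute-force oracles", {
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(sample(20:64, 1))
    for (tau in 1:3) {
      expect_equal(co_trev(x, tau), bf_co_trev(x, tau), tolerance = 1e-12)
      if (length(x) > 2 * tau + 1)
        expect_equal(dk_trev(x, tau), bf_dk_trev(x, tau), tolerance = 1e-12)
    }
  }
})

test_that("co_trev is antisymmetric under time reversal", {
  set.seed(7)
  for (i in 1:20) {
    x <- cumsum(rnorm(200))
    expect_equal(co_trev(rev(x), 1), -co_trev(x, 1), tolerance = 1e-12)
  }
  pal <- c(1, 4, 2, 8, 2, 4, 1)
  expect_equal(co_trev(pal, 1), 0, tolerance = 1e-12)
})

test_that("symbolic lag modes resolve as documented", {
  x <- sin(2 * pi * seq_len(600) / 25) + 0.05 * sin(seq_len(600))
  lag0 <- first_zero_acf(x)
  expect_false(is.na(lag0))
  expect_equal(co_trev(x, "acf_zero"), co_trev(x, lag0))
  lam <- first_min_ami(x)
  expect_false(is.na(lam))
  expect_equal(co_trev(x, "ami_min"), co_trev(x, lam))
  expect_true(is.na(co_trev(rep(1, 100), 1)))
})

test_that("permutation entropy matches the rank-pattern oracle", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(sample(80, 1) + 120)
    for (m in c(3, 4)) {
      got <- unname(permutation_entropy(x, m, 1, 1))
      expect_equal(got, bf_perm_entropy(x, m, 1), tolerance = 1e-10)
    }
  }
  # monotone series has a single pattern: zero entropy
  expect_equal(unname(permutation_entropy(seq_len(200), 3, 1, 1)), 0)
})

test_that("transition matrices match the brute-force oracle", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(64)
    for (k in 2:4) {
      tm <- transition_matrix(x, k)
      expect_equal(unname(tm), unname(bf_transition_matrix(x, k)),
                   tolerance = 1e-10)
      expect_true(all(abs(rowSums(tm) - 1) < 1e-12 | rowSums(tm) == 0))
    }
  }
})

test_that("preprocessing bandpasses and renormalizes", {
  fs <- 44100
  t <- seq_len(fs %/% 5) / fs
  low <- sin(2 * pi * 60 * t)           # below the 250 Hz corner
  mid <- sin(2 * pi * 2000 * t)
  w <- motif_waveform(low + mid, fs, "b", "courtship")
  out <- preprocess_waveform(w)
  ps <- songsift:::psd_estimate(out$samples, fs, "welch", "hamming")
  p60 <- sum(ps$power[ps$freq < 150])
  p2000 <- sum(ps$power[ps$freq > 1500 & ps$freq < 2500])
  expect_lt(p60, 0.2 * p2000)
  expect_equal(20 * log10(songsift:::rms(out$samples)), -20, tolerance = 0.1)
})

test_that("spectral summaries locate a pure tone", {
  fs <- 8000
  x <- sin(2 * pi * 1000 * seq_len(4096) / fs)
  for (method in c("welch", "fourier", "periodogram")) {
    s <- psd_summaries(x, fs, method, "hamming")
    pre <- sprintf("sp_%s_hamm_", substr(method, 1, 4))
    expect_equal(unname(s[paste0(pre, "peak")]), 1000, tolerance = 10)
    expect_equal(unname(s[paste0(pre, "centroid")]), 1000, tolerance = 25)
  }
})

test_that("extract_all is deterministic, complete, and failure-tolerant", {
  cfg <- synth_config(n_birds = 1, renditions_per_context = 1, seed = 21)
  w <- preprocess_waveform(make_motif(cfg, 1, "courtship", 1))
  f1 <- extract_all(w, seed = 9)
  f2 <- extract_all(w, seed = 9)
  expect_identical(unclass(f1)[], unclass(f2)[])
  expect_length(f1, length(registry_feature_names(default_registry())))
  expect_equal(sum(is.na(f1)), 0)
  # a registry with a failing operation never aborts the motif
  bad <- c(default_registry()[1],
           list(feature_spec("boom", list(), "boom_value",
                             function(x, fs, seed, cache) stop("kaput"))))
  fb <- extract_all(w, bad, seed = 1)
  expect_true(is.na(fb["boom_value"]))
  expect_match(attr(fb, "failures")[["boom"]], "kaput")
  # constant waveform: irreversibility/acf features are invalid-markers
  const <- motif_waveform(rep(0.5, 4000), 8000, "b", "courtship")
  fc <- extract_all(const, seed = 1)
  expect_true(is.na(fc["co_trev_tau1"]))
})

test_that("registry rejects duplicate feature names", {
  reg <- default_registry()
  dup <- c(reg[1], reg[1])
  expect_error(extract_all(
    motif_waveform(rnorm(100), 1000, "b", "courtship"), dup), "duplicate")
})
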