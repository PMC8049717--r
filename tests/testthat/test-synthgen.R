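test_that("motif synthesis is deterministic and rendition-jittered", {
  cfg <- synth_config(n_birds = 2, renditions_per_context = 3, seed = 11)
  m1 <- make_motif(cfg, 1, "courtship", 1)
  m2 <- make_motif(cfg, 1, "courtship", 1)
  expect_identical(m1$samples, m2$samples)
  m3 <- make_motif(cfg, 1, "courtship", 2)
  expect_false(identical(m1$samples, m3$samples))
  expect_true(all(is.finite(m1$samples)))
  expect_gt(length(m1$samples), 0.2 * cfg$rate_hz)
})

test_that("dataset counts, labels, and probe roles are correct", {
  ds <- tiny_dataset(seed = 2, n_birds = 2, renditions = 3, probes = 1)
  expect_s3_class(ds, "motif_dataset")
  expect_length(ds$motifs, 2 * 2 * (3 + 1))
  expect_equal(nrow(ds$truth), length(ds$motifs))
  expect_setequal(unique(ds$truth$context), c("courtship", "noncourtship"))
  expect_equal(sum(ds$truth$role == "probe"), 2 * 2 * 1)
  expect_equal(length(unique(ds$truth$bird_id)), 2)
})

test_that("courtship motifs carry the injected pitch shift", {
  cfg <- synth_config(n_birds = 1, renditions_per_context = 5,
                      f0_context_shift = 0.05, bandwidth_effect = 0,
                      asym_effect = 0, rendition_jitter_cv = 0, seed = 3)
  # full-length periodogram: Welch's ~43 Hz bins cannot resolve a 5% shift
  # of a 600 Hz fundamental
  peak_freq <- function(w) {
    ps <- songsift:::psd_estimate(w$samples, w$rate_hz, "periodogram",
                                  "hamming")
    ps$freq[which.max(ps$power)]
  }
  f_c <- peak_freq(make_motif(cfg, 1, "courtship", 1))
  f_n <- peak_freq(make_motif(cfg, 1, "noncourtship", 1))
  expect_gt(f_c / f_n, 1.02)
})

test_that("behavior sessions respect schema and rates", {
  cfg <- behavior_config(days = 8, trials_per_day = 200, probe_rate = 0.15,
                         seed = 5)
  tr <- make_behavior_sessions(cfg)
  expect_true(all(c("day", "trial", "stimulus_id", "context", "probe",
                    "response", "correct", "rewarded", "rt_s",
                    "reward_balanced") %in% names(tr)))
  expect_equal(nrow(tr), 8 * 200)
  expect_true(all(tr$rt_s[tr$response != "none"] > 0))
  expect_true(all(is.na(tr$rt_s[tr$response == "none"])))
  pr <- mean(tr$probe)
  expect_gt(pr, 0.10)
  expect_lt(pr, 0.20)
  expect_identical(make_behavior_sessions(cfg), tr)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(synth_config(n_birds = 0))
  expect_error(make_behavior_sessions(behavior_config(days = 0)),
               "days")
})
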