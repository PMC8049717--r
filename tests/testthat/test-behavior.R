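test_that("daily summaries apply the response and balance filters", {
  mk <- function(day, n, n_correct, balanced = TRUE, probe = FALSE) {
    data.frame(day = day, trial = seq_len(n), stimulus_id = "C01",
               context = "courtship", probe = probe,
               response = "A",
               correct = rep(c(TRUE, FALSE), c(n_correct, n - n_correct)),
               rewarded = TRUE, rt_s = 1, reward_balanced = balanced)
  }
  tr <- rbind(mk(1, 19, 19),            # too few responses
              mk(2, 20, 10),            # kept: 50%
              mk(3, 40, 30, balanced = FALSE),  # unbalanced day
              mk(4, 30, 30, probe = TRUE),      # probes never count
              mk(5, 25, 20))            # kept: 80%
  s <- summarize_sessions(tr)
  expect_equal(s$day, c(2, 5))
  expect_equal(s$pct_correct, c(50, 80))
})

test_that("sigmoid fit recovers noiseless parameters", {
  days <- 1:30
  pct <- 50 + 35 / (1 + exp(-1 * (days - 10)))
  f <- fit_learning_sigmoid(
    data.frame(day = days, n_responses = 100, pct_correct = pct))
  expect_true(f$converged)
  expect_equal(f$U, 85, tolerance = 1e-3)
  expect_equal(f$d0, 10, tolerance = 1e-2)
  # a noiseless fit has zero residual and parameter uncertainty, so the
  # lower bound coincides with the asymptote
  expect_lte(f$threshold, f$U)
  expect_equal(f$sigma, 0, tolerance = 1e-6)
  short <- fit_learning_sigmoid(
    data.frame(day = 1:4, n_responses = 100, pct_correct = 50))
  expect_false(short$converged)
})

test_that("required run length matches the stated arithmetic and is monotone", {
  expect_identical(required_run_length(32, 0.5), 10L)
  expect_identical(required_run_length(10, 0.1), 3L)
  expect_identical(required_run_length(10, 0), 1L)
  expect_identical(required_run_length(10, 1), Inf)
  r1 <- required_run_length(30, 0.4)
  r2 <- required_run_length(30, 0.7)
  expect_lte(r1, r2)
  expect_lte(required_run_length(10, 0.5), required_run_length(100, 0.5))
})

test_that("run criterion is conservative against the exact DP oracle", {
  # sanity of the oracle itself: P(run >= 2 in 3 fair tosses) = 3/8
  expect_equal(bf_run_probability(3, 0.5, 2), 3 / 8, tolerance = 1e-12)
  for (n in c(10, 15, 20)) for (p in c(0.3, 0.5, 0.7)) {
    r <- required_run_length(n, p)
    if (is.finite(r) && r <= n)
      expect_lt(bf_run_probability(n, p, r), 0.05 * 1.0000001)
  }
})

test_that("learning day detection scans runs correctly", {
  s <- data.frame(day = 1:10, n_responses = 50,
                  pct_correct = c(40, 40, 80, 80, 40, 80, 80, 80, 80, 80))
  expect_equal(detect_learning_day(s, 70, 3), 6)
  expect_equal(detect_learning_day(s, 70, 2), 3)
  expect_true(is.na(detect_learning_day(s, 70, 6)))
  all_above <- data.frame(day = 1:6, n_responses = 50, pct_correct = 90)
  expect_equal(detect_learning_day(all_above, 70, 4), 1)
  expect_true(is.na(detect_learning_day(s, 70, Inf)))
})

test_that("a simulated learner is detected and a flat performer is not", {
  cfg <- behavior_config(p_start = 0.5, p_asymptote = 0.85, inflection_day = 10,
                         slope = 1, days = 30, trials_per_day = 500, seed = 61)
  a <- assess_learning(make_behavior_sessions(cfg))
  expect_true(a$learned)
  expect_gt(a$fit$U, 80)
  flat <- behavior_config(p_start = 0.5, p_asymptote = 0.5, days = 30,
                          trials_per_day = 500, seed = 61)
  af <- assess_learning(make_behavior_sessions(flat))
  expect_false(af$learned)
  expect_type(af$reason, "character")
})

test_that("probe generalization flags behave at the extremes", {
  cfg <- behavior_config(p_start = 0.8, p_asymptote = 0.85, days = 10,
                         trials_per_day = 300, seed = 62)
  pp <- probe_performance(make_behavior_sessions(cfg))
  expect_true(pp$generalized)
  expect_equal(nrow(pp$by_context), 2)
  expect_true(all(pp$by_context$n_trials > 0))
  # no probes at all: untestable, not generalized
  tr <- make_behavior_sessions(behavior_config(days = 6, seed = 63))
  pp0 <- probe_performance(tr[!tr$probe, ])
  expect_false(pp0$generalized)
  expect_true(all(!pp0$by_context$testable))
})

test_that("pairwise correlations have the stated structure", {
  set.seed(64)
  base <- runif(30, 0.3, 0.9)
  acc <- rbind(s1 = base, s2 = base,                  # identical: r = 1
               s3 = base + rnorm(30, 0, 0.02),
               s4 = rep(0.5, 30))                     # zero variance: skipped
  pc <- pairwise_subject_correlations(acc)
  expect_equal(pc$r["s1", "s2"], 1, tolerance = 1e-12)
  expect_equal(pc$r, t(pc$r))
  expect_equal(unname(diag(pc$r)), rep(1, 4))
  expect_true(any(grepl("s4", pc$skipped)))
  expect_lte(pc$n_significant_positive, pc$n_tests)
})

test_that("trials CSV schema errors name the offending column", {
  tr <- make_behavior_sessions(behavior_config(days = 2, seed = 65))
  f <- tempfile(fileext = ".csv")
  write_trials_csv(tr, f)
  back <- read_trials_csv(f)
  expect_equal(nrow(back), nrow(tr))
  broken <- utils::read.csv(f)
  broken$rt_s <- NULL
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(broken, f2, row.names = FALSE)
  expect_error(read_trials_csv(f2), "rt_s")
})
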