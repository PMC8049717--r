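# Analysis of two-alternative choice operant sessions: daily summaries, the
# sigmoid + geometric-run learning criterion, probe generalization, and
# stimulus-level inter-subject correlations.

trial_schema <- c("day", "trial", "stimulus_id", "context", "probe",
                  "response", "correct", "rewarded", "rt_s",
                  "reward_balanced")

#' Read an operant trials CSV
#'
#' @param path CSV path with the trial schema written by
#'   [write_trials_csv()].
#' @return data frame of trials.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop2("trials file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_schema, names(df))
  if (length(miss))
    stop2("trials file ", path, " is missing column(s): ",
          paste(miss, collapse = ", "))
  df
}

#' Write an operant trials CSV
#'
#' @param trials data frame of trials (schema of
#'   [make_behavior_sessions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  miss <- setdiff(trial_schema, names(trials))
  if (length(miss))
    stop2("trials are missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(trials[trial_schema], path, row.names = FALSE)
  invisible(path)
}

#' Daily performance summaries
#'
#' Percent correct per day over responded, non-probe trials. Days with fewer
#' than `min_responses` responses, or on which the two reward ports were not
#' rewarded at equal rates, are excluded.
#'
#' @param trials trial data frame.
#' @param min_responses minimum responded trials for a day to qualify
#'   (default 20).
#' @return data frame with `day`, `n_responses`, `pct_correct` (possibly
#'   zero rows).
#' @export
summarize_sessions <- function(trials, min_responses = 20) {
  miss <- setdiff(trial_schema, names(trials))
  if (length(miss))
    stop2("trials are missing column(s): ", paste(miss, collapse = ", "))
  t0 <- trials[!trials$probe & trials$response != "none", , drop = FALSE]
  days <- sort(unique(t0$day))
  out <- do.call(rbind, lapply(days, function(d) {
    td <- t0[t0$day == d, , drop = FALSE]
    data.frame(day = d, n_responses = nrow(td),
               pct_correct = 100 * mean(td$correct),
               reward_balanced = all(td$reward_balanced))
  }))
  if (is.null(out))
    return(data.frame(day = integer(), n_responses = integer(),
                      pct_correct = numeric()))
  out <- out[out$n_responses >= min_responses & out$reward_balanced, , drop = FALSE]
  rownames(out) <- NULL
  out[c("day", "n_responses", "pct_correct")]
}

#' Fit a four-parameter logistic learning curve
#'
#' Least-squares fit of `pct(day) = L + (U - L) / (1 + exp(-s (day - d0)))`
#' to daily percent correct, with `L, U` in `[0, 100]` and `s >= 0` so `U`
#' is the late-training asymptote. The learning threshold is the lower 95%
#' bound of the asymptote.
#'
#' Two threshold readings are available. `"prediction"` (the default) asks
#' where a single day's *observed* performance at asymptote would fall with
#' 95% confidence, so it widens the parameter uncertainty by the residual
#' day-to-day noise: `U - t * sqrt(se(U)^2 + sigma^2)`. `"parameter"` uses
#' the parameter confidence bound alone, `U - t * se(U)`. With hundreds of
#' trials per day the parameter bound sits well inside the daily sampling
#' noise (its margin shrinks like `sigma / sqrt(days)`), so consecutive-day
#' runs above it break by chance even in a fully learned subject and the
#' downstream run criterion becomes a coin flip; the prediction bound keeps
#' the run criterion's sensitivity without costing specificity (a flat
#' performer sits above the prediction bound on essentially every day, which
#' makes a long run uninformative and the subject "not learned").
#'
#' @param sessions daily summaries from [summarize_sessions()].
#' @param threshold_method `"prediction"` (default) or `"parameter"`; see
#'   Details.
#' @return list: `converged`, and when TRUE the parameters `L`, `U`, `d0`,
#'   `s`, the standard error `u_se`, the residual standard deviation
#'   `sigma`, and `threshold` (lower 95% bound of the asymptote under the
#'   chosen reading); when FALSE a `reason` string.
#' @export
fit_learning_sigmoid <- function(sessions,
                                 threshold_method = c("prediction",
                                                      "parameter")) {
  threshold_method <- match.arg(threshold_method)
  if (nrow(sessions) < 5)
    return(list(converged = FALSE,
                reason = sprintf("only %d qualifying days (need >= 5)",
                                 nrow(sessions))))
  df <- data.frame(day = sessions$day, pct = sessions$pct_correct)
  start <- list(L = 50, U = max(df$pct), d0 = stats::median(df$day), s = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(pct ~ L + (U - L) / (1 + exp(-s * (day - d0))),
                      data = df, start = start,
                      lower = c(0, 0, -Inf, 0), upper = c(100, 100, Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(converged = FALSE, reason = conditionMessage(fit)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
  if (is.null(se) || !is.finite(se[["U"]]))
    return(list(converged = FALSE,
                reason = "asymptote uncertainty not estimable"))
  resid_df <- nrow(df) - length(cf)
  tq <- stats::qt(0.975, df = resid_df)
  sigma <- sqrt(sum(stats::resid(fit)^2) / resid_df)
  margin <- if (threshold_method == "prediction") {
    tq * sqrt(se[["U"]]^2 + sigma^2)
  } else {
    tq * se[["U"]]
  }
  list(converged = TRUE, L = unname(cf[["L"]]), U = unname(cf[["U"]]),
       d0 = unname(cf[["d0"]]), s = unname(cf[["s"]]),
       u_se = unname(se[["U"]]), sigma = unname(sigma),
       threshold = unname(cf[["U"]] - margin))
}

#' Required consecutive-day run length
#'
#' Smallest run length `r` whose expected number of chance occurrences over
#' the task,`n_days * p_above^r`, falls below `alpha`: a run that long is
#' unlikely to arise from day-to-day chance alone.
#'
#' @param n_days number of qualifying days.
#' @param p_above per-day probability of exceeding the threshold.
#' @param alpha evidence level (default 0.05).
#' @return integer run length; `Inf` when `p_above = 1` (no finite run can
#'   be non-random).
#' @export
required_run_length <- function(n_days, p_above, alpha = 0.05) {
  stopifnot(n_days >= 1, p_above >= 0, p_above <= 1, alpha > 0)
  if (p_above == 0) return(1L)
  if (p_above == 1) return(Inf)
  r <- max(1L, as.integer(floor(log(alpha / n_days) / log(p_above))) )
  while (n_days * p_above^r >= alpha) r <- r + 1L
  r
}

#' First day of a sufficiently long above-threshold run
#'
#' Scans qualifying days in order and returns the first day that begins at
#' least `run_length` consecutive qualifying days above `threshold`.
#' Consecutive means adjacent in the qualifying-day sequence (excluded days
#' do not break a run).
#'
#' @param sessions daily summaries from [summarize_sessions()].
#' @param threshold percent-correct threshold.
#' @param run_length required run length (from [required_run_length()]).
#' @return the day index, or `NA` when the criterion is never met.
#' @export
detect_learning_day <- function(sessions, threshold, run_length) {
  if (!is.finite(run_length) || nrow(sessions) == 0) return(NA_integer_)
  sessions <- sessions[order(sessions$day), , drop = FALSE]
  above <- sessions$pct_correct > threshold
  run <- rle(above)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= run_length)
  if (length(hit) == 0) return(NA_integer_)
  start_idx <- ends[hit[1]] - run$lengths[hit[1]] + 1L
  sessions$day[start_idx]
}

#' Full learning assessment
#'
#' Orchestrates the learning criterion: daily summaries, sigmoid fit,
#' asymptote threshold, per-day above-threshold probability, geometric
#' required run length, and the learning day. Any failure along the way
#' (too few days, non-convergent fit, every day above threshold) yields
#' `learned = FALSE` with the reason recorded, never an exception.
#'
#' @param trials trial data frame.
#' @param alpha evidence level for the run criterion.
#' @param p_above_method `"empirical"` (fraction of qualifying days above
#'   the threshold; default) or `"model"` (fraction of days the fitted curve
#'   exceeds the threshold).
#' @param threshold_method passed to [fit_learning_sigmoid()].
#' @param min_responses passed to [summarize_sessions()].
#' @return a `learning_assessment` list: `learned`, `learning_day`, `fit`,
#'   `threshold`, `p_above`, `run_length`, `n_days`, `reason`.
#' @export
assess_learning <- function(trials, alpha = 0.05,
                            p_above_method = c("empirical", "model"),
                            threshold_method = c("prediction", "parameter"),
                            min_responses = 20) {
  p_above_method <- match.arg(p_above_method)
  threshold_method <- match.arg(threshold_method)
  sessions <- summarize_sessions(trials, min_responses)
  res <- list(learned = FALSE, learning_day = NA_integer_, fit = NULL,
              threshold = NA_real_, p_above = NA_real_,
              run_length = NA_real_, n_days = nrow(sessions),
              sessions = sessions, reason = NULL)
  class(res) <- "learning_assessment"
  fit <- fit_learning_sigmoid(sessions, threshold_method)
  res$fit <- fit
  if (!fit$converged) {
    res$reason <- paste("sigmoid fit failed:", fit$reason)
    return(res)
  }
  res$threshold <- fit$threshold
  res$p_above <- if (p_above_method == "empirical") {
    mean(sessions$pct_correct > fit$threshold)
  } else {
    curve <- fit$L + (fit$U - fit$L) /
      (1 + exp(-fit$s * (sessions$day - fit$d0)))
    mean(curve > fit$threshold)
  }
  if (res$p_above == 1) {
    res$reason <- "every day above threshold: no finite run is non-random"
    return(res)
  }
  res$run_length <- required_run_length(nrow(sessions), res$p_above, alpha)
  day <- detect_learning_day(sessions, fit$threshold, res$run_length)
  if (is.na(day)) {
    res$reason <- sprintf("no run of %d consecutive days above %.1f%%",
                          res$run_length, fit$threshold)
    return(res)
  }
  res$learned <- TRUE
  res$learning_day <- day
  res
}

#' @export
print.learning_assessment <- function(x, ...) {
  if (x$learned) {
    cat(sprintf(paste0("<learning_assessment> learned on day %d ",
                       "(threshold %.1f%%, run >= %d of %d days)\n"),
                x$learning_day, x$threshold, x$run_length, x$n_days))
  } else {
    cat("<learning_assessment> not learned:", x$reason, "\n")
  }
  if (!is.null(x$fit) && isTRUE(x$fit$converged))
    cat(sprintf("  sigmoid: L=%.1f U=%.1f d0=%.1f s=%.2f (U se %.2f)\n",
                x$fit$L, x$fit$U, x$fit$d0, x$fit$s, x$fit$u_se))
  invisible(x)
}

# one-sample test of daily proportions against 0.5, robust to zero variance
prop_above_chance <- function(props, alpha) {
  if (length(props) < 2)
    return(list(p = NA_real_, significant = FALSE,
                reason = "fewer than 2 days with probe responses"))
  if (stats::sd(props) == 0) {
    p <- if (props[1] > 0.5) 0 else 1
    return(list(p = p, significant = p < alpha, reason = NULL))
  }
  tt <- stats::t.test(props, mu = 0.5, alternative = "greater")
  list(p = tt$p.value, significant = tt$p.value < alpha, reason = NULL)
}

#' Probe-stimulus generalization
#'
#' Percent correct on responded probe trials by context, a one-sided
#' per-context test of daily probe proportions against chance (0.5), and the
#' generalized flag (both contexts significantly above chance). Also reports
#' probe-vs-training percent correct and median reaction times.
#'
#' @param trials trial data frame.
#' @param alpha significance level per context.
#' @return list with `by_context` data frame (`context`, `n_trials`,
#'   `pct_correct`, `p_value`, `significant`, `testable`), `generalized`,
#'   `training_pct_correct`, `probe_pct_correct`, `median_rt_probe_s`,
#'   `median_rt_training_s`.
#' @export
probe_performance <- function(trials, alpha = 0.05) {
  pr <- trials[trials$probe & trials$response != "none", , drop = FALSE]
  tr <- trials[!trials$probe & trials$response != "none", , drop = FALSE]
  contexts <- sort(unique(trials$context))
  rows <- lapply(contexts, function(cx) {
    px <- pr[pr$context == cx, , drop = FALSE]
    if (nrow(px) == 0)
      return(data.frame(context = cx, n_trials = 0L, pct_correct = NA_real_,
                        p_value = NA_real_, significant = FALSE,
                        testable = FALSE))
    props <- tapply(px$correct, px$day, mean)
    tst <- prop_above_chance(as.numeric(props), alpha)
    data.frame(context = cx, n_trials = nrow(px),
               pct_correct = 100 * mean(px$correct),
               p_value = tst$p, significant = tst$significant,
               testable = is.null(tst$reason))
  })
  by_context <- do.call(rbind, rows)
  list(by_context = by_context,
       generalized = nrow(by_context) >= 2 && all(by_context$significant),
       training_pct_correct = if (nrow(tr)) 100 * mean(tr$correct) else NA_real_,
       probe_pct_correct = if (nrow(pr)) 100 * mean(pr$correct) else NA_real_,
       median_rt_probe_s = if (nrow(pr)) stats::median(pr$rt_s) else NA_real_,
       median_rt_training_s = if (nrow(tr)) stats::median(tr$rt_s) else NA_real_)
}

#' Pairwise inter-subject correlations of per-stimulus accuracy
#'
#' Pearson correlation, per pair of subjects, of percent correct across the
#' stimuli both responded to; pairs with fewer than 3 shared stimuli or a
#' zero-variance subject are skipped.
#'
#' @param acc subjects x stimuli numeric matrix of per-stimulus accuracy
#'   (NA where a subject never responded to a stimulus); rownames identify
#'   subjects.
#' @param alpha significance level.
#' @return list with symmetric `r` and `p` matrices (unit/NA diagonals),
#'   `n_significant_positive`, `n_tests`, and `skipped` pair labels.
#' @export
pairwise_subject_correlations <- function(acc, alpha = 0.05) {
  stopifnot(is.matrix(acc), nrow(acc) >= 2)
  ns <- nrow(acc)
  ids <- rownames(acc)
  if (is.null(ids)) ids <- paste0("subject", seq_len(ns))
  r <- matrix(NA_real_, ns, ns, dimnames = list(ids, ids))
  p <- r
  diag(r) <- 1
  n_sig <- 0L; n_tests <- 0L; skipped <- character()
  for (i in seq_len(ns - 1)) for (j in seq.int(i + 1, ns)) {
    ok <- is.finite(acc[i, ]) & is.finite(acc[j, ])
    lab <- paste(ids[i], ids[j], sep = " x ")
    if (sum(ok) < 3) { skipped <- c(skipped, lab); next }
    xi <- acc[i, ok]; xj <- acc[j, ok]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      skipped <- c(skipped, lab); next
    }
    ct <- stats::cor.test(xi, xj)
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    n_tests <- n_tests + 1L
    if (ct$p.value < alpha && ct$estimate > 0) n_sig <- n_sig + 1L
  }
  list(r = r, p = p, n_significant_positive = n_sig, n_tests = n_tests,
       skipped = skipped)
}

#' Per-stimulus accuracy table from trials
#'
#' Convenience builder for [pairwise_subject_correlations()] and the
#' classifier-vs-subject analysis: fraction correct per stimulus over
#' responded trials.
#'
#' @param trials trial data frame.
#' @param probe_only restrict to probe trials (default FALSE).
#' @return named numeric vector, one entry per stimulus.
#' @export
per_stimulus_accuracy <- function(trials, probe_only = FALSE) {
  t0 <- trials[trials$response != "none", , drop = FALSE]
  if (probe_only) t0 <- t0[t0$probe, , drop = FALSE]
  if (nrow(t0) == 0) return(stats::setNames(numeric(), character()))
  vapply(split(t0$correct, t0$stimulus_id), mean, 0)
}
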