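# Synthetic motif and operant-session generators. Every downstream stage of
# the package is testable against these, with ground truth known by
# construction.

#' Configuration for the synthetic motif generator
#'
#' Motifs are built as sequences of harmonic-stack syllables. The three
#' context knobs emulate the acoustic contrasts between courtship and
#' non-courtship renditions of the same motif: courtship raises the
#' fundamental (`f0_context_shift`), non-courtship widens the spectral
#' spread by weakening the per-harmonic amplitude decay (`bandwidth_effect`),
#' and non-courtship increases the attack/decay asymmetry of the amplitude
#' envelope (`asym_effect`), which drives time irreversibility of the
#' waveform.
#'
#' @param n_birds number of synthetic birds.
#' @param renditions_per_context training renditions per context per bird.
#' @param probe_renditions_per_context additional probe-role renditions per
#'   context per bird (default 0).
#' @param rate_hz sampling rate (Hz).
#' @param syllable_count syllables per motif.
#' @param f0_base_hz fundamental of the first bird's first syllable.
#' @param f0_spacing_hz spacing between consecutive birds' fundamentals.
#' @param f0_context_shift fractional increase of courtship fundamental.
#' @param bandwidth_effect fractional weakening of the non-courtship
#'   harmonic amplitude decay (widens the PSD).
#' @param asym_effect additive increment of the non-courtship envelope
#'   attack/decay asymmetry parameter.
#' @param rendition_jitter_cv per-parameter rendition-to-rendition
#'   coefficient of variation; a named vector with entries `f0`, `decay`,
#'   `asym`, `dur`, `amp` (a single unnamed number is recycled to all five).
#' @param noise_floor additive white-noise RMS relative to signal RMS.
#' @param seed integer root seed.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_birds = 17,
                         renditions_per_context = 30,
                         probe_renditions_per_context = 0,
                         rate_hz = 44100,
                         syllable_count = 4,
                         f0_base_hz = 600,
                         f0_spacing_hz = 60,
                         f0_context_shift = 0.05,
                         bandwidth_effect = 0.3,
                         asym_effect = 0.4,
                         rendition_jitter_cv = c(f0 = 0.02, decay = 0.15,
                                                 asym = 0.20, dur = 0.08,
                                                 amp = 0.12),
                         noise_floor = 0.01,
                         seed = 1) {
  if (length(rendition_jitter_cv) == 1 && is.null(names(rendition_jitter_cv))) {
    rendition_jitter_cv <- c(f0 = rendition_jitter_cv, decay = rendition_jitter_cv,
                             asym = rendition_jitter_cv, dur = rendition_jitter_cv,
                             amp = rendition_jitter_cv)
  }
  need <- c("f0", "decay", "asym", "dur", "amp")
  if (!all(need %in% names(rendition_jitter_cv)))
    stop2("rendition_jitter_cv must name ", paste(need, collapse = ", "))
  cfg <- list(n_birds = as.integer(n_birds),
              renditions_per_context = as.integer(renditions_per_context),
              probe_renditions_per_context = as.integer(probe_renditions_per_context),
              rate_hz = rate_hz, syllable_count = as.integer(syllable_count),
              f0_base_hz = f0_base_hz, f0_spacing_hz = f0_spacing_hz,
              f0_context_shift = f0_context_shift,
              bandwidth_effect = bandwidth_effect, asym_effect = asym_effect,
              rendition_jitter_cv = rendition_jitter_cv[need],
              noise_floor = noise_floor, seed = as.integer(seed))
  with(cfg, {
    if (n_birds < 1 || renditions_per_context < 1 || syllable_count < 1)
      stop2("all counts must be >= 1")
    if (probe_renditions_per_context < 0) stop2("probe count must be >= 0")
    if (rate_hz <= 0) stop2("rate_hz must be > 0")
    if (f0_context_shift < 0 || bandwidth_effect < 0 || asym_effect < 0)
      stop2("effect sizes must be >= 0")
    if (any(rendition_jitter_cv < 0) || noise_floor < 0)
      stop2("jitter cv and noise_floor must be >= 0")
    if (!all(vapply(list(rate_hz, f0_base_hz, f0_spacing_hz, f0_context_shift,
                         bandwidth_effect, asym_effect, noise_floor),
                    is_scalar_num, TRUE)))
      stop2("non-finite parameter in synth_config")
  })
  structure(cfg, class = "synth_config")
}

#' Construct a motif waveform object
#'
#' @param samples numeric amplitude sequence.
#' @param rate_hz sampling rate in Hz.
#' @param bird_id,context,role,rendition_id labels.
#' @return a `motif_wav` object.
#' @export
motif_waveform <- function(samples, rate_hz, bird_id, context,
                           role = "training", rendition_id = 1L) {
  if (length(samples) < 1 || !all(is.finite(samples)))
    stop2("motif samples must be a non-empty finite sequence")
  if (rate_hz <= 0) stop2("rate_hz must be > 0")
  context <- match.arg(context, c("courtship", "noncourtship"))
  role <- match.arg(role, c("training", "probe"))
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 bird_id = as.character(bird_id), context = context,
                 role = role, rendition_id = rendition_id),
            class = "motif_wav")
}

#' @export
print.motif_wav <- function(x, ...) {
  cat(sprintf("<motif_wav %s %s %s #%s: %d samples @ %g Hz (%.0f ms)>\n",
              x$bird_id, x$context, x$role, x$rendition_id,
              length(x$samples), x$rate_hz,
              1000 * length(x$samples) / x$rate_hz))
  invisible(x)
}

bird_id_of <- function(i) sprintf("bird%02d", i)

# Per-bird stable song profile: syllable f0 ratios, duration pattern, baseline
# harmonic decay. Drawn from the bird's own stream so adding birds or
# renditions never perturbs the others.
bird_profile <- function(config, bird_idx) {
  with_local_seed(derive_seed(config$seed, bird_id_of(bird_idx), "profile"), {
    k <- config$syllable_count
    list(
      f0_hz = config$f0_base_hz + (bird_idx - 1) * config$f0_spacing_hz,
      syl_f0_ratio = exp(stats::runif(k, log(0.8), log(1.3))),
      syl_dur_s = stats::runif(k, 0.06, 0.09),
      gap_s = stats::runif(max(k - 1, 1), 0.012, 0.022),
      decay_base = stats::runif(1, 3.0, 4.5),
      asym_base = 0.2
    )
  })
}

# Piecewise-linear attack/decay envelope on [0, 1]; attack fraction shrinks
# as the asymmetry parameter grows (fast attack, slow decay). The tent is the
# pointwise minimum of the attack and decay lines.
tent_env <- function(u, asym) {
  a <- 0.5 / (1 + asym)
  v <- u / a
  w <- (1 - u) / (1 - a)
  0.5 * (v + w - abs(v - w))
}

synth_syllable <- function(n, rate_hz, f0, decay, asym, amp, band_top = 8000,
                           pulse_floor = 0.55) {
  t <- (seq_len(n) - 0.5) / rate_hz
  n_harm <- max(1L, min(12L, floor(band_top / f0)))
  carrier <- numeric(n)
  # cosine phases make the bare harmonic stack an even, palindromic
  # waveform: time-reversible by construction, so any third-moment
  # asymmetry of the synthesized motif comes from the envelope asymmetry
  # knob, not from the carrier, and the power spectrum is unaffected
  for (h in seq_len(n_harm))
    carrier <- carrier + exp(-(h - 1) / decay) * cos(2 * pi * h * f0 * t)
  # within-period pulsatile envelope: the same attack/decay asymmetry applied
  # at the fundamental-period scale, which is what makes the waveform itself
  # time irreversible (a syllable-scale envelope alone barely does)
  pulse <- tent_env((f0 * t) %% 1, asym)
  pulse <- pulse_floor + (1 - pulse_floor) * pulse
  env <- tent_env((seq_len(n) - 0.5) / n, asym)
  amp * env * pulse * carrier
}

#' Synthesize one motif waveform
#'
#' @param config a [synth_config()].
#' @param bird bird index (1-based) or id string `"birdNN"`.
#' @param context `"courtship"` or `"noncourtship"`.
#' @param rendition rendition index (selects the rendition's RNG stream).
#' @param role `"training"` or `"probe"`.
#' @return a `motif_wav` object.
#' @export
make_motif <- function(config, bird, context, rendition = 1L,
                       role = "training") {
  stopifnot(inherits(config, "synth_config"))
  context <- match.arg(context, c("courtship", "noncourtship"))
  bird_idx <- if (is.character(bird)) as.integer(sub("^bird", "", bird)) else as.integer(bird)
  if (!is.finite(bird_idx) || bird_idx < 1 || bird_idx > config$n_birds)
    stop2("bird out of range")
  prof <- bird_profile(config, bird_idx)
  cv <- config$rendition_jitter_cv
  court <- context == "courtship"
  seed <- derive_seed(config$seed, bird_id_of(bird_idx), context, role, rendition)
  x <- with_local_seed(seed, {
    k <- config$syllable_count
    f0s <- prof$f0_hz * prof$syl_f0_ratio *
      (1 + if (court) config$f0_context_shift else 0) *
      exp(stats::rnorm(k, 0, cv[["f0"]]))
    decay <- prof$decay_base *
      (1 + if (court) 0 else config$bandwidth_effect) *
      exp(stats::rnorm(1, 0, cv[["decay"]]))
    asym <- (prof$asym_base + if (court) 0 else config$asym_effect) *
      exp(stats::rnorm(1, 0, cv[["asym"]]))
    durs <- prof$syl_dur_s * exp(stats::rnorm(k, 0, cv[["dur"]]))
    amps <- exp(stats::rnorm(k, 0, cv[["amp"]]))
    if (!all(is.finite(c(f0s, decay, asym, durs, amps))))
      stop2("non-finite synthesis parameter")
    pad <- numeric(round(0.010 * config$rate_hz))
    pieces <- list(pad)
    for (s in seq_len(k)) {
      n <- max(8L, as.integer(round(durs[s] * config$rate_hz)))
      pieces[[length(pieces) + 1L]] <-
        synth_syllable(n, config$rate_hz, f0s[s], decay, asym, amps[s])
      if (s < k)
        pieces[[length(pieces) + 1L]] <-
          numeric(round(prof$gap_s[min(s, length(prof$gap_s))] * config$rate_hz))
    }
    pieces[[length(pieces) + 1L]] <- pad
    x <- unlist(pieces, use.names = FALSE)
    r <- rms(x)
    if (!is.finite(r) || r == 0) stop2("degenerate silence-only motif")
    x <- x / r * 0.1
    if (config$noise_floor > 0)
      x <- x + stats::rnorm(length(x), 0, config$noise_floor * rms(x))
    x
  })
  motif_waveform(x, config$rate_hz, bird_id_of(bird_idx), context, role,
                 rendition)
}

#' Generate a full synthetic motif dataset with ground truth
#'
#' One motif family per bird; equal renditions per context. The ground-truth
#' table records the generative parameters actually drawn for each motif so
#' recovery can be tested downstream.
#'
#' @param config a [synth_config()].
#' @return a `motif_dataset`: list with `motifs` (list of `motif_wav`) and
#'   `truth` (data frame of per-motif generative parameters).
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_birds < 1) stop2("empty dataset: n_birds must be >= 1")
  motifs <- list()
  rows <- list()
  for (b in seq_len(config$n_birds)) {
    prof <- bird_profile(config, b)
    for (context in c("courtship", "noncourtship")) {
      n_train <- config$renditions_per_context
      n_probe <- config$probe_renditions_per_context
      for (r in seq_len(n_train + n_probe)) {
        role <- if (r <= n_train) "training" else "probe"
        m <- make_motif(config, b, context, r, role)
        motifs[[length(motifs) + 1L]] <- m
        rows[[length(rows) + 1L]] <- data.frame(
          bird_id = m$bird_id, context = context, role = role, rendition = r,
          f0_base_hz = prof$f0_hz, decay_base = prof$decay_base,
          asym_base = prof$asym_base, n_samples = length(m$samples),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(motifs = motifs, truth = do.call(rbind, rows),
                 config = config),
            class = "motif_dataset")
}

#' Configuration for synthetic 2AFC operant sessions
#'
#' Per-trial correctness follows a sigmoidal learning curve
#' `p(day) = p_start + (p_asymptote - p_start) / (1 + exp(-slope (day - inflection_day)))`.
#' Probe trials are interspersed at `probe_rate` and rewarded at
#' `reward_rate` independent of the response; training trials are rewarded
#' at `reward_rate` only when correct (variable-ratio partial reinforcement).
#'
#' @param days number of session days.
#' @param trials_per_day trials per day.
#' @param p_start,p_asymptote starting and asymptotic probability correct.
#' @param inflection_day,slope sigmoid inflection (days) and slope (1/day).
#' @param probe_rate fraction of probe trials (typical operant protocols
#'   use 0.10-0.20).
#' @param reward_rate reward probability (typically 0.75-0.95).
#' @param rt_params list with `correct` and `incorrect` lognormal
#'   `c(meanlog, sdlog)` parameters (seconds); incorrect responses slow down
#'   after the inflection day.
#' @param no_response_rate fraction of trials with no response.
#' @param n_stimuli_per_context distinct stimuli per context.
#' @param seed integer seed.
#' @return a validated `behavior_config` list.
#' @export
behavior_config <- function(days = 30, trials_per_day = 500,
                            p_start = 0.5, p_asymptote = 0.82,
                            inflection_day = 10, slope = 0.6,
                            probe_rate = 0.15, reward_rate = 0.85,
                            rt_params = list(correct = c(meanlog = log(0.8), sdlog = 0.4),
                                             incorrect = c(meanlog = log(1.1), sdlog = 0.4)),
                            no_response_rate = 0.02,
                            n_stimuli_per_context = 30,
                            seed = 1) {
  cfg <- list(days = as.integer(days), trials_per_day = as.integer(trials_per_day),
              p_start = p_start, p_asymptote = p_asymptote,
              inflection_day = inflection_day, slope = slope,
              probe_rate = probe_rate, reward_rate = reward_rate,
              rt_params = rt_params, no_response_rate = no_response_rate,
              n_stimuli_per_context = as.integer(n_stimuli_per_context),
              seed = as.integer(seed))
  with(cfg, {
    if (days < 0) stop2("days must be >= 0")
    if (!(0 <= p_start && p_start <= p_asymptote && p_asymptote <= 1))
      stop2("need 0 <= p_start <= p_asymptote <= 1")
    if (!(probe_rate > 0 && probe_rate < 1)) stop2("probe_rate must be in (0, 1)")
    if (!(reward_rate > 0 && reward_rate <= 1)) stop2("reward_rate must be in (0, 1]")
  })
  structure(cfg, class = "behavior_config")
}

learning_p <- function(cfg, day) {
  cfg$p_start + (cfg$p_asymptote - cfg$p_start) /
    (1 + exp(-cfg$slope * (day - cfg$inflection_day)))
}

#' Simulate 2AFC operant trial records
#'
#' @param config a [behavior_config()].
#' @return data frame of trial records with columns `day, trial,
#'   stimulus_id, context, probe, response, correct, rewarded, rt_s,
#'   reward_balanced`.
#' @export
make_behavior_sessions <- function(config) {
  stopifnot(inherits(config, "behavior_config"))
  if (config$days == 0) stop2("empty session: days must be >= 1")
  stim <- data.frame(
    stimulus_id = c(sprintf("C%02d", seq_len(config$n_stimuli_per_context)),
                    sprintf("N%02d", seq_len(config$n_stimuli_per_context))),
    context = rep(c("courtship", "noncourtship"),
                  each = config$n_stimuli_per_context),
    stringsAsFactors = FALSE)
  with_local_seed(derive_seed(config$seed, "behavior"), {
    out <- vector("list", config$days)
    for (d in seq_len(config$days)) {
      n <- config$trials_per_day
      idx <- sample.int(nrow(stim), n, replace = TRUE)
      probe <- stats::runif(n) < config$probe_rate
      responded <- stats::runif(n) >= config$no_response_rate
      p <- learning_p(config, d)
      correct <- ifelse(responded, stats::runif(n) < p, NA)
      context <- stim$context[idx]
      correct_side <- ifelse(context == "courtship", "A", "B")
      response <- ifelse(!responded, "none",
                         ifelse(correct == 1, correct_side,
                                ifelse(correct_side == "A", "B", "A")))
      rewarded <- ifelse(!responded, FALSE,
                         ifelse(probe, stats::runif(n) < config$reward_rate,
                                (correct == 1) & (stats::runif(n) < config$reward_rate)))
      slow <- responded & (correct == 0) & (d > config$inflection_day)
      pr <- config$rt_params
      rt <- ifelse(slow,
                   stats::rlnorm(n, pr$incorrect[["meanlog"]], pr$incorrect[["sdlog"]]),
                   stats::rlnorm(n, pr$correct[["meanlog"]], pr$correct[["sdlog"]]))
      rt[!responded] <- NA
      out[[d]] <- data.frame(day = d, trial = seq_len(n),
                             stimulus_id = stim$stimulus_id[idx],
                             context = context, probe = probe,
                             response = response,
                             correct = as.logical(correct),
                             rewarded = rewarded, rt_s = rt,
                             reward_balanced = TRUE,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
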