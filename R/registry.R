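# Feature registry: named specifications mapping one operation (with fixed
# parameters) to its ordered output feature names, and the extractor that
# runs a registry over one motif.

#' Create a feature specification
#'
#' @param operation_name operation identifier (HCTSA-style naming).
#' @param parameters named list of operation parameters (serializable).
#' @param output_feature_names ordered output names, unique within a registry.
#' @param fn function `(samples, rate_hz, seed, cache)` returning a named
#'   numeric vector matching `output_feature_names`; `cache` is a per-motif
#'   memoization environment shared across the registry.
#' @return a `feature_spec` object.
#' @export
feature_spec <- function(operation_name, parameters, output_feature_names, fn) {
  stopifnot(is.character(operation_name), is.list(parameters),
            is.character(output_feature_names), is.function(fn))
  structure(list(operation_name = operation_name, parameters = parameters,
                 output_feature_names = output_feature_names, fn = fn),
            class = "feature_spec")
}

registry_feature_names <- function(registry) {
  unlist(lapply(registry, `[[`, "output_feature_names"), use.names = FALSE)
}

validate_registry <- function(registry) {
  nm <- registry_feature_names(registry)
  if (anyDuplicated(nm))
    stop2("duplicate feature names in registry: ",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  invisible(nm)
}

#' Default feature registry
#'
#' A compact bank covering the operation families used for motif
#' classification: time irreversibility (CO_trev, DK_trev), autocorrelation,
#' automutual information, spectral summaries under several
#' transform/window combinations, symbolic dynamics, permutation entropy,
#' AR model fits, bootstrap stationarity, walker simulation, local
#' forecasting and surprise, successive-difference statistics, iterated
#' differencing, and the approximate SAP-style 12-feature baseline.
#'
#' @return a list of [feature_spec()] objects.
#' @export
default_registry <- function() {
  # deterministic probe series used only to enumerate output names
  probe <- sin(seq_len(500)) + seq_len(500) * 1e-4
  reg <- list(
    feature_spec("CO_trev", list(tau = list(1, 2, 3, "acf_zero", "ami_min")),
                 c("co_trev_tau1", "co_trev_tau2", "co_trev_tau3",
                   "co_trev_acfzero", "co_trev_amimin"),
                 function(x, fs, seed, cache)
                   c(co_trev_tau1 = co_trev(x, 1), co_trev_tau2 = co_trev(x, 2),
                     co_trev_tau3 = co_trev(x, 3),
                     co_trev_acfzero = co_trev(x, "acf_zero", cache),
                     co_trev_amimin = co_trev(x, "ami_min", cache))),
    feature_spec("DK_trev", list(tau = 1:4, M = 3),
                 paste0("dk_trev_tau", 1:4),
                 function(x, fs, seed, cache)
                   stats::setNames(vapply(1:4, function(t) dk_trev(x, t), 0),
                                   paste0("dk_trev_tau", 1:4))),
    feature_spec("AC", list(lags = c(1:10, 14, 21, 33)),
                 c(paste0("acf_lag", c(1:10, 14, 21, 33)), "acf_firstzero"),
                 function(x, fs, seed, cache) acf_features(x, cache = cache)),
    feature_spec("CO_Histogram_AddNoise",
                 list(lags = 1:5, n_bins = 8, noise_levels = seq(0, 1, 0.25)),
                 c(paste0("ami_lag", 1:5), "ami_firstmin", "ami_noise_slope"),
                 function(x, fs, seed, cache) ami_features(x, seed = seed, cache = cache)),
    feature_spec("EN_PermEn", list(m = c(3, 4), tau = c(1, 2)),
                 c(sprintf("permen_m3_tau1_scale%d", c(1, 2, 3, 5)),
                   "permen_m3_tau2_scale1", "permen_m4_tau1_scale1"),
                 function(x, fs, seed, cache)
                   c(permutation_entropy(x, 3, 1, c(1, 2, 3, 5)),
                     permutation_entropy(x, 3, 2, 1),
                     permutation_entropy(x, 4, 1, 1))),
    feature_spec("SB", list(alphabet_sizes = 2:5),
                 names(symbolic_features(probe)),
                 function(x, fs, seed, cache) symbolic_features(x)),
    feature_spec("MF", list(orders = 1:8, horizons = c(1, 2, 5, 10),
                            n_segments = 5),
                 names(ar_features(probe)),
                 function(x, fs, seed, cache) ar_features(x)),
    feature_spec("SY", list(window_fractions = c(0.05, 0.2), n_boot = 100),
                 c(names(stationarity_features(probe, 0.05)),
                   names(stationarity_features(probe, 0.2))[1:4]),
                 function(x, fs, seed, cache)
                   c(stationarity_features(x, 0.05, seed = seed),
                     stationarity_features(x, 0.2, seed = seed + 1)[1:4])),
    feature_spec("PH_walker", list(attraction = c(0.1, 0.5, 0.9)),
                 as.vector(vapply(c(0.1, 0.5, 0.9), function(a)
                   names(walker_features(c(0, 1, 0), a)), character(3))),
                 function(x, fs, seed, cache)
                   c(walker_features(x, 0.1), walker_features(x, 0.5),
                     walker_features(x, 0.9))),
    feature_spec("FC", list(train_windows = c(1, 2, 3, 5, 8, 13, 21),
                            memory = c(5, 10)),
                 names(forecast_features(probe)),
                 function(x, fs, seed, cache) forecast_features(x)),
    feature_spec("MD_hrv", list(pnn_thresholds = c(0.1, 0.25, 0.5, 1, 2)),
                 names(diffstats_hrv(c(0, 1, 0))),
                 function(x, fs, seed, cache) diffstats_hrv(x)),
    feature_spec("PP_iterate", list(n_iter = 3),
                 c("pp_slope_sd", "pp_slope_ac1", "pp_slope_specmed"),
                 function(x, fs, seed, cache) iterated_preprocess_compare(x)$slopes)
  )
  sp <- list()
  for (method in c("welch", "fourier", "periodogram"))
    for (window in c("hamming", "rectangular")) {
      m <- method; wd <- window
      sp[[length(sp) + 1L]] <- feature_spec(
        "SP_summaries", list(method = m, window = wd),
        names(psd_summaries(probe, 2, m, wd)),
        local({
          m2 <- m; w2 <- wd
          function(x, fs, seed, cache) psd_summaries(x, fs, m2, w2)
        }))
    }
  reg <- c(reg, sp,
           list(feature_spec("SAP_baseline", list(),
                             paste0("sap_", c("mean_pitch", "mean_amplitude",
                                              "mean_meanfreq", "var_meanfreq",
                                              "mean_wiener", "var_wiener",
                                              "mean_goodness", "var_goodness",
                                              "mean_fm", "var_fm",
                                              "mean_am", "var_am")),
                             function(x, fs, seed, cache)
                               baseline_spectral_features(
                                 motif_waveform(x, fs, "x", "courtship")))))
  validate_registry(reg)
  reg
}

#' Extract every registered feature from one motif
#'
#' Runs each specification over the motif's samples, collecting values and
#' NA invalid-markers; operation failures are logged (as an attribute) and
#' never abort the motif. Stochastic operations receive seeds derived from
#' `seed` and the operation name, so repeated extraction is bit-identical.
#'
#' @param w a `motif_wav`.
#' @param registry list of [feature_spec()]s (default [default_registry()]).
#' @param seed integer root seed for stochastic operations.
#' @return named numeric `feature_vector` (attribute `motif` carries the
#'   labels, attribute `failures` any operation error messages).
#' @export
extract_all <- function(w, registry = default_registry(), seed = 1) {
  stopifnot(inherits(w, "motif_wav"))
  if (length(registry) == 0) stop2("registry must be non-empty")
  all_names <- validate_registry(registry)
  out <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
  failures <- character()
  cache <- new.env(parent = emptyenv())
  for (spec in registry) {
    v <- tryCatch(
      spec$fn(w$samples, w$rate_hz, derive_seed(seed, spec$operation_name),
              cache),
      error = function(e) {
        failures[[spec$operation_name]] <<- conditionMessage(e)
        NULL
      })
    if (!is.null(v)) {
      if (!identical(names(v), spec$output_feature_names))
        v <- v[spec$output_feature_names]
      v[!is.finite(v)] <- NA_real_
      out[spec$output_feature_names] <- as.numeric(v)
    }
  }
  structure(out, class = "feature_vector",
            motif = list(bird_id = w$bird_id, context = w$context,
                         role = w$role, rendition_id = w$rendition_id),
            failures = failures)
}
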