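# End-to-end pipeline commands tying the stages together, plus YAML run
# configuration and manifest/reporting plumbing. Each command is
# reproducible from its config and seed alone.

# classed errors so the command-line wrapper can map them to exit codes
stop_config <- function(...) {
  stop(structure(class = c("songsift_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
stop_data <- function(...) {
  stop(structure(class = c("songsift_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible(NULL))
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  message(msg)
  logfile <- file.path(config$out_dir, "run.log")
  if (dir.exists(config$out_dir))
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  invisible(NULL)
}

#' Default run configuration
#'
#' @return nested list of configuration blocks with package defaults.
#' @export
default_run_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    out_dir = "songsift_out",
    log_level = "info",
    synthgen = local({
      sc <- unclass(synth_config()); sc[names(sc) != "seed"]
    }),
    behavior = local({
      bc <- unclass(behavior_config()); bc[names(bc) != "seed"]
    }),
    classify = list(n_trees = 300L, k_folds = 10L, n_iterations = 10L,
                    top_k = 50L, random_iterations = 200L,
                    per_bird = FALSE, combined = TRUE),
    behavior_analysis = list(alpha = 0.05, min_responses = 20L,
                             p_above_method = "empirical",
                             threshold_method = "prediction")
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop_config("unknown configuration key: ", full)
    if (is.list(base[[key]]) && is.list(override[[key]]))
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    else base[[key]] <- override[[key]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take package defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e)
                       stop_config("unparsable YAML: ", conditionMessage(e)))
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  if (!identical(as.integer(cfg$schema_version), 1L))
    stop_config("unsupported schema_version: ", cfg$schema_version)
  cfg
}

motif_filename <- function(bird_id, context, rendition, role) {
  sprintf("%s_%s_r%03d_%s.wav", bird_id, context, rendition, role)
}

parse_motif_filename <- function(name) {
  bn <- basename(name)
  m <- regmatches(bn, regexec(
    "^([A-Za-z0-9]+)_([a-z]+)_r([0-9]+)_([a-z]+)\\.wav$", bn))[[1]]
  if (length(m) != 5) return(NULL)
  list(bird = m[2], context = m[3],
       rendition = as.integer(m[4]), role = m[5])
}

write_manifest <- function(config, command, files, extra = list()) {
  manifest <- c(list(command = command, seed = config$seed,
                     n_files = length(files), files = as.list(files)),
                extra)
  path <- file.path(config$out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Simulate stimuli and behavior to disk
#'
#' Generates the synthetic motif dataset and one operant subject's sessions,
#' writing WAV stimuli, the ground-truth TSV, the trials CSV, and a manifest
#' recording seeds and file lists.
#'
#' @param config run configuration (see [read_run_config()]).
#' @return invisible list with `manifest`, `wav_dir`, `truth_tsv`,
#'   `trials_csv`, and the in-memory `dataset`.
#' @export
run_simulate <- function(config = default_run_config()) {
  scfg <- tryCatch(
    do.call(synth_config, c(config$synthgen, list(seed = config$seed))),
    error = function(e) stop_config("invalid synthgen block: ",
                                    conditionMessage(e)))
  bcfg <- tryCatch(
    do.call(behavior_config,
            c(config$behavior, list(seed = derive_seed(config$seed, "behavior")))),
    error = function(e) stop_config("invalid behavior block: ",
                                    conditionMessage(e)))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wav_dir <- file.path(config$out_dir, "wav")
  dir.create(wav_dir, showWarnings = FALSE)
  ds <- make_dataset(scfg)
  files <- character(length(ds$motifs))
  for (i in seq_along(ds$motifs)) {
    w <- ds$motifs[[i]]
    tr <- ds$truth[i, ]
    f <- file.path(wav_dir, motif_filename(tr$bird_id, tr$context,
                                           tr$rendition, tr$role))
    write_wav(w$samples, w$rate_hz, f, format = "float32")
    files[i] <- f
  }
  truth_tsv <- file.path(config$out_dir, "truth.tsv")
  utils::write.table(ds$truth, truth_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  trials <- make_behavior_sessions(bcfg)
  trials_csv <- file.path(config$out_dir, "trials.csv")
  write_trials_csv(trials, trials_csv)
  manifest <- write_manifest(config, "simulate",
                             c(files, truth_tsv, trials_csv),
                             list(n_motifs = length(ds$motifs),
                                  n_trials = nrow(trials)))
  log_msg(config, "simulate: ", length(ds$motifs), " motifs, ",
          nrow(trials), " trials -> ", config$out_dir)
  invisible(list(manifest = manifest, wav_dir = wav_dir,
                 truth_tsv = truth_tsv, trials_csv = trials_csv,
                 dataset = ds))
}

#' Extract a raw feature matrix from a directory of WAV files
#'
#' Reads every `*.wav` whose name encodes `bird/context/rendition/role`,
#' preprocesses, runs the registry, and writes the raw matrix as TSV with a
#' provenance sidecar. Unreadable or unparsable files are logged and
#' skipped; the run aborts only if nothing remains.
#'
#' @param config run configuration.
#' @param wav_dir directory of WAV stimuli (default `<out_dir>/wav`).
#' @param registry feature registry (default [default_registry()]).
#' @return invisible list with `features_tsv` and the `feature_matrix`.
#' @export
run_extract <- function(config = default_run_config(),
                        wav_dir = file.path(config$out_dir, "wav"),
                        registry = default_registry()) {
  paths <- sort(list.files(wav_dir, pattern = "\\.wav$", full.names = TRUE))
  if (length(paths) == 0) stop_data("no WAV files in ", wav_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  nm <- validate_registry(registry)
  rows <- list(); idx <- list(); skipped <- character()
  for (pth in paths) {
    meta <- parse_motif_filename(pth)
    if (is.null(meta)) {
      skipped <- c(skipped, pth)
      log_msg(config, "extract: skipping unparsable name ", basename(pth))
      next
    }
    wav <- tryCatch(read_wav(pth), error = function(e) NULL)
    if (is.null(wav)) {
      skipped <- c(skipped, pth)
      log_msg(config, "extract: skipping unreadable WAV ", basename(pth))
      next
    }
    w <- motif_waveform(wav$samples, wav$rate_hz, meta$bird, meta$context,
                        role = meta$role, rendition_id = meta$rendition)
    fv <- extract_all(preprocess_waveform(w), registry,
                      seed = derive_seed(config$seed, basename(pth)))
    rows[[length(rows) + 1L]] <- as.numeric(fv)
    idx[[length(idx) + 1L]] <- data.frame(bird = meta$bird,
                                          context = meta$context,
                                          role = meta$role,
                                          rendition = meta$rendition)
  }
  if (length(rows) == 0)
    stop_data("every WAV in ", wav_dir, " was skipped")
  vals <- do.call(rbind, rows)
  colnames(vals) <- nm
  M <- feature_matrix(vals, do.call(rbind, idx), state = "raw",
                      provenance = list(registry_hash = registry_hash(registry),
                                        seed = config$seed,
                                        skipped = skipped))
  features_tsv <- file.path(config$out_dir, "features_raw.tsv")
  write_feature_tsv(M, features_tsv)
  write_manifest(config, "extract", features_tsv,
                 list(n_motifs = nrow(vals), n_skipped = length(skipped),
                      registry_hash = registry_hash(registry)))
  log_msg(config, "extract: ", nrow(vals), " motifs (",
          length(skipped), " skipped) -> ", features_tsv)
  invisible(list(features_tsv = features_tsv, matrix = M))
}

classify_one <- function(M, config, tag) {
  ccfg <- config$classify
  seed <- derive_seed(config$seed, "classify", tag)
  train <- M$index$role != "probe"
  y <- M$index$context[train]
  if (length(unique(y)) < 2)
    stop_data("training rows contain a single class")
  Xtr <- M$values[train, , drop = FALSE]
  cv <- kfold_cv(Xtr, y, k = ccfg$k_folds, n_iterations = ccfg$n_iterations,
                 seed = derive_seed(seed, "cv"), n_trees = ccfg$n_trees)
  model <- train_bgdt(Xtr, y, n_trees = ccfg$n_trees,
                      seed = derive_seed(seed, "final"))
  ranking <- importance_ranking(model)
  out <- list(tag = tag, seed = seed, cv = cv, model = model,
              ranking = ranking)
  if (!is.null(ccfg$top_k) && ccfg$top_k >= 1 &&
      ccfg$top_k <= ncol(Xtr)) {
    out$top_k <- top_k_evaluation(Xtr, y, ranking, k = ccfg$top_k,
                                  folds = ccfg$k_folds,
                                  n_iterations = ccfg$n_iterations,
                                  seed = derive_seed(seed, "topk"),
                                  n_trees = ccfg$n_trees)
    if (!is.null(ccfg$random_iterations) && ccfg$random_iterations > 0)
      out$random <- random_subset_benchmark(
        Xtr, y, k = ccfg$top_k, n_iterations = ccfg$random_iterations,
        folds = ccfg$k_folds, seed = derive_seed(seed, "random"),
        reference_accuracy = out$top_k$median_accuracy,
        n_trees = ccfg$n_trees)
  }
  if (any(!train)) {
    sc <- predict_scores(model, M$values[!train, , drop = FALSE])
    out$probe <- data.frame(M$index[!train, , drop = FALSE],
                            score = sc,
                            predicted = labels_from_scores(sc),
                            confidence = confidence_scores(
                              sc, M$index$context[!train]))
  }
  out
}

classification_summary <- function(res) {
  s <- list(tag = res$tag, seed = res$seed,
            median_accuracy = res$cv$median_accuracy,
            iteration_accuracy = res$cv$iteration_accuracy,
            n_features = length(res$model$feature_names),
            top_features = utils::head(res$ranking$feature, 10))
  if (!is.null(res$top_k))
    s$top_k_accuracy <- res$top_k$median_accuracy
  if (!is.null(res$random))
    s <- c(s, list(random_subset_max = res$random$max_accuracy,
                   random_subset_mean = mean(res$random$accuracies),
                   all_random_below_top_k = res$random$all_below_reference))
  if (!is.null(res$probe))
    s$probe_accuracy <- mean(res$probe$predicted == res$probe$context)
  s
}

#' Normalize a raw matrix and run the classification analyses
#'
#' Applies the fixed normalization pipeline, cross-validates the combined
#' (all-birds) classifier and/or one classifier per bird, ranks feature
#' importance, optionally evaluates the top-k subset against a random-subset
#' Monte Carlo benchmark, and scores probe-role motifs with the final model
#' (probe rows are never used for training). Writes CSV/JSON reports.
#'
#' @param config run configuration.
#' @param features raw `feature_matrix`, or path to its TSV.
#' @return invisible list with `combined` and/or `per_bird` results and
#'   `report_json`.
#' @export
run_classify <- function(config = default_run_config(),
                         features = file.path(config$out_dir,
                                              "features_raw.tsv")) {
  M <- if (inherits(features, "feature_matrix")) features
       else read_feature_tsv(features)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (isTRUE(config$classify$combined)) {
    per_bird_raw <- lapply(split(seq_len(nrow(M$values)), M$index$bird),
                           function(ix)
                             feature_matrix(M$values[ix, , drop = FALSE],
                                            M$index[ix, , drop = FALSE],
                                            provenance = M$provenance))
    cmb <- assemble_combined(per_bird_raw)
    out$combined <- classify_one(cmb, config, "combined")
    utils::write.csv(out$combined$cv$per_motif,
                     file.path(config$out_dir, "cv_combined.csv"),
                     row.names = FALSE)
    utils::write.csv(out$combined$ranking,
                     file.path(config$out_dir, "importance_combined.csv"),
                     row.names = FALSE)
    if (!is.null(out$combined$probe))
      utils::write.csv(out$combined$probe,
                       file.path(config$out_dir, "probe_scores_combined.csv"),
                       row.names = FALSE)
  }
  if (isTRUE(config$classify$per_bird)) {
    out$per_bird <- lapply(split(seq_len(nrow(M$values)), M$index$bird),
                           function(ix) {
      Mb <- normalize_features(
        feature_matrix(M$values[ix, , drop = FALSE],
                       M$index[ix, , drop = FALSE],
                       provenance = M$provenance))
      classify_one(Mb, config, paste0("bird", Mb$index$bird[1]))
    })
  }
  if (length(out) == 0) stop_config("neither combined nor per_bird requested")
  report <- lapply(out[!vapply(out, is.null, TRUE)], function(res) {
    if (res_is_single <- !is.null(res$tag)) classification_summary(res)
    else lapply(res, classification_summary)
  })
  report_json <- file.path(config$out_dir, "classify_report.json")
  jsonlite::write_json(c(list(seed = config$seed), report), report_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$report_json <- report_json
  if (!is.null(out$combined))
    log_msg(config, "classify: combined median accuracy ",
            sprintf("%.1f%%", 100 * out$combined$cv$median_accuracy))
  invisible(out)
}

#' Analyze an operant trials file end to end
#'
#' Learning assessment (sigmoid + run criterion), probe generalization, and
#' inter-stimulus summaries, written as JSON/CSV reports.
#'
#' @param config run configuration.
#' @param trials trials data frame, or path to a trials CSV.
#' @return invisible list with `assessment`, `probes`, and `report_json`.
#' @export
run_behave <- function(config = default_run_config(),
                       trials = file.path(config$out_dir, "trials.csv")) {
  tr <- if (is.data.frame(trials)) trials else
    tryCatch(read_trials_csv(trials),
             error = function(e) stop_data(conditionMessage(e)))
  ba <- config$behavior_analysis
  assessment <- assess_learning(tr, alpha = ba$alpha,
                                p_above_method = ba$p_above_method,
                                threshold_method = ba$threshold_method,
                                min_responses = ba$min_responses)
  probes <- probe_performance(tr, alpha = ba$alpha)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    seed = config$seed,
    learned = assessment$learned,
    learning_day = if (assessment$learned) assessment$learning_day else NULL,
    threshold = assessment$threshold,
    p_above = assessment$p_above,
    run_length = if (is.finite(assessment$run_length))
      assessment$run_length else NULL,
    n_days = assessment$n_days,
    reason = assessment$reason,
    sigmoid = if (isTRUE(assessment$fit$converged))
      assessment$fit[c("L", "U", "d0", "s", "u_se")] else NULL,
    generalized = probes$generalized,
    probe_pct_correct = probes$probe_pct_correct,
    training_pct_correct = probes$training_pct_correct)
  report_json <- file.path(config$out_dir, "behavior_report.json")
  jsonlite::write_json(report, report_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(summarize_sessions(tr, ba$min_responses),
                   file.path(config$out_dir, "daily_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(probes$by_context,
                   file.path(config$out_dir, "probe_by_context.csv"),
                   row.names = FALSE)
  log_msg(config, "behave: ",
          if (assessment$learned)
            paste0("learned on day ", assessment$learning_day)
          else "not learned",
          "; generalized: ", probes$generalized)
  invisible(list(assessment = assessment, probes = probes,
                 report_json = report_json))
}
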