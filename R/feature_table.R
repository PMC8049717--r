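# Feature matrices: assembly of per-motif feature vectors, filtering of
# degenerate columns, and the two-stage normalization (robust sigmoid, then
# unit scaling after aggregating birds).

#' Construct a feature matrix
#'
#' @param values numeric matrix, one row per motif, named feature columns.
#' @param index data.frame with columns `bird`, `context`, `role`,
#'   `rendition`, one row per motif row.
#' @param state normalization state: `"raw"`, `"sigmoid"` or `"unit"`.
#' @param dropped named character vector of dropped feature -> reason.
#' @param provenance list of free-form provenance fields.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, index, state = "raw",
                           dropped = character(), provenance = list()) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(index))
  if (nrow(values) != nrow(index))
    stop2("values and index disagree on row count")
  need <- c("bird", "context", "role", "rendition")
  if (!all(need %in% names(index)))
    stop2("index must have columns: ", paste(need, collapse = ", "))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop2("feature names must be present and unique")
  state <- match.arg(state, c("raw", "sigmoid", "unit"))
  structure(list(values = values, index = index[need], state = state,
                 dropped = dropped, provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d motifs x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  birds: %d  contexts: %s  dropped so far: %d\n",
              length(unique(x$index$bird)),
              paste(unique(x$index$context), collapse = "/"),
              length(x$dropped)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# stable short hash describing a registry (names, parameters, outputs)
registry_hash <- function(registry) {
  desc <- vapply(registry, function(s)
    paste(s$operation_name,
          paste(deparse(s$parameters), collapse = ""),
          paste(s$output_feature_names, collapse = ","), sep = "|"),
    character(1))
  sprintf("%08x", derive_seed(0, paste(desc, collapse = ";")))
}

#' Extract a raw feature matrix from a motif dataset
#'
#' Preprocesses every motif waveform and runs the registry over it, stacking
#' the feature vectors into a raw `feature_matrix`.
#'
#' @param dataset a `motif_dataset` from [make_dataset()].
#' @param registry feature registry (default [default_registry()]).
#' @param seed root seed for stochastic operations.
#' @param preprocess apply [preprocess_waveform()] first (default TRUE).
#' @return a raw `feature_matrix`.
#' @export
collect_features <- function(dataset, registry = default_registry(), seed = 1,
                             preprocess = TRUE) {
  stopifnot(inherits(dataset, "motif_dataset"))
  nm <- validate_registry(registry)
  vals <- matrix(NA_real_, nrow = length(dataset$motifs), ncol = length(nm),
                 dimnames = list(NULL, nm))
  for (i in seq_along(dataset$motifs)) {
    w <- dataset$motifs[[i]]
    if (preprocess) w <- preprocess_waveform(w)
    vals[i, ] <- as.numeric(extract_all(w, registry,
                                        seed = derive_seed(seed, i)))
  }
  idx <- data.frame(bird = dataset$truth$bird_id,
                    context = dataset$truth$context,
                    role = dataset$truth$role,
                    rendition = dataset$truth$rendition)
  feature_matrix(vals, idx, state = "raw",
                 provenance = list(registry_hash = registry_hash(registry),
                                   seed = seed,
                                   n_operations = length(registry)))
}

#' Drop degenerate feature columns
#'
#' Removes any column that is constant, or contains an invalid-marker (NA)
#' or non-finite value anywhere: only features extracted consistently across
#' every motif are retained.
#'
#' @param M a `feature_matrix`.
#' @return the filtered `feature_matrix`; dropped names and reasons are
#'   recorded in `$dropped`.
#' @export
filter_features <- function(M) {
  stopifnot(inherits(M, "feature_matrix"))
  v <- M$values
  bad_na <- apply(v, 2, function(col) any(!is.finite(col)))
  rng <- apply(v, 2, function(col) if (any(!is.finite(col))) c(0, 1)
               else range(col))
  bad_const <- !bad_na & (rng[1, ] == rng[2, ])
  reasons <- character(0)
  reasons[colnames(v)[bad_na]] <- "invalid-marker or non-finite value"
  reasons[colnames(v)[bad_const]] <- "constant"
  keep <- !(bad_na | bad_const)
  if (!any(keep)) stop2("all feature columns dropped during filtering")
  M$values <- v[, keep, drop = FALSE]
  M$dropped <- c(M$dropped, reasons)
  M
}

#' Robust sigmoidal normalization
#'
#' Per column: `v -> 1 / (1 + exp(-(v - median) / (1.35 * IQR)))`. The 1.35
#' factor standardizes the IQR to a Gaussian standard deviation, making the
#' transform resistant to outliers. Columns with zero IQR cannot be scaled
#' and are dropped.
#'
#' @param M a filtered `feature_matrix`.
#' @return the transformed `feature_matrix` with `state = "sigmoid"`.
#' @export
robust_sigmoid <- function(M) {
  stopifnot(inherits(M, "feature_matrix"))
  v <- M$values
  med <- apply(v, 2, stats::median)
  iqr <- apply(v, 2, stats::IQR)
  zero <- iqr == 0
  if (all(zero)) stop2("all feature columns have zero IQR")
  if (any(zero)) {
    reasons <- stats::setNames(rep("zero IQR", sum(zero)),
                               colnames(v)[zero])
    M$dropped <- c(M$dropped, reasons)
    v <- v[, !zero, drop = FALSE]
    med <- med[!zero]; iqr <- iqr[!zero]
  }
  M$values <- 1 / (1 + exp(-sweep(sweep(v, 2, med), 2, 1.35 * iqr, "/")))
  M$state <- "sigmoid"
  M
}

#' Unit (0-1) scaling
#'
#' Per column: `v -> (v - min) / (max - min)`, so the column minimum maps to
#' 0 and the maximum to 1. Applied after aggregating birds so that the
#' combined matrix is scaled jointly rather than per bird. Columns with
#' `max == min` are dropped.
#'
#' @param M a `feature_matrix` (normally sigmoid-normalized).
#' @return the scaled `feature_matrix` with `state = "unit"`.
#' @export
unit_scale <- function(M) {
  stopifnot(inherits(M, "feature_matrix"))
  v <- M$values
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  flat <- hi == lo
  if (all(flat)) stop2("all feature columns are flat; cannot unit-scale")
  if (any(flat)) {
    reasons <- stats::setNames(rep("flat after sigmoid", sum(flat)),
                               colnames(v)[flat])
    M$dropped <- c(M$dropped, reasons)
    v <- v[, !flat, drop = FALSE]
    lo <- lo[!flat]; hi <- hi[!flat]
  }
  M$values <- sweep(sweep(v, 2, lo), 2, hi - lo, "/")
  M$state <- "unit"
  M
}

#' Full normalization pipeline on one matrix
#'
#' Fixed order: [filter_features()], then [robust_sigmoid()], then
#' [unit_scale()].
#'
#' @param M a raw `feature_matrix`.
#' @return a unit-normalized `feature_matrix`.
#' @export
normalize_features <- function(M) {
  unit_scale(robust_sigmoid(filter_features(M)))
}

#' Aggregate per-bird matrices and normalize jointly
#'
#' Row-concatenates the birds' raw matrices (taking the intersection of
#' feature names when they differ), then runs the full normalization on the
#' aggregate, so the combined matrix reflects context differences rather
#' than bird identity.
#'
#' @param per_bird list of raw `feature_matrix` objects.
#' @return a unit-normalized combined `feature_matrix`.
#' @export
assemble_combined <- function(per_bird) {
  stopifnot(is.list(per_bird), length(per_bird) >= 1,
            all(vapply(per_bird, inherits, TRUE, "feature_matrix")))
  common <- Reduce(intersect, lapply(per_bird, function(m) colnames(m$values)))
  if (length(common) == 0) stop2("no feature names shared across birds")
  narrowed <- any(vapply(per_bird, function(m)
    ncol(m$values) > length(common), TRUE))
  vals <- do.call(rbind, lapply(per_bird, function(m)
    m$values[, common, drop = FALSE]))
  idx <- do.call(rbind, lapply(per_bird, function(m) m$index))
  rownames(idx) <- NULL
  prov <- per_bird[[1]]$provenance
  prov$aggregated_birds <- length(per_bird)
  if (narrowed) prov$feature_intersection <- length(common)
  normalize_features(feature_matrix(vals, idx, state = "raw",
                                    provenance = prov))
}

#' Write a feature matrix as TSV with a provenance sidecar
#'
#' Lead columns `bird`, `context`, `role`, `rendition`, then one column per
#' feature; invalid markers serialize as `NA`. A JSON sidecar
#' (`<path>.provenance.json`) records the normalization state, registry
#' hash, and dropped features.
#'
#' @param M a `feature_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(M, path) {
  stopifnot(inherits(M, "feature_matrix"))
  df <- cbind(M$index, as.data.frame(M$values, optional = TRUE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  side <- list(state = M$state,
               n_motifs = nrow(M$values), n_features = ncol(M$values),
               dropped = as.list(M$dropped), provenance = M$provenance)
  jsonlite::write_json(side, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_tsv()]
#'
#' @param path TSV path.
#' @return a `feature_matrix`; state is restored from the sidecar when
#'   present, otherwise `"raw"`.
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("bird", "context", "role", "rendition")
  if (!all(need %in% names(df)))
    stop2("missing index columns in ", path, ": ",
          paste(setdiff(need, names(df)), collapse = ", "))
  vals <- as.matrix(df[setdiff(names(df), need)])
  state <- "raw"; dropped <- character(); prov <- list()
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    state <- side$state
    dropped <- unlist(side$dropped)
    if (is.null(dropped)) dropped <- character()
    prov <- side$provenance
    if (is.null(prov)) prov <- list()
  }
  feature_matrix(vals, df[need], state = state, dropped = dropped,
                 provenance = prov)
}
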