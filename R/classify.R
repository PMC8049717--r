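# Bagged-decision-tree classification of motifs: training, vote scores,
# repeated stratified 10-fold cross-validation, impurity importance, top-k
# and random-k subset analyses, and signed confidence scores.

# accept either a feature_matrix or a plain numeric matrix
as_values <- function(X) {
  if (inherits(X, "feature_matrix")) X$values
  else if (is.matrix(X) && is.numeric(X)) X
  else stop2("X must be a feature_matrix or numeric matrix")
}

check_labels <- function(y, n) {
  y <- as.character(y)
  if (length(y) != n) stop2("labels and rows disagree in length")
  lv <- sort(unique(y))
  if (length(lv) != 2)
    stop2("exactly two classes required, got: ", paste(lv, collapse = ", "))
  if (min(table(y)) < 2) stop2("need >= 2 motifs per class")
  positive <- if ("courtship" %in% lv) "courtship" else lv[1]
  list(y = y, levels = lv, positive = positive)
}

#' Train a bagged-decision-tree classifier
#'
#' An ensemble of decision trees, each grown on a bootstrap sample of the
#' rows with a random feature subset considered at every split (Gini
#' criterion). Out-of-bag membership is retained per tree.
#'
#' @param X feature matrix (`feature_matrix` or numeric matrix), normalized.
#' @param y two-class labels, one per row.
#' @param n_trees ensemble size (default 300).
#' @param features_per_split features tried per split; default
#'   `floor(sqrt(n_features))`.
#' @param seed integer seed; fixes bootstraps and split randomness.
#' @return a `bgdt_model`.
#' @export
train_bgdt <- function(X, y, n_trees = 300, features_per_split = NULL,
                       seed = 1) {
  v <- as_values(X)
  if (n_trees < 1) stop2("n_trees must be >= 1")
  lab <- check_labels(y, nrow(v))
  if (is.null(features_per_split))
    features_per_split <- max(1L, floor(sqrt(ncol(v))))
  fit <- ranger::ranger(
    x = v, y = factor(lab$y, levels = lab$levels),
    num.trees = n_trees, mtry = min(features_per_split, ncol(v)),
    importance = "impurity", keep.inbag = TRUE, oob.error = FALSE,
    num.threads = 1, seed = seed)
  structure(list(forest = fit, feature_names = colnames(v),
                 levels = lab$levels, positive = lab$positive,
                 n_trees = n_trees, seed = seed),
            class = "bgdt_model")
}

#' @export
print.bgdt_model <- function(x, ...) {
  cat(sprintf("<bgdt_model> %d trees, %d features, classes %s (positive: %s)\n",
              x$n_trees, length(x$feature_names),
              paste(x$levels, collapse = "/"), x$positive))
  invisible(x)
}

#' Ensemble vote scores
#'
#' Fraction of trees voting for the positive (courtship) class, per row.
#'
#' @param model a `bgdt_model`.
#' @param X matrix containing at least the model's features.
#' @return numeric scores in `[0, 1]`.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "bgdt_model"))
  v <- as_values(X)
  missing <- setdiff(model$feature_names, colnames(v))
  if (length(missing))
    stop2("missing features: ", paste(utils::head(missing, 5), collapse = ", "))
  v <- v[, model$feature_names, drop = FALSE]
  pr <- stats::predict(model$forest, data = v,
                       predict.all = TRUE, num.threads = 1)
  pos <- match(model$positive, model$forest$forest$levels)
  rowMeans(pr$predictions == pos)
}

#' Out-of-bag accuracy
#'
#' For each training row, aggregates votes only from trees whose bootstrap
#' sample excluded that row (using the recorded in-bag counts), then scores
#' the resulting labels against the truth.
#'
#' @param model a `bgdt_model`.
#' @param X the training matrix.
#' @param y the training labels.
#' @return out-of-bag accuracy in `[0, 1]`.
#' @export
oob_accuracy <- function(model, X, y) {
  stopifnot(inherits(model, "bgdt_model"))
  v <- as_values(X)[, model$feature_names, drop = FALSE]
  pr <- stats::predict(model$forest, data = v,
                       predict.all = TRUE, num.threads = 1)
  pos <- match(model$positive, model$forest$forest$levels)
  inbag <- do.call(cbind, model$forest$inbag.counts)  # rows x trees
  votes <- (pr$predictions == pos) & (inbag == 0)
  n_oob <- rowSums(inbag == 0)
  if (any(n_oob == 0)) stop2("some rows were in-bag for every tree")
  score <- rowSums(votes) / n_oob
  neg <- setdiff(model$levels, model$positive)
  mean(labels_from_scores(score, model$positive, neg) == as.character(y))
}

#' Labels from vote scores
#'
#' Positive (courtship) iff score strictly exceeds 0.5; a tie at exactly 0.5
#' is assigned to the non-positive class, deterministically.
#'
#' @param scores numeric in `[0, 1]`.
#' @param positive positive class label.
#' @param negative negative class label.
#' @return character labels.
#' @export
labels_from_scores <- function(scores, positive = "courtship",
                               negative = "noncourtship") {
  if (any(scores < 0 | scores > 1)) stop2("scores must lie in [0, 1]")
  ifelse(scores > 0.5, positive, negative)
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in unique(y)) {
      ix <- which(y == cl)
      ix <- ix[sample.int(length(ix))]
      fold[ix] <- rep_len(seq_len(k), length(ix))[sample.int(length(ix))]
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Shuffles and partitions the rows into `k` stratified folds, holds out each
#' fold once, and repeats with independent shuffles; the median per-iteration
#' held-out accuracy is the headline number.
#'
#' @param X normalized feature matrix.
#' @param y two-class labels.
#' @param k folds (default 10).
#' @param n_iterations independent shuffles (default 10).
#' @param seed integer seed.
#' @param n_trees,features_per_split passed to [train_bgdt()].
#' @return a `cv_result`: `per_motif` data frame (iteration, fold, row, truth,
#'   score, predicted), `iteration_accuracy`, `median_accuracy`, and
#'   per-iteration `confusion` matrices (actual x predicted).
#' @export
kfold_cv <- function(X, y, k = 10, n_iterations = 10, seed = 1,
                     n_trees = 300, features_per_split = NULL) {
  v <- as_values(X)
  lab <- check_labels(y, nrow(v))
  y <- lab$y
  if (nrow(v) < k) stop2("need at least k rows")
  if (min(table(y)) < k)
    stop2("a class has fewer members than folds; stratification impossible")
  neg <- setdiff(lab$levels, lab$positive)
  rows <- vector("list", n_iterations)
  acc <- numeric(n_iterations)
  confusion <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    fold <- stratified_folds(y, k, derive_seed(seed, "folds", it))
    truth <- y
    score <- numeric(length(y))
    for (f in seq_len(k)) {
      te <- fold == f
      m <- train_bgdt(v[!te, , drop = FALSE], y[!te], n_trees = n_trees,
                      features_per_split = features_per_split,
                      seed = derive_seed(seed, "tree", it, f))
      score[te] <- predict_scores(m, v[te, , drop = FALSE])
    }
    pred <- labels_from_scores(score, lab$positive, neg)
    acc[it] <- mean(pred == truth)
    confusion[[it]] <- table(actual = factor(truth, lab$levels),
                             predicted = factor(pred, lab$levels))
    rows[[it]] <- data.frame(iteration = it, fold = fold,
                             row = seq_along(y), truth = truth,
                             score = score, predicted = pred)
  }
  structure(list(per_motif = do.call(rbind, rows),
                 iteration_accuracy = acc,
                 median_accuracy = stats::median(acc),
                 confusion = confusion, k = k,
                 n_iterations = n_iterations, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d iterations: median accuracy %.1f%%\n",
              x$k, x$n_iterations, 100 * x$median_accuracy))
  cat("  per-iteration:",
      paste(sprintf("%.1f", 100 * x$iteration_accuracy), collapse = " "), "\n")
  cat("confusion (median-accuracy iteration; actual x predicted):\n")
  print(x$confusion[[order(x$iteration_accuracy)[ceiling(x$n_iterations / 2)]]])
  invisible(x)
}

#' Feature importance ranking
#'
#' Mean impurity-decrease importance per feature, normalized to a maximum of
#' 1, in stable descending order (ties broken by feature name). A list of
#' models is averaged before normalization.
#'
#' @param model a `bgdt_model`, or a list of them.
#' @return data frame with `feature`, `importance`, `rank`.
#' @export
importance_ranking <- function(model) {
  if (inherits(model, "bgdt_model")) model <- list(model)
  stopifnot(all(vapply(model, inherits, TRUE, "bgdt_model")))
  imp <- Reduce(`+`, lapply(model, function(m)
    ranger::importance(m$forest)[m$feature_names])) / length(model)
  imp <- pmax(imp, 0)
  if (max(imp) > 0) imp <- imp / max(imp)
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp))
}

#' Cross-validate on the top-k ranked features
#'
#' @param X normalized feature matrix.
#' @param y labels.
#' @param ranking data frame from [importance_ranking()].
#' @param k number of top features (default 50).
#' @param folds CV folds (default 10).
#' @param ... passed to [kfold_cv()] (including `seed`).
#' @return a `cv_result`; the feature subset is recorded as `$features`.
#' @export
top_k_evaluation <- function(X, y, ranking, k = 50, folds = 10, ...) {
  v <- as_values(X)
  if (k < 1) stop2("k must be >= 1")
  if (k > ncol(v)) stop2("k exceeds the number of features")
  feats <- ranking$feature[seq_len(k)]
  if (!all(feats %in% colnames(v)))
    stop2("ranking names features absent from X")
  out <- kfold_cv(v[, feats, drop = FALSE], y, k = folds, ...)
  out$features <- feats
  out
}

#' Random feature-subset benchmark
#'
#' Monte Carlo control for the top-k analysis: repeatedly draws `k` features
#' uniformly without replacement, runs a single-shuffle k-fold CV, and
#' records the accuracy.
#'
#' @param X normalized feature matrix.
#' @param y labels.
#' @param k subset size (default 50).
#' @param n_iterations Monte Carlo draws (default 1000).
#' @param seed integer seed.
#' @param reference_accuracy optional top-k accuracy to compare against.
#' @param folds CV folds per draw (default 10).
#' @param n_trees ensemble size per fit.
#' @return list with `accuracies` (length `n_iterations`), `max_accuracy`,
#'   and, when a reference is given, `reference_accuracy` and
#'   `all_below_reference`.
#' @export
random_subset_benchmark <- function(X, y, k = 50, n_iterations = 1000,
                                    seed = 1, reference_accuracy = NULL,
                                    folds = 10, n_trees = 300) {
  v <- as_values(X)
  if (k > ncol(v)) stop2("k exceeds the number of features")
  acc <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    feats <- with_local_seed(derive_seed(seed, "subset", it),
                             sample.int(ncol(v), k))
    cv <- kfold_cv(v[, feats, drop = FALSE], y, k = folds, n_iterations = 1,
                   seed = derive_seed(seed, "cv", it), n_trees = n_trees)
    acc[it] <- cv$median_accuracy
  }
  out <- list(accuracies = acc, max_accuracy = max(acc), k = k, seed = seed)
  if (!is.null(reference_accuracy)) {
    out$reference_accuracy <- reference_accuracy
    out$all_below_reference <- max(acc) < reference_accuracy
  }
  out
}

#' Signed confidence scores
#'
#' `|score - 0.5|`, signed positive when the predicted label matches the
#' truth and negative otherwise; a score of exactly 0.5 yields 0.
#'
#' @param scores vote scores in `[0, 1]`.
#' @param truth true labels.
#' @param positive positive class (default `"courtship"`).
#' @param negative negative class (default `"noncourtship"`).
#' @return numeric confidence values in `[-0.5, 0.5]`.
#' @export
confidence_scores <- function(scores, truth, positive = "courtship",
                              negative = "noncourtship") {
  if (any(scores < 0 | scores > 1)) stop2("scores must lie in [0, 1]")
  if (length(scores) != length(truth))
    stop2("scores and truth disagree in length")
  pred <- labels_from_scores(scores, positive, negative)
  abs(scores - 0.5) * ifelse(pred == as.character(truth), 1, -1)
}

#' Regress subject accuracy on classifier confidence
#'
#' Fixed-effects stimulus-level analysis:
#' ordinary least squares of per-stimulus subject accuracy on the
#' classifier's confidence score.
#'
#' @param confidence per-stimulus confidence scores.
#' @param subject_pct_correct per-stimulus subject accuracy (same length).
#' @return list with `slope`, `intercept`, `r` (Pearson), `p` (two-sided),
#'   `n`.
#' @export
classifier_vs_subject <- function(confidence, subject_pct_correct) {
  if (length(confidence) != length(subject_pct_correct))
    stop2("inputs disagree in length")
  n <- length(confidence)
  if (n < 3) stop2("need >= 3 paired stimuli")
  if (stats::sd(confidence) == 0 || stats::sd(subject_pct_correct) == 0)
    stop2("zero variance: correlation undefined")
  fit <- stats::lm(subject_pct_correct ~ confidence)
  ct <- stats::cor.test(confidence, subject_pct_correct)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = n)
}
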