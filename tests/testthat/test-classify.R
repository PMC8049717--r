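separable_data <- function(n = 200, noise_features = 20, seed = 51) {
  set.seed(seed)
  y <- rep(c("courtship", "noncourtship"), each = n / 2)
  X <- cbind(sig = ifelse(y == "courtship", 1, 0) + rnorm(n, 0, 0.05),
             matrix(rnorm(n * noise_features), n, noise_features,
                    dimnames = list(NULL, paste0("noise", seq_len(noise_features)))))
  list(X = X, y = y)
}

test_that("training is deterministic and separable data is learned", {
  d <- separable_data()
  m1 <- train_bgdt(d$X, d$y, n_trees = 200, seed = 3)
  m2 <- train_bgdt(d$X, d$y, n_trees = 200, seed = 3)
  s <- predict_scores(m1, d$X)
  expect_identical(predict_scores(m2, d$X), s)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(labels_from_scores(s), d$y)
  expect_gte(oob_accuracy(m1, d$X, d$y), 0.95)
})

test_that("training rejects degenerate inputs", {
  d <- separable_data(n = 20)
  expect_error(train_bgdt(d$X, rep("courtship", 20), seed = 1), "two classes")
  expect_error(train_bgdt(d$X, d$y, n_trees = 0, seed = 1), "n_trees")
  m <- train_bgdt(d$X, d$y, n_trees = 20, seed = 1)
  expect_error(predict_scores(m, d$X[, 1:3]), "missing features")
})

test_that("score 0.5 ties resolve to noncourtship", {
  expect_identical(labels_from_scores(c(0.5, 0.500001)),
                   c("noncourtship", "courtship"))
  expect_error(labels_from_scores(1.2), "0, 1")
})

test_that("cross-validation partitions correctly and nails separable data", {
  d <- separable_data(n = 120, noise_features = 8)
  cv <- kfold_cv(d$X, d$y, k = 10, n_iterations = 3, seed = 5, n_trees = 100)
  expect_gte(cv$median_accuracy, 0.99)
  per <- cv$per_motif
  for (it in unique(per$iteration)) {
    sl <- per[per$iteration == it, ]
    expect_setequal(sl$row, seq_len(120))       # each motif tested once
    expect_equal(sum(sl$fold %in% 1:10), 120)
    expect_equal(sum(cv$confusion[[it]]), 120)  # confusion sums to n
  }
  expect_identical(kfold_cv(d$X, d$y, k = 10, n_iterations = 3, seed = 5,
                            n_trees = 100)$median_accuracy,
                   cv$median_accuracy)
})

test_that("importance puts the single informative feature first", {
  d <- separable_data(n = 150, noise_features = 30, seed = 52)
  m <- train_bgdt(d$X, d$y, n_trees = 200, seed = 2)
  rk <- importance_ranking(m)
  expect_identical(rk$feature[1], "sig")
  expect_equal(rk$importance[1], 1)
  expect_true(all(rk$importance >= 0))
  expect_identical(rk$rank, seq_len(ncol(d$X)))
})

test_that("top-k with all features equals the full CV at the same seed", {
  d <- separable_data(n = 80, noise_features = 5, seed = 53)
  m <- train_bgdt(d$X, d$y, n_trees = 50, seed = 2)
  rk <- importance_ranking(m)
  full <- kfold_cv(d$X[, rk$feature], d$y, k = 5, n_iterations = 2, seed = 9,
                   n_trees = 50)
  top <- top_k_evaluation(d$X, d$y, rk, k = ncol(d$X), folds = 5,
                          n_iterations = 2, seed = 9, n_trees = 50)
  expect_identical(top$median_accuracy, full$median_accuracy)
  expect_error(top_k_evaluation(d$X, d$y, rk, k = 0), "k must be")
})

test_that("random subset benchmark returns the requested distribution", {
  d <- separable_data(n = 60, noise_features = 10, seed = 54)
  rb <- random_subset_benchmark(d$X, d$y, k = 3, n_iterations = 5, seed = 4,
                                folds = 5, n_trees = 30,
                                reference_accuracy = 1.0)
  expect_length(rb$accuracies, 5)
  expect_equal(rb$max_accuracy, max(rb$accuracies))
  expect_true(is.logical(rb$all_below_reference))
})

test_that("confidence scores follow the printed arithmetic", {
  expect_equal(confidence_scores(0.9, "courtship"), 0.4)
  expect_equal(confidence_scores(0.2, "courtship"), -0.3)
  expect_equal(confidence_scores(0.5, "courtship"), 0)
  expect_equal(confidence_scores(0.2, "noncourtship"), 0.3)
  expect_error(confidence_scores(1.3, "courtship"), "0, 1")
  s <- c(0.1, 0.6, 0.95)
  tr <- c("noncourtship", "courtship", "noncourtship")
  cs <- confidence_scores(s, tr)
  expect_true(all((cs > 0) == (labels_from_scores(s) == tr) | cs == 0))
})

test_that("classifier-vs-subject regression recovers a linear relation", {
  set.seed(55)
  conf <- runif(100, -0.5, 0.5)
  subj <- 0.5 + 0.8 * conf + rnorm(100, 0, 0.03)
  r <- classifier_vs_subject(conf, subj)
  expect_gt(r$slope, 0.6)
  expect_lt(r$slope, 1.0)
  expect_gt(r$r, 0.9)
  perfect <- classifier_vs_subject(conf, 0.5 + 0.8 * conf)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_error(classifier_vs_subject(conf, rep(0.5, 100)), "variance")
})
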