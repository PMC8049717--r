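make_fm <- function(values) {
  n <- nrow(values)
  feature_matrix(values,
                 data.frame(bird = rep("bird01", n),
                            context = rep_len(c("courtship", "noncourtship"), n),
                            role = "training", rendition = seq_len(n)))
}

test_that("filtering drops constant and invalid columns only", {
  set.seed(41)
  v <- cbind(ok = rnorm(20), const = rep(2, 20),
             invalid = c(NA, rnorm(19)), inf = c(Inf, rnorm(19)))
  M <- filter_features(make_fm(v))
  expect_identical(colnames(M$values), "ok")
  expect_setequal(names(M$dropped), c("const", "invalid", "inf"))
  expect_error(filter_features(make_fm(cbind(a = rep(1, 5)))), "dropped")
})

test_that("robust sigmoid centers the median and is affine invariant", {
  set.seed(42)
  v <- cbind(a = c(rnorm(19), 30))  # outlier ~20 IQRs out
  M <- robust_sigmoid(make_fm(v))
  med_row <- which(v[, "a"] == stats::median(v[1:19, "a"]))
  expect_true(all(M$values > 0 & M$values < 1))
  shifted <- robust_sigmoid(make_fm(cbind(a = 3.5 * v[, "a"] + 11)))
  expect_equal(shifted$values, M$values, tolerance = 1e-12)
  exact <- robust_sigmoid(make_fm(cbind(a = c(1, 2, 3, 4, 5))))
  expect_equal(unname(exact$values[3, 1]), 0.5)   # median maps to 0.5
})

test_that("unit scaling hits [0, 1] exactly and is idempotent", {
  M <- unit_scale(make_fm(cbind(f = c(2, 4, 6))))
  expect_equal(as.numeric(M$values), c(0, 0.5, 1))
  expect_equal(unit_scale(M)$values, M$values)
  expect_identical(M$state, "unit")
})

test_that("normalization preserves within-column rank order", {
  set.seed(43)
  v <- cbind(a = rnorm(30), b = rexp(30))
  M <- normalize_features(make_fm(v))
  for (cn in colnames(M$values))
    expect_identical(order(M$values[, cn]), order(v[, cn]))
})

test_that("assemble_combined is invariant to bird order up to row permutation", {
  set.seed(44)
  pb <- lapply(1:3, function(b) feature_matrix(
    cbind(a = rnorm(8, b), b = rnorm(8)),
    data.frame(bird = sprintf("bird%02d", b),
               context = rep_len(c("courtship", "noncourtship"), 8),
               role = "training", rendition = 1:8)))
  c1 <- assemble_combined(pb)
  c2 <- assemble_combined(rev(pb))
  expect_equal(nrow(c1$values), 24)
  key1 <- paste(c1$index$bird, c1$index$rendition, c1$index$context)
  key2 <- paste(c2$index$bird, c2$index$rendition, c2$index$context)
  expect_equal(c1$values[order(key1), ], c2$values[order(key2), ],
               tolerance = 1e-12)
  expect_identical(c1$index$context[c1$index$bird == "bird02"],
                   pb[[2]]$index$context)
})

test_that("TSV roundtrip preserves values, index, and provenance", {
  ds <- tiny_dataset(seed = 45, n_birds = 2, renditions = 2)
  M <- collect_features(ds, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_feature_tsv(M, f)
  expect_true(file.exists(paste0(f, ".provenance.json")))
  back <- read_feature_tsv(f)
  expect_equal(back$values, M$values, tolerance = 1e-12)
  expect_equal(back$index, M$index)
  expect_identical(back$provenance$registry_hash,
                   M$provenance$registry_hash)
})
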