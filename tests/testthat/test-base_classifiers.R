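adapters <- c("rf", "knn", "svm", "lr", "nb", "ftt_pca")

test_that("every adapter separates two distant Gaussian classes", {
  data <- gaussian_features(n_per_class = 100, width = 10, sep = 4, seed = 1)
  tr <- seq_len(140)
  te <- setdiff(seq_len(200), tr)
  ftr <- feature_table(data$features$X[tr, ], data$features$sample_ids[tr])
  fte <- feature_table(data$features$X[te, ], data$features$sample_ids[te])
  ltr <- label_vector(ftr$sample_ids, data$labels$grades[tr], K = 2L)
  lte <- data$labels$grades[te]
  for (m in adapters) {
    spec <- classifier_spec(paste0("t_", m), m)
    trained <- train_classifier(spec, ftr, ltr, rng_seed = 7)
    pr <- predict_proba(trained, fte)
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
    acc <- mean(max.col(pr, ties.method = "first") - 1L == lte)
    expect_gt(acc, 0.95)
  }
})

test_that("training is deterministic under a fixed seed", {
  data <- gaussian_features(n_per_class = 40, width = 6, sep = 3, seed = 2)
  for (m in c("rf", "svm")) {
    spec <- classifier_spec(m, m)
    p1 <- predict_proba(train_classifier(spec, data$features, data$labels,
                                         rng_seed = 11), data$features)
    p2 <- predict_proba(train_classifier(spec, data$features, data$labels,
                                         rng_seed = 11), data$features)
    expect_identical(p1, p2)
  }
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  ft <- feature_table(X)
  single <- label_vector(ft$sample_ids, rep(0L, 10), K = 2L)
  expect_error(train_classifier(classifier_spec("rf", "rf"), ft, single),
               "class")
  expect_error(feature_table(matrix(c(1, NA), 1, 2)), "finite")

  spec <- classifier_spec("rf", "rf")
  expect_error(predict_proba(spec, ft), "not trained")
  mixed <- label_vector(ft$sample_ids, rep(c(0L, 1L), 5), K = 2L)
  trained <- train_classifier(spec, ft, mixed, rng_seed = 1)
  wide <- feature_table(matrix(rnorm(50), 10, 5))
  expect_error(predict_proba(trained, wide), "width")
})

test_that("a six-adapter stack composes into a valid probability panel", {
  set.seed(5)
  K <- 4L
  n <- 160
  X <- matrix(rnorm(n * 8), n, 8)
  grades <- sample(0:3, n, replace = TRUE)
  X <- X + grades * 2.5
  ft <- feature_table(X)
  lab <- label_vector(ft$sample_ids, grades, K = K)
  tr <- seq_len(120); te <- setdiff(seq_len(n), tr)
  panel <- panel_from_features(
    default_stack(n_components = 8L),
    feature_table(X[tr, ], ft$sample_ids[tr]),
    label_vector(ft$sample_ids[tr], grades[tr], K = K),
    feature_table(X[te, ], ft$sample_ids[te]),
    rng_seed = 9)
  expect_s3_class(validate_panel(panel), "probability_panel")
  expect_identical(panel$classifier_names,
                   c("RF", "kNN", "SVM", "LR", "NB", "FTT+PCA"))
  cs <- combine_panel(panel, repair_weights(rep(1, 6)))
  expect_gt(mean(cs$dc == grades[te]), 0.8)
})

test_that("the trig-transform stand-in behaves like nearest centroid", {
  data <- gaussian_features(n_per_class = 150, width = 8, sep = 3, seed = 6)
  tr <- seq_len(200); te <- setdiff(seq_len(300), tr)
  ftr <- feature_table(data$features$X[tr, ], data$features$sample_ids[tr])
  fte <- feature_table(data$features$X[te, ], data$features$sample_ids[te])
  ltr <- label_vector(ftr$sample_ids, data$labels$grades[tr], K = 2L)

  pr <- ftt_pca_standin(ftr, ltr, fte, n_components = 8L)
  acc <- mean(max.col(pr, ties.method = "first") - 1L ==
                data$labels$grades[te])
  expect_gt(acc, 0.9)

  # a training sample scored against itself concentrates on its own class
  self <- ftt_pca_standin(ftr, ltr,
                          feature_table(ftr$X[1, , drop = FALSE], "q1"),
                          n_components = 8L)
  expect_equal(unname(which.max(self[1, ])) - 1L, ltr$grades[1])

  # identity transform + full components ranks exactly like nearest centroid
  pr_id <- ftt_pca_standin(ftr, ltr, fte, n_components = 8L,
                           transform = "identity")
  cent <- rbind(colMeans(ftr$X[ltr$grades == 0L, , drop = FALSE]),
                colMeans(ftr$X[ltr$grades == 1L, , drop = FALSE]))
  d2 <- outer(rowSums(fte$X^2), rowSums(cent^2), "+") - 2 * fte$X %*% t(cent)
  expect_equal(max.col(pr_id, ties.method = "first"),
               max.col(-d2, ties.method = "first"))

  expect_error(ftt_pca_standin(ftr, ltr, fte, n_components = 99L),
               "n_components")
})
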