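#' Tabular feature data for the base-classifier adapters
#'
#' A plain numeric feature matrix with one row per sample; CNN-extracted
#' descriptors (1024 features per image in the original setting) or any
#' other fixed-width tabular representation.
#'
#' @param X numeric matrix (samples x features), no missing values.
#' @param sample_ids character vector of unique ids (default: rownames or
#'   generated).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(X, sample_ids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("features must be numeric and finite")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(X))) rownames(X)
      else sprintf("s%04d", seq_len(nrow(X)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) stop("sample_ids length must match rows")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  rownames(X) <- sample_ids
  structure(list(X = X, sample_ids = sample_ids, width = ncol(X)),
            class = "feature_table")
}

#' Read a feature table from delimited text
#' @param path CSV with a `sample_id` column followed by numeric feature
#'   columns.
#' @return A `feature_table`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"sample_id" %in% names(df))
    stop("feature file must have a 'sample_id' column: ", path)
  X <- as.matrix(df[setdiff(names(df), "sample_id")])
  feature_table(X, df$sample_id)
}

#' Write a feature table to delimited text
#' @param features a `feature_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_table"))
  df <- data.frame(sample_id = features$sample_ids, features$X,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Declare a base-classifier adapter
#'
#' Adapter contracts over standard learners so the full pipeline can run
#' end-to-end on tabular features.  Supported methods and their default
#' hyperparameters mirror the stack the package targets: `"rf"` (random
#' forest, 200 trees), `"knn"` (Euclidean k-nearest neighbours, k = 2),
#' `"svm"` (RBF support-vector machine with calibrated probabilities),
#' `"lr"` (multinomial logistic regression with L2 penalty 10, no L1),
#' `"nb"` (Gaussian naive Bayes), and `"ftt_pca"` (the in-package
#' trig-transform + PCA nearest-centroid stand-in, see
#' [ftt_pca_standin()]).
#'
#' @param name unique display name within a stack.
#' @param method one of `"rf"`, `"knn"`, `"svm"`, `"lr"`, `"nb"`,
#'   `"ftt_pca"`.
#' @param ... method hyperparameters overriding the defaults
#'   (`ntree`, `k`, `l2`, `n_components`, ...).
#' @return An object of class `classifier_spec` (untrained).
#' @export
classifier_spec <- function(name, method, ...) {
  method <- match.arg(method, c("rf", "knn", "svm", "lr", "nb", "ftt_pca"))
  defaults <- switch(method,
                     rf = list(ntree = 200L),
                     knn = list(k = 2L),
                     svm = list(),
                     lr = list(l2 = 10),
                     nb = list(),
                     ftt_pca = list(n_components = NULL, transform = "ftt"))
  hyper <- utils::modifyList(defaults, list(...))
  structure(list(name = name, method = method, hyper = hyper, model = NULL),
            class = "classifier_spec")
}

#' The default six-classifier stack
#' @param n_components principal components kept by the FTT+PCA stand-in
#'   (NULL: min(32, feature width), resolved at training time).
#' @return A named list of `classifier_spec`s in stable stack order.
#' @export
default_stack <- function(n_components = NULL) {
  specs <- list(classifier_spec("RF", "rf"),
                classifier_spec("kNN", "knn"),
                classifier_spec("SVM", "svm"),
                classifier_spec("LR", "lr"),
                classifier_spec("NB", "nb"),
                classifier_spec("FTT+PCA", "ftt_pca",
                                n_components = n_components))
  setNames(specs, vapply(specs, `[[`, character(1L), "name"))
}

#' Train a base-classifier adapter
#'
#' @param spec a `classifier_spec`.
#' @param features a `feature_table` of training samples.
#' @param labels a `label_vector` aligned with `features` (every class
#'   must be represented by at least one training sample).
#' @param rng_seed optional seed making stochastic learners (RF, SVM
#'   internals) reproducible.
#' @return The spec with a trained model handle.
#' @export
train_classifier <- function(spec, features, labels, rng_seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(features, "feature_table"),
            inherits(labels, "label_vector"))
  if (!identical(features$sample_ids, labels$sample_ids))
    stop("features and labels are not aligned")
  y <- factor(labels$grades, levels = seq_len(labels$K) - 1L)
  if (any(table(y) == 0L))
    stop("every class needs at least one training sample (empty class ",
         paste(levels(y)[table(y) == 0L], collapse = ", "), ")")
  if (length(levels(y)) < 2L) stop("training data covers a single class")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  X <- features$X
  h <- spec$hyper
  model <- switch(spec$method,
    rf = randomForest::randomForest(X, y, ntree = h$ntree),
    knn = caret::knn3(X, y, k = h$k),
    svm = e1071::svm(X, y, probability = TRUE),
    lr = glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                        lambda = h$l2 / nrow(X)),
    nb = e1071::naiveBayes(X, y),
    ftt_pca = .ftt_pca_fit(X, y, h$n_components, h$transform))
  spec$model <- model
  spec$K <- labels$K
  spec$width <- features$width
  spec
}

#' Per-class probabilities from a trained adapter
#'
#' Returns one classifier slice of a probability panel: an `n x K` matrix
#' of class probabilities, each row on the unit simplex.
#'
#' @param spec a trained `classifier_spec`.
#' @param features a `feature_table` of test samples (same width as the
#'   training features).
#' @return numeric matrix (samples x classes), rows summing to 1.
#' @export
predict_proba <- function(spec, features) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(features, "feature_table"))
  if (is.null(spec$model)) stop("classifier '", spec$name, "' is not trained")
  if (features$width != spec$width)
    stop(sprintf("feature width %d does not match training width %d",
                 features$width, spec$width))
  X <- features$X
  K <- spec$K
  lev <- as.character(seq_len(K) - 1L)
  pr <- switch(spec$method,
    rf = predict(spec$model, X, type = "prob"),
    knn = predict(spec$model, X, type = "prob"),
    svm = {
      raw <- predict(spec$model, X, probability = TRUE)
      attr(raw, "probabilities")
    },
    lr = {
      arr <- predict(spec$model, X, type = "response")
      matrix(arr[, , 1L], nrow = nrow(X), dimnames = list(NULL, dimnames(arr)[[2L]]))
    },
    nb = predict(spec$model, X, type = "raw"),
    ftt_pca = .ftt_pca_predict(spec$model, X))
  pr <- as.matrix(pr)
  missing <- setdiff(lev, colnames(pr))
  if (length(missing)) {
    add <- matrix(0, nrow(pr), length(missing), dimnames = list(NULL, missing))
    pr <- cbind(pr, add)
  }
  pr <- pr[, lev, drop = FALSE]
  pr[pr < 0] <- 0
  pr / rowSums(pr)
}

#' Build a probability panel from a classifier stack
#'
#' Trains every adapter in the stack on the training partition and stacks
#' their test-set probability outputs into one validated panel.
#'
#' @param stack list of `classifier_spec`s (see [default_stack()]).
#' @param train_features,train_labels training partition.
#' @param test_features held-out samples to score.
#' @param rng_seed optional seed (one stream across the stack).
#' @return A `probability_panel` with one slice per adapter.
#' @export
panel_from_features <- function(stack, train_features, train_labels,
                                test_features, rng_seed = NULL) {
  stopifnot(length(stack) >= 1L)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- length(test_features$sample_ids)
  K <- train_labels$K
  p <- array(NA_real_, dim = c(length(stack), n, K))
  for (j in seq_along(stack)) {
    trained <- train_classifier(stack[[j]], train_features, train_labels)
    p[j, , ] <- predict_proba(trained, test_features)
  }
  probability_panel(p, vapply(stack, `[[`, character(1L), "name"),
                    test_features$sample_ids)
}

#' Run the full Monte-Carlo protocol on tabular features
#'
#' For each trial of the split plan, re-trains the whole stack on the
#' trial's training samples and scores its held-out samples, yielding the
#' per-trial panels the weight search consumes.
#'
#' @param features a `feature_table` for all samples.
#' @param labels a `label_vector` aligned with `features`.
#' @param plan a [make_splits()] plan.
#' @param stack list of `classifier_spec`s.
#' @param rng_seed optional seed.
#' @return A `trial_outputs`.
#' @export
mccv_trials <- function(features, labels, plan, stack = default_stack(),
                        rng_seed = NULL) {
  stopifnot(inherits(features, "feature_table"), inherits(labels, "label_vector"),
            inherits(plan, "split_plan"))
  if (!identical(features$sample_ids, labels$sample_ids))
    stop("features and labels are not aligned")
  if (plan$n_samples != nrow(features$X))
    stop("plan and features disagree on the number of samples")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  subset_ft <- function(idx) feature_table(features$X[idx, , drop = FALSE],
                                           features$sample_ids[idx])
  subset_lb <- function(idx) label_vector(labels$sample_ids[idx],
                                          labels$grades[idx], K = labels$K)
  panels <- vector("list", plan$n_trials)
  labs <- vector("list", plan$n_trials)
  for (t in seq_len(plan$n_trials)) {
    tr <- plan$trials[[t]]
    panels[[t]] <- panel_from_features(stack, subset_ft(tr$train),
                                       subset_lb(tr$train),
                                       subset_ft(tr$heldout))
    labs[[t]] <- subset_lb(tr$heldout)
  }
  trial_outputs(panels, labs)
}

# --- FTT+PCA stand-in ------------------------------------------------------
# A stand-in, not a reproduction: the original trig-transform classifier is
# specified elsewhere and only its role in the stack (a decorrelated sixth
# view of the features) matters here.  Pipeline: discrete Fourier transform
# of each feature vector, keeping the real (cosine) and imaginary (sine)
# coefficient blocks; principal-component reduction fitted on the training
# transforms; nearest-class-centroid scoring in component space, turned into
# simplex probabilities by a softmax of negative scaled distances.

.ftt_transform <- function(X, transform) {
  if (transform == "identity") return(X)
  tr <- t(apply(X, 1L, function(v) {
    f <- stats::fft(v)
    c(Re(f), -Im(f))
  }))
  tr
}

.ftt_pca_fit <- function(X, y, n_components, transform = "ftt") {
  tx <- .ftt_transform(X, transform)
  if (is.null(n_components)) n_components <- min(32L, ncol(X))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > ncol(X))
    stop("n_components must be in 1 .. feature width")
  n_components <- min(n_components, ncol(tx), nrow(tx))
  pca <- stats::prcomp(tx, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  centroids <- do.call(rbind, lapply(levels(y), function(l)
    colMeans(scores[y == l, , drop = FALSE])))
  rownames(centroids) <- levels(y)
  # distance scale for the softmax: typical training distance to a centroid
  d <- sqrt(pmax(outer(rowSums(scores^2), rowSums(centroids^2), "+") -
                   2 * scores %*% t(centroids), 0))
  list(pca = pca, n_components = n_components, centroids = centroids,
       scale = stats::median(d) + 1e-12, transform = transform,
       levels = levels(y))
}

#' Trig-transform + PCA nearest-centroid stand-in classifier
#'
#' Trains and applies the stand-in directly (outside the adapter
#' machinery): Fourier cosine/sine coefficients of each feature vector,
#' principal-component reduction, and nearest-class-centroid scoring
#' converted to probabilities via a softmax of negative scaled distances.
#' With `transform = "identity"` and `n_components` equal to the feature
#' width the ranking reduces to plain nearest-centroid on the raw
#' features.
#'
#' @param train_features,train_labels training partition.
#' @param test_features samples to score.
#' @param n_components principal components retained.
#' @param transform `"ftt"` (default) or `"identity"`.
#' @return numeric matrix (samples x classes) of probabilities.
#' @export
ftt_pca_standin <- function(train_features, train_labels, test_features,
                            n_components = NULL, transform = "ftt") {
  spec <- classifier_spec("FTT+PCA", "ftt_pca", n_components = n_components,
                          transform = transform)
  trained <- train_classifier(spec, train_features, train_labels)
  predict_proba(trained, test_features)
}

.ftt_pca_predict <- function(model, X) {
  tx <- .ftt_transform(X, model$transform)
  scores <- predict(model$pca, tx)[, seq_len(model$n_components), drop = FALSE]
  d <- sqrt(pmax(outer(rowSums(scores^2), rowSums(model$centroids^2), "+") -
                   2 * scores %*% t(model$centroids), 0))
  logits <- -d / model$scale
  logits <- logits - apply(logits, 1L, max)
  pr <- exp(logits)
  pr <- pr / rowSums(pr)
  colnames(pr) <- model$levels
  pr
}
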