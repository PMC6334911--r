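# Fixture builders and independent oracles shared across test files.

# Panel from a list of per-classifier n x K probability matrices.
panel_from_mats <- function(mats, classifier_names = NULL, sample_ids = NULL) {
  M <- length(mats)
  n <- nrow(mats[[1L]]); K <- ncol(mats[[1L]])
  p <- array(NA_real_, dim = c(M, n, K))
  for (j in seq_len(M)) p[j, , ] <- mats[[j]]
  if (is.null(classifier_names)) classifier_names <- sprintf("clf%d", seq_len(M))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n))
  probability_panel(p, classifier_names, sample_ids)
}

# Random valid panel: independent Dirichlet(1,...,1) rows.
random_panel <- function(M, n, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mats <- lapply(seq_len(M), function(j) {
    g <- matrix(rgamma(n * K, 1), n, K)
    g / rowSums(g)
  })
  panel_from_mats(mats)
}

random_labels <- function(panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  label_vector(panel$sample_ids,
               sample.int(panel$K, length(panel$sample_ids), replace = TRUE) - 1L,
               K = panel$K)
}

# One-hot M=1 panel that forces a given determined-class sequence.
forced_panel <- function(dc, K = 4L) {
  n <- length(dc)
  m <- matrix(0.01 / (K - 1), n, K)
  m[cbind(seq_len(n), dc + 1L)] <- 0.99
  panel_from_mats(list(m / rowSums(m)))
}

# Independent sample-by-sample recount of the squared class-distance fitness,
# written with explicit loops so it shares no code with the package path.
brute_fitness <- function(panel, labels, w) {
  total <- 0
  for (i in seq_along(labels$grades)) {
    scores <- numeric(panel$K)
    for (k in seq_len(panel$K)) {
      s <- 0
      for (j in seq_along(w)) s <- s + w[j] * panel$p[j, i, k]
      scores[k] <- s
    }
    dc <- which(scores == max(scores))[1L] - 1L
    total <- total + (dc - labels$grades[i])^2
  }
  total
}

# Minimal combined_scores stand-in for confidence tests that only need
# p_max / dc / ids.
make_scores <- function(p_max, dc, K = 4L) {
  n <- length(p_max)
  s <- matrix((1 - p_max) / (K - 1), n, K)
  s[cbind(seq_len(n), dc + 1L)] <- p_max
  structure(list(sample_ids = sprintf("s%04d", seq_len(n)),
                 s = s / rowSums(s), dc = as.integer(dc), p_max = p_max, K = K),
            class = "combined_scores")
}

# Two well-separated Gaussian classes in `width` dimensions.
gaussian_features <- function(n_per_class, width = 10L, sep = 4, seed = 1,
                              K = 2L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(K) - 1L, function(k)
    matrix(rnorm(n_per_class * width, mean = k * sep), n_per_class, width)))
  grades <- rep(seq_len(K) - 1L, each = n_per_class)
  idx <- sample.int(nrow(X))
  ft <- feature_table(X[idx, , drop = FALSE])
  list(features = ft,
       labels = label_vector(ft$sample_ids, grades[idx], K = K))
}
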