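# Feasible region for classifier weights: each coordinate in [0, 1] and the
# total in [0.5, 2].  Relative weighting is what matters for the fused argmax,
# but bounding the sum keeps the search away from the all-zero corner and from
# uniformly saturated vectors.
.w_lo <- 0
.w_hi <- 1
.w_sum_lo <- 0.5
.w_sum_hi <- 2

#' Classifier weight vector
#'
#' One non-negative weight per classifier, each in `[0, 1]`, with the sum
#' constrained to `[0.5, 2]`.
#'
#' @param w numeric vector of weights.
#' @param classifier_names optional names (length `M`).
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(w, classifier_names = NULL) {
  w <- as.numeric(w)
  if (length(w) < 1L) stop("need at least one weight")
  if (any(!is.finite(w))) stop("weights must be finite")
  if (any(w < .w_lo - 1e-12) || any(w > .w_hi + 1e-12))
    stop("each weight must lie in [0, 1]")
  s <- sum(w)
  if (s < .w_sum_lo - 1e-9 || s > .w_sum_hi + 1e-9)
    stop(sprintf("sum of weights must lie in [%.1f, %.1f] (got %.4f)",
                 .w_sum_lo, .w_sum_hi, s))
  if (!is.null(classifier_names)) {
    classifier_names <- as.character(classifier_names)
    if (length(classifier_names) != length(w))
      stop("classifier_names length must match weights")
    names(w) <- classifier_names
  }
  structure(list(w = pmin(pmax(w, .w_lo), .w_hi),
                 classifier_names = classifier_names),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> M=%d, sum=%.4f\n", length(x$w), sum(x$w)))
  print(round(x$w, 4))
  invisible(x)
}

#' Repair an arbitrary real vector onto the feasible weight region
#'
#' Coordinates are clipped to `[0, 1]`; if the clipped sum falls outside
#' `[0.5, 2]` the vector is rescaled multiplicatively onto the nearest sum
#' bound and re-clipped, iterating to a fixed point (at most 10 rounds).
#' The all-zero vector has no scale to work with and maps to the uniform
#' vector at the lower sum bound.
#'
#' @param w_raw numeric vector.
#' @return A feasible `weight_vector`.
#' @export
repair_weights <- function(w_raw) {
  w <- as.numeric(w_raw)
  if (any(!is.finite(w))) stop("weights must be finite")
  w <- pmin(pmax(w, .w_lo), .w_hi)
  if (sum(w) == 0) {
    message("all-zero weight vector repaired to the uniform vector at sum ",
            .w_sum_lo)
    return(weight_vector(rep(.w_sum_lo / length(w), length(w))))
  }
  for (iter in 1:10) {
    s <- sum(w)
    if (s >= .w_sum_lo - 1e-12 && s <= .w_sum_hi + 1e-12) break
    target <- if (s < .w_sum_lo) .w_sum_lo else .w_sum_hi
    w <- pmin(pmax(w * target / s, .w_lo), .w_hi)
  }
  weight_vector(w)
}

#' Fuse a probability panel under a weight vector
#'
#' Computes, for every sample, the weight-normalized average of the
#' classifiers' probability rows,
#' `s[i, k] = sum_j w_j p[j, i, k] / sum_j w_j`, the determined class
#' `dc_i = argmax_k s[i, k]` (ties broken toward the lowest class index,
#' i.e. the least severe grade), and the top fused probability `p_max`.
#' The fused rows stay on the unit simplex, so `p_max` is directly
#' comparable to a confidence threshold.
#'
#' @param panel a `probability_panel`.
#' @param weights a `weight_vector` (or numeric vector, repaired first),
#'   length equal to the panel's classifier count.
#' @return An object of class `combined_scores` with fields `sample_ids`,
#'   `s` (n x K matrix), `dc` (0-based determined class) and `p_max`.
#' @export
combine_panel <- function(panel, weights) {
  stopifnot(inherits(panel, "probability_panel"))
  if (!inherits(weights, "weight_vector")) weights <- weight_vector(weights)
  w <- weights$w
  M <- dim(panel$p)[1L]
  if (length(w) != M)
    stop(sprintf("weight length %d does not match classifier count %d", length(w), M))
  if (sum(w) <= 0) stop("weights must have positive sum")
  if (!is.null(weights$classifier_names) &&
      !identical(weights$classifier_names, panel$classifier_names))
    stop("weight classifier names do not match the panel's classifier stack")
  n <- dim(panel$p)[2L]; K <- panel$K
  flat <- panel_flat(panel)                       # M x (n*K)
  s <- matrix(crossprod(flat, w), nrow = n, ncol = K, byrow = TRUE) / sum(w)
  dc <- max.col(s, ties.method = "first") - 1L
  structure(list(sample_ids = panel$sample_ids, s = s, dc = dc,
                 p_max = s[cbind(seq_len(n), dc + 1L)], K = K),
            class = "combined_scores")
}

#' @export
print.combined_scores <- function(x, ...) {
  cat(sprintf("<combined_scores> %d samples, %d classes\n",
              length(x$sample_ids), x$K))
  cat("determined-class counts:\n")
  print(table(factor(x$dc, levels = seq_len(x$K) - 1L)))
  invisible(x)
}

#' Ordinal squared-distance fitness of a weighting
#'
#' The quantity the weight search minimizes:
#' `f(w) = sum_i |dc_i(w) - ac_i|^2`, the sum over samples of the squared
#' integer distance between the determined and actual grades.  A perfect
#' weighting scores 0; an off-by-two grade error costs four times an
#' off-by-one error, reflecting that confusing healthy tissue with a
#' high-grade carcinoma is far worse than confusing adjacent grades.
#'
#' @param panel a `probability_panel`, aligned with `labels`.
#' @param labels a `label_vector`.
#' @param weights a `weight_vector` (or numeric vector).
#' @return A list of class `fitness_value` with `f` (the fitness) and `n`
#'   (number of samples scored).
#' @export
ensemble_fitness <- function(panel, labels, weights) {
  stopifnot(inherits(labels, "label_vector"))
  if (!identical(panel$sample_ids, labels$sample_ids))
    stop("panel and labels are not aligned; call align_panel() first")
  cs <- combine_panel(panel, weights)
  f <- sum((cs$dc - labels$grades)^2)
  structure(list(f = f, n = length(labels$grades)), class = "fitness_value")
}

#' @export
print.fitness_value <- function(x, ...) {
  cat(sprintf("<fitness_value> f=%g over n=%d samples\n", x$f, x$n))
  invisible(x)
}

#' Write a weight vector as structured text
#'
#' One `classifier,weight` pair per line after a header; classifier order
#' is preserved so the file also records the stack order.
#'
#' @param weights a `weight_vector`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_vector"))
  nm <- weights$classifier_names
  if (is.null(nm)) nm <- paste0("clf", seq_along(weights$w))
  df <- data.frame(classifier = nm,
                   weight = formatC(weights$w, format = "g", digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weight vector written by [write_weights()]
#' @param path file path.
#' @return A `weight_vector`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("classifier", "weight") %in% names(df)))
    stop("weights file must have columns 'classifier' and 'weight': ", path)
  weight_vector(as.numeric(df$weight), df$classifier)
}
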