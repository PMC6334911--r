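#' Round a percentage half-up at presentation
#'
#' Reports round half-up to the given number of decimals (so 65.27310...
#' prints as 65.27 and 0.125 at two decimals prints as 0.13), as opposed to
#' R's default round-half-even.  All internal computation stays at full
#' precision; this is applied only when numbers are displayed or written.
#'
#' @param x numeric vector of percentages (or any values).
#' @param digits decimals to keep.
#' @return numeric vector rounded half-up.
#' @export
percent_round <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Confusion matrix and per-class statistics
#'
#' Builds the K x K confusion matrix with predicted classes on the rows and
#' true classes on the columns (counts and percents of the total), plus
#' one-vs-rest per-class statistics: specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)` and balanced
#' accuracy `(recall + specificity)/2`, all in percent, and the overall
#' accuracy.  A statistic whose denominator is empty (e.g. recall for a
#' class absent from the truth) is reported as `NA` with a warning.
#'
#' @param pred a `label_vector` of predicted grades.
#' @param truth a `label_vector` of actual grades (same samples, same K).
#' @return An object of class `metrics_report` with fields `counts`,
#'   `percents`, `classwise` (data frame), `accuracy` and `n`.
#' @export
classification_report <- function(pred, truth) {
  stopifnot(inherits(pred, "label_vector"), inherits(truth, "label_vector"))
  if (length(pred$grades) != length(truth$grades))
    stop("pred and truth have different lengths")
  if (pred$K != truth$K) stop("pred and truth disagree on K")
  K <- truth$K
  n <- length(truth$grades)
  lev <- seq_len(K) - 1L
  counts <- table(predicted = factor(pred$grades, levels = lev),
                  true = factor(truth$grades, levels = lev))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"
  rat <- function(num, den, what, k) {
    if (den == 0L) {
      warning(sprintf("%s undefined for class %d (empty denominator)", what, k))
      return(NA_real_)
    }
    100 * num / den
  }
  classwise <- do.call(rbind, lapply(seq_len(K), function(ki) {
    k <- ki - 1L
    TP <- counts[ki, ki]
    FP <- sum(counts[ki, ]) - TP
    FN <- sum(counts[, ki]) - TP
    TN <- n - TP - FP - FN
    precision <- rat(TP, TP + FP, "precision", k)
    recall <- rat(TP, TP + FN, "recall", k)
    specificity <- rat(TN, TN + FP, "specificity", k)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
      NA_real_ else 2 * precision * recall / (precision + recall)
    bacc <- if (is.na(recall) || is.na(specificity)) NA_real_
      else (recall + specificity) / 2
    data.frame(class = k, specificity = specificity, precision = precision,
               recall = recall, f1 = f1, balanced_accuracy = bacc)
  }))
  structure(list(counts = counts,
                 percents = 100 * counts / n,
                 classwise = classwise,
                 accuracy = 100 * sum(diag(counts)) / n,
                 n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d, accuracy %.2f%%\n", x$n,
              percent_round(x$accuracy)))
  cat("confusion matrix (counts; predicted on rows, true on columns):\n")
  print(x$counts)
  cat("per-class statistics (%):\n")
  cw <- x$classwise
  cw[-1L] <- lapply(cw[-1L], percent_round)
  print(cw, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as delimited tables
#' @param report a `metrics_report`.
#' @param path output file path (confusion percents and class statistics
#'   are appended as two labelled CSV blocks).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# overall accuracy %%,%.2f,n,%d",
                     percent_round(report$accuracy), report$n), con)
  writeLines("# confusion matrix percents (predicted rows, true columns)", con)
  write.csv(percent_round(report$percents), con, quote = FALSE)
  writeLines("# per-class statistics (%)", con)
  cw <- report$classwise
  cw[-1L] <- lapply(cw[-1L], percent_round)
  write.csv(cw, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohen's kappa between two label vectors
#'
#' Unweighted (nominal) chance-corrected agreement:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the two raters' marginal label frequencies.
#'
#' @param a,b integer vectors of labels (same length).
#' @param K number of classes (defaults to the range of the data).
#' @return kappa in `[-1, 1]`, or `NA` when both raters are constant and
#'   agreement is degenerate.
#' @export
cohen_kappa <- function(a, b, K = max(a, b) + 1L) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  po <- mean(a == b)
  pa <- tabulate(a + 1L, nbins = K) / length(a)
  pb <- tabulate(b + 1L, nbins = K) / length(b)
  pe <- sum(pa * pb)
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate marginals: chance agreement is 1, kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Pairwise classifier agreement matrices
#'
#' For every classifier pair: the Pearson correlation of the flattened
#' (sample x class) probability vectors, and Cohen's kappa of the
#' per-classifier predicted labels (argmax with the ensemble's
#' lowest-index tie rule).  Classifiers whose probability output has zero
#' variance get `NA` correlations with a warning.  High off-diagonal
#' values flag classifiers whose mistakes are redundant; the weight search
#' tends to concentrate weight on classifiers that disagree with the rest.
#'
#' @param panel a `probability_panel` with at least 2 classifiers.
#' @return An object of class `agreement_matrices` with fields `pearson`
#'   and `kappa` (both M x M, unit diagonal).
#' @export
agreement <- function(panel) {
  stopifnot(inherits(panel, "probability_panel"))
  M <- length(panel$classifier_names)
  if (M < 2L) stop("agreement needs at least 2 classifiers")
  n <- length(panel$sample_ids); K <- panel$K
  flat <- matrix(panel_flat(panel), nrow = M)     # M x (n*K)
  preds <- vapply(seq_len(M), function(j)
    max.col(matrix(panel$p[j, , ], nrow = n), ties.method = "first") - 1L,
    integer(n))
  pearson <- matrix(1, M, M); kap <- matrix(1, M, M)
  vars <- apply(flat, 1L, sd)
  if (any(vars == 0))
    warning("zero-variance probability output; Pearson undefined for that classifier")
  for (j1 in seq_len(M - 1L)) for (j2 in (j1 + 1L):M) {
    r <- if (vars[j1] == 0 || vars[j2] == 0) NA_real_
      else cor(flat[j1, ], flat[j2, ])
    pearson[j1, j2] <- pearson[j2, j1] <- r
    k <- cohen_kappa(preds[, j1], preds[, j2], K = K)
    kap[j1, j2] <- kap[j2, j1] <- k
  }
  dimnames(pearson) <- dimnames(kap) <-
    list(panel$classifier_names, panel$classifier_names)
  structure(list(pearson = pearson, kappa = kap),
            class = "agreement_matrices")
}

#' @export
print.agreement_matrices <- function(x, ...) {
  cat("<agreement_matrices>\nPearson (probability outputs):\n")
  print(round(x$pearson, 3))
  cat("Cohen's kappa (predicted labels):\n")
  print(round(x$kappa, 3))
  invisible(x)
}

#' Patient-level recognition rate
#'
#' For each patient, the fraction of that patient's samples (images)
#' classified correctly; the recognition rate is the mean of these
#' per-patient fractions, in percent.  Patients therefore count equally
#' regardless of how many images they contributed; with one image per
#' patient this reduces to the image-level accuracy.
#'
#' @param pred a `label_vector` of predicted grades.
#' @param truth a `label_vector` of actual grades (same samples).
#' @param patients a `patient_map` covering every sample.
#' @return recognition rate in percent.
#' @export
patient_level_recognition <- function(pred, truth, patients) {
  stopifnot(inherits(pred, "label_vector"), inherits(truth, "label_vector"),
            inherits(patients, "patient_map"))
  if (!identical(pred$sample_ids, truth$sample_ids))
    stop("pred and truth are not aligned")
  idx <- match(truth$sample_ids, patients$sample_ids)
  if (any(is.na(idx)))
    stop("unmapped sample(s): ",
         paste(head(truth$sample_ids[is.na(idx)], 5L), collapse = ", "))
  correct <- as.numeric(pred$grades == truth$grades)
  per_patient <- tapply(correct, patients$patient_ids[idx], mean)
  100 * mean(per_patient)
}
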