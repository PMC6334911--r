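#' @useDynLib tandemfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rnorm runif sd setNames predict qnorm rgamma
#' @importFrom utils read.csv write.csv head
NULL

# Tolerances for probability-row validation: rows off the unit simplex by no
# more than .renorm are renormalized (with a warning); beyond that, rejected.
.simplex_tol <- 1e-6
.renorm_tol <- 1e-2

#' Ground-truth grade labels for a set of samples
#'
#' Stores an ordered set of unique sample identifiers together with an
#' integer grade per sample on the ordinal scale `0 .. K-1` (grade names
#' such as `"G0" .. "G3"` map to `0 .. 3`).  Grade 0 is healthy tissue and
#' higher grades are increasingly severe, so the integer distance between
#' two grades is scientifically meaningful.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param grades integer vector (same length), each in `0 .. K-1`, or a
#'   character vector of grade names `"G<k>"`.
#' @param K number of classes (>= 2); defaults to `max(grades) + 1`.
#' @return An object of class `label_vector` with fields `sample_ids`,
#'   `grades` and `K`.
#' @export
label_vector <- function(sample_ids, grades, K = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (is.character(grades) || is.factor(grades))
    grades <- grade_to_int(grades)
  grades <- as.integer(grades)
  if (length(grades) != length(sample_ids))
    stop("grades and sample_ids must have the same length")
  if (any(is.na(grades)) || any(grades < 0L))
    stop("grades must be non-negative integers")
  if (is.null(K)) K <- max(grades, 0L) + 1L
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  if (any(grades >= K)) stop("every grade must be < K")
  structure(list(sample_ids = sample_ids, grades = grades, K = K),
            class = "label_vector")
}

#' Map grade names to the 0-based integer scale
#'
#' `"G0" .. "G3"` become `0 .. 3`; bare integers pass through.
#'
#' @param x character (or factor) vector of grade names, or integers.
#' @return integer vector.
#' @export
grade_to_int <- function(x) {
  x <- as.character(x)
  g <- sub("^[Gg]", "", x)
  suppressWarnings(out <- as.integer(g))
  if (any(is.na(out) & !is.na(x)))
    stop("unparseable grade label(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("<label_vector> %d samples, %d classes\n",
              length(x$sample_ids), x$K))
  print(table(grade = x$grades))
  invisible(x)
}

#' Per-classifier, per-sample class-probability panel
#'
#' The central container: a 3-way array `p[j, i, k]` holding the probability
#' classifier `j` assigns to class `k` for sample `i`.  Every `(j, i)` row
#' must lie on the unit simplex (entries in `[0, 1]`, summing to 1 within
#' `1e-6`).  Rows off the simplex by at most `1e-2` are renormalized with a
#' warning (tolerating print round-off in upstream tools); anything worse is
#' rejected.
#'
#' @param p numeric array with `dim = c(M, n, K)` indexed
#'   (classifier, sample, class).
#' @param classifier_names character vector of `M` unique names.
#' @param sample_ids character vector of `n` unique sample identifiers.
#' @return An object of class `probability_panel` with fields `p`,
#'   `classifier_names`, `sample_ids` and `K`.
#' @export
probability_panel <- function(p, classifier_names, sample_ids) {
  if (length(dim(p)) != 3L) stop("p must be a 3-way array (classifier, sample, class)")
  classifier_names <- as.character(classifier_names)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(classifier_names)) stop("classifier_names must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  d <- dim(p)
  if (d[1L] != length(classifier_names) || d[2L] != length(sample_ids))
    stop("array dimensions do not match classifier_names / sample_ids")
  if (d[3L] < 2L) stop("panel needs at least 2 classes")
  dimnames(p) <- list(classifier_names, sample_ids, paste0("class_", seq_len(d[3L]) - 1L))
  panel <- structure(list(p = p, classifier_names = classifier_names,
                          sample_ids = sample_ids, K = d[3L]),
                     class = "probability_panel")
  validate_panel(panel)
}

#' Validate (and possibly renormalize) a probability panel
#'
#' Checks that every entry is in `[0, 1]` and every `(classifier, sample)`
#' row sums to 1 within `1e-6`.  Rows whose sum deviates by at most `1e-2`
#' are renormalized with a warning; larger deviations are an error naming
#' the offending row.
#'
#' @param panel a `probability_panel`.
#' @return The validated (possibly renormalized) panel.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "probability_panel"))
  p <- panel$p
  if (any(!is.finite(p))) stop("panel contains non-finite probabilities")
  if (any(p < 0) || any(p > 1 + .simplex_tol))
    stop("panel probabilities must lie in [0, 1]")
  sums <- apply(p, c(1L, 2L), sum)
  dev <- abs(sums - 1)
  if (any(dev > .renorm_tol)) {
    bad <- which(dev > .renorm_tol, arr.ind = TRUE)[1L, ]
    stop(sprintf("probability row does not sum to 1 (classifier '%s', sample '%s', sum %.4f)",
                 panel$classifier_names[bad[1L]], panel$sample_ids[bad[2L]],
                 sums[bad[1L], bad[2L]]))
  }
  fix <- dev > .simplex_tol
  if (any(fix)) {
    warning(sprintf("%d probability row(s) off the simplex by <= %g; renormalized",
                    sum(fix), .renorm_tol))
    idx <- which(fix, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      j <- idx[r, 1L]; i <- idx[r, 2L]
      p[j, i, ] <- p[j, i, ] / sums[j, i]
    }
    panel$p <- p
  }
  panel
}

#' @export
print.probability_panel <- function(x, ...) {
  cat(sprintf("<probability_panel> %d classifiers x %d samples x %d classes\n",
              length(x$classifier_names), length(x$sample_ids), x$K))
  cat("classifiers:", paste(x$classifier_names, collapse = ", "), "\n")
  invisible(x)
}

#' Sample-to-patient mapping
#'
#' Used for patient-level recognition rates: each sample (image) belongs to
#' exactly one patient.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param patient_ids character vector (same length) of patient identifiers.
#' @return An object of class `patient_map`.
#' @export
patient_map <- function(sample_ids, patient_ids) {
  sample_ids <- as.character(sample_ids)
  patient_ids <- as.character(patient_ids)
  if (length(sample_ids) != length(patient_ids))
    stop("sample_ids and patient_ids must have the same length")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  structure(list(sample_ids = sample_ids, patient_ids = patient_ids),
            class = "patient_map")
}

#' Read a probability panel from delimited text
#'
#' Expects a comma-delimited file with header
#' `classifier,sample_id,class_0,...,class_{K-1}` and one row per
#' (classifier, sample) pair.  Sample order is taken from the file (first
#' appearance); every classifier must cover the same samples.
#'
#' @param path path to the panel file.
#' @return A validated `probability_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE, comment.char = "#")
  need <- c("classifier", "sample_id")
  if (!all(need %in% names(df)))
    stop("panel file must have columns 'classifier' and 'sample_id': ", path)
  prob_cols <- grep("^class_[0-9]+$", names(df), value = TRUE)
  if (length(prob_cols) < 2L)
    stop("panel file must have columns class_0 ... class_{K-1}: ", path)
  prob_cols <- paste0("class_", seq_len(length(prob_cols)) - 1L)
  if (!all(prob_cols %in% names(df)))
    stop("class_* columns must be contiguous from class_0: ", path)
  K <- length(prob_cols)
  key <- paste(df$classifier, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (classifier, sample) pair at data row %d of %s", row, path))
  }
  classifiers <- unique(df$classifier)
  samples <- unique(df$sample_id)
  M <- length(classifiers); n <- length(samples)
  if (nrow(df) != M * n)
    stop(sprintf("incomplete panel: expected %d rows (%d classifiers x %d samples), found %d",
                 M * n, M, n, nrow(df)))
  suppressWarnings(
    vals <- matrix(as.numeric(as.matrix(df[, prob_cols])), nrow = nrow(df)))
  if (any(!is.finite(vals))) {
    row <- which(rowSums(!is.finite(vals)) > 0L)[1L]
    stop(sprintf("malformed probability value at data row %d of %s", row, path))
  }
  p <- array(NA_real_, dim = c(M, n, K))
  ji <- cbind(match(df$classifier, classifiers), match(df$sample_id, samples))
  for (k in seq_len(K)) p[cbind(ji, k)] <- vals[, k]
  probability_panel(p, classifiers, samples)
}

#' Write a probability panel to delimited text
#'
#' Inverse of [read_panel()]; round-trips probabilities losslessly
#' (15 significant digits).
#'
#' @param panel a `probability_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "probability_panel"))
  M <- length(panel$classifier_names); n <- length(panel$sample_ids); K <- panel$K
  rows <- expand.grid(sample = seq_len(n), classifier = seq_len(M))[, c(2L, 1L)]
  mat <- matrix(NA_real_, nrow = M * n, ncol = K)
  for (k in seq_len(K))
    mat[, k] <- panel$p[cbind(rows$classifier, rows$sample, k)]
  df <- data.frame(classifier = panel$classifier_names[rows$classifier],
                   sample_id = panel$sample_ids[rows$sample],
                   mat, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("class_", seq_len(K) - 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  fmt <- apply(mat, 1L, function(r) paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(paste(df$classifier, df$sample_id, fmt, sep = ","), con)
  invisible(path)
}

#' Read ground-truth labels from delimited text
#'
#' Expects columns `sample_id,grade`; grades may be integers or names
#' (`G0` ...).
#'
#' @param path path to the labels file.
#' @param K optional class count (defaults to `max(grade) + 1`).
#' @return A `label_vector`.
#' @export
read_labels <- function(path, K = NULL) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "grade") %in% names(df)))
    stop("labels file must have columns 'sample_id' and 'grade': ", path)
  label_vector(df$sample_id, df$grade, K = K)
}

#' Write labels to delimited text
#' @param labels a `label_vector`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_vector"))
  df <- data.frame(sample_id = labels$sample_ids, grade = labels$grades)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample-to-patient map from delimited text
#' @param path file with columns `sample_id,patient_id`.
#' @return A `patient_map`.
#' @export
read_patient_map <- function(path) {
  if (!file.exists(path)) stop("patient map file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "patient_id") %in% names(df)))
    stop("patient map file must have columns 'sample_id' and 'patient_id': ", path)
  patient_map(df$sample_id, df$patient_id)
}

#' Write a sample-to-patient map
#' @param map a `patient_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_patient_map <- function(map, path) {
  stopifnot(inherits(map, "patient_map"))
  df <- data.frame(sample_id = map$sample_ids, patient_id = map$patient_ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a panel and a label vector on their shared samples
#'
#' Restricts both objects to the intersection of their sample identifiers,
#' in the panel's order.  Inputs whose identifier sets already match are
#' returned unchanged.
#'
#' @param panel a `probability_panel`.
#' @param labels a `label_vector`.
#' @return A list with elements `panel` and `labels`, aligned.
#' @export
align_panel <- function(panel, labels) {
  stopifnot(inherits(panel, "probability_panel"), inherits(labels, "label_vector"))
  if (panel$K != labels$K)
    stop(sprintf("class-count mismatch: panel has K=%d, labels K=%d", panel$K, labels$K))
  common <- panel$sample_ids[panel$sample_ids %in% labels$sample_ids]
  if (length(common) == 0L) stop("no samples in common between panel and labels")
  if (length(common) == length(panel$sample_ids) &&
      length(common) == length(labels$sample_ids) &&
      all(panel$sample_ids == labels$sample_ids))
    return(list(panel = panel, labels = labels))
  p <- panel$p[, match(common, panel$sample_ids), , drop = FALSE]
  panel2 <- probability_panel(p, panel$classifier_names, common)
  idx <- match(common, labels$sample_ids)
  labels2 <- label_vector(common, labels$grades[idx], K = labels$K)
  list(panel = panel2, labels = labels2)
}

# Internal: panel as an M x (n*K) matrix with column index (i-1)*K + k,
# the flat layout the C++ evaluator consumes.
panel_flat <- function(panel) {
  matrix(aperm(panel$p, c(1L, 3L, 2L)), nrow = dim(panel$p)[1L])
}

# Internal: subset a panel's samples by index, preserving order.
panel_subset <- function(panel, idx, sample_ids = NULL) {
  p <- panel$p[, idx, , drop = FALSE]
  ids <- if (is.null(sample_ids)) panel$sample_ids[idx] else sample_ids
  probability_panel(p, panel$classifier_names, ids)
}

# Internal: concatenate panels over samples (same classifiers, same K).
# Sample ids are prefixed to stay unique across blocks.
panel_rbind <- function(panels, prefixes = NULL) {
  stopifnot(length(panels) >= 1L)
  M <- length(panels[[1L]]$classifier_names); K <- panels[[1L]]$K
  for (pp in panels) {
    if (!identical(pp$classifier_names, panels[[1L]]$classifier_names))
      stop("panels have different classifier stacks")
    if (pp$K != K) stop("panels have different class counts")
  }
  ns <- vapply(panels, function(pp) length(pp$sample_ids), integer(1L))
  p <- array(NA_real_, dim = c(M, sum(ns), K))
  ids <- character(sum(ns))
  at <- 0L
  for (b in seq_along(panels)) {
    idx <- at + seq_len(ns[b])
    p[, idx, ] <- panels[[b]]$p
    pre <- if (is.null(prefixes)) sprintf("b%d:", b) else paste0(prefixes[b], ":")
    ids[idx] <- paste0(pre, panels[[b]]$sample_ids)
    at <- at + ns[b]
  }
  probability_panel(p, panels[[1L]]$classifier_names, ids)
}
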