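#' Partition fused predictions at one confidence threshold
#'
#' A sample is *trusted* when its top fused probability `p_max` reaches the
#' confidence threshold (`p_max >= t_conf`) and *unreliable* otherwise
#' (`p_max < t_conf`), so the two sets always partition the data, including
#' samples sitting exactly on the boundary.  A *failure* in either set is a
#' sample whose determined class differs from its actual grade.
#'
#' @param scores a `combined_scores` (see [combine_panel()]).
#' @param labels a `label_vector` aligned with `scores`.
#' @param t_conf threshold in `(0, 1]`.
#' @return A one-row data frame: `threshold`, counts
#'   `trusted_results`, `trusted_failures`, `unreliable_results`,
#'   `unreliable_failures`, `trusted_correct`, and the corresponding
#'   percents of the total, with attribute `index_sets` holding the four
#'   index vectors.
#' @export
confidence_partition <- function(scores, labels, t_conf) {
  stopifnot(inherits(scores, "combined_scores"), inherits(labels, "label_vector"),
            t_conf > 0, t_conf <= 1)
  if (!identical(scores$sample_ids, labels$sample_ids))
    stop("scores and labels are not aligned")
  n <- length(scores$p_max)
  trusted <- scores$p_max >= t_conf
  wrong <- scores$dc != labels$grades
  sets <- list(trusted_results = which(trusted),
               trusted_failures = which(trusted & wrong),
               unreliable_results = which(!trusted),
               unreliable_failures = which(!trusted & wrong))
  row <- data.frame(threshold = t_conf,
                    trusted_results = length(sets$trusted_results),
                    trusted_failures = length(sets$trusted_failures),
                    unreliable_results = length(sets$unreliable_results),
                    unreliable_failures = length(sets$unreliable_failures))
  row$trusted_correct <- row$trusted_results - row$trusted_failures
  for (col in c("trusted_results", "trusted_failures", "unreliable_results",
                "unreliable_failures", "trusted_correct"))
    row[[paste0(col, "_pct")]] <- 100 * row[[col]] / n
  attr(row, "index_sets") <- sets
  row
}

#' Sweep the confidence threshold over its grid
#'
#' Applies [confidence_partition()] at every threshold of the inclusive
#' grid 0.50, 0.55, ..., 1.00 (11 values by default).  As the threshold
#' rises, the trusted set — and with it the trusted failures — can only
#' shrink: the sweep exposes the trade-off between how much of the data is
#' auto-classified and how often that trusted subset is wrong.
#'
#' @param scores a `combined_scores`.
#' @param labels a `label_vector` aligned with `scores`.
#' @param thresholds threshold grid (default `seq(0.5, 1, by = 0.05)`).
#' @return An object of class `confidence_report`: the per-threshold data
#'   frame plus `n`.
#' @export
confidence_sweep <- function(scores, labels,
                             thresholds = seq(0.5, 1, by = 0.05)) {
  rows <- lapply(thresholds, function(t) {
    r <- confidence_partition(scores, labels, t)
    attr(r, "index_sets") <- NULL
    r
  })
  structure(list(table = do.call(rbind, rows), n = length(scores$p_max)),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report> %d samples, %d thresholds\n",
              x$n, nrow(x$table)))
  tab <- x$table
  pct <- grep("_pct$", names(tab))
  tab[pct] <- lapply(tab[pct], percent_round)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a confidence report as a delimited table
#' @param report a `confidence_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_confidence_report <- function(report, path) {
  stopifnot(inherits(report, "confidence_report"))
  write.csv(report$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pareto front of coverage versus trusted error
#'
#' From the sweep, keeps the nondominated (percent trusted,
#' percent trusted-but-wrong) points: a point survives unless some other
#' threshold trusts at least as many samples with no more trusted failures
#' (strictly better in one of the two).  The front is sorted by percent
#' trusted.
#'
#' @param report a `confidence_report`.
#' @return An object of class `pareto_front`: a data frame with columns
#'   `threshold`, `percent_trusted`, `percent_trusted_wrong`.
#' @export
pareto_front <- function(report) {
  stopifnot(inherits(report, "confidence_report"))
  tab <- report$table
  pts <- data.frame(threshold = tab$threshold,
                    percent_trusted = tab$trusted_results_pct,
                    percent_trusted_wrong = tab$trusted_failures_pct)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    dominated <- (pts$percent_trusted >= pts$percent_trusted[i]) &
      (pts$percent_trusted_wrong <= pts$percent_trusted_wrong[i]) &
      ((pts$percent_trusted > pts$percent_trusted[i]) |
         (pts$percent_trusted_wrong < pts$percent_trusted_wrong[i]))
    !any(dominated)
  }, logical(1L))
  front <- pts[keep, , drop = FALSE]
  front <- front[!duplicated(front[c("percent_trusted", "percent_trusted_wrong")]), ,
                 drop = FALSE]
  front <- front[order(front$percent_trusted, front$percent_trusted_wrong), ,
                 drop = FALSE]
  rownames(front) <- NULL
  structure(front, class = c("pareto_front", "data.frame"))
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %d nondominated points\n", nrow(x)))
  y <- as.data.frame(x)
  y$percent_trusted <- percent_round(y$percent_trusted)
  y$percent_trusted_wrong <- percent_round(y$percent_trusted_wrong)
  print(y, row.names = FALSE)
  invisible(x)
}
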