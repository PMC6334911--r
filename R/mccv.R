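#' Monte-Carlo cross-validation split plan
#'
#' Draws `n_trials` independent uniform random train/held-out splits of
#' `n_samples` samples.  Each trial's training set holds
#' `floor(train_fraction * n_samples)` samples and the held-out set is its
#' complement, so at the defaults (40 trials, fraction 2/3) a 357-sample
#' study yields 238 training and 119 held-out samples per trial and a
#' pooled held-out total of 4760 classifications.  The fraction is kept as
#' the exact ratio 2/3 rather than a rounded 0.67 precisely so that this
#' arithmetic holds.
#'
#' @param n_samples number of samples to split.
#' @param n_trials number of random splits.
#' @param train_fraction fraction of samples used for training, in (0, 1).
#' @param rng_seed optional integer seed.
#' @return An object of class `split_plan`: a list with `n_samples`,
#'   `n_trials`, `train_fraction`, and per-trial integer index vectors
#'   `train` and `heldout`.
#' @export
make_splits <- function(n_samples, n_trials = 40L, train_fraction = 2 / 3,
                        rng_seed = NULL) {
  stopifnot(n_samples >= 2L, n_trials >= 1L,
            train_fraction > 0, train_fraction < 1)
  n_train <- floor(train_fraction * n_samples)
  if (n_train < 1L || n_train >= n_samples)
    stop("degenerate split: train or held-out set would be empty")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  trials <- lapply(seq_len(n_trials), function(t) {
    tr <- sort(sample.int(n_samples, n_train))
    list(train = tr, heldout = setdiff(seq_len(n_samples), tr))
  })
  structure(list(n_samples = as.integer(n_samples),
                 n_trials = as.integer(n_trials),
                 train_fraction = train_fraction,
                 n_train = as.integer(n_train),
                 n_heldout = as.integer(n_samples - n_train),
                 trials = trials),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d trials of %d samples: %d train / %d held out (pooled held-out %d)\n",
              x$n_trials, x$n_samples, x$n_train, x$n_heldout,
              x$n_trials * x$n_heldout))
  invisible(x)
}

#' Write a split plan as delimited text for audit
#' @param plan a `split_plan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  df <- do.call(rbind, lapply(seq_len(plan$n_trials), function(t) {
    tr <- plan$trials[[t]]
    data.frame(trial = t,
               role = rep(c("train", "heldout"), c(length(tr$train), length(tr$heldout))),
               sample_index = c(tr$train, tr$heldout))
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-trial held-out panels and labels
#'
#' The unit the weight-search protocol consumes: for each Monte-Carlo
#' trial, the probability panel the (re-trained) classifier stack produced
#' on that trial's held-out samples, together with the held-out ground
#' truth.  All trials must share the classifier stack and class count, and
#' each panel must be aligned with its labels.
#'
#' @param panels list of `probability_panel`, one per trial.
#' @param labels list of `label_vector`, one per trial.
#' @return An object of class `trial_outputs`.
#' @export
trial_outputs <- function(panels, labels) {
  stopifnot(length(panels) == length(labels), length(panels) >= 1L)
  for (t in seq_along(panels)) {
    stopifnot(inherits(panels[[t]], "probability_panel"),
              inherits(labels[[t]], "label_vector"))
    if (!identical(panels[[t]]$sample_ids, labels[[t]]$sample_ids))
      stop(sprintf("trial %d: panel and labels are not aligned", t))
    if (!identical(panels[[t]]$classifier_names, panels[[1L]]$classifier_names))
      stop(sprintf("trial %d: classifier stack differs from trial 1", t))
    if (panels[[t]]$K != panels[[1L]]$K)
      stop(sprintf("trial %d: class count differs from trial 1", t))
  }
  structure(list(panels = panels, labels = labels,
                 classifier_names = panels[[1L]]$classifier_names,
                 K = panels[[1L]]$K),
            class = "trial_outputs")
}

#' @export
print.trial_outputs <- function(x, ...) {
  ns <- vapply(x$labels, function(l) length(l$grades), integer(1L))
  cat(sprintf("<trial_outputs> %d trials, %d classifiers, %d classes, %d pooled held-out samples\n",
              length(x$panels), length(x$classifier_names), x$K, sum(ns)))
  invisible(x)
}

# Pool a subset of trials into one aligned panel + label vector.  Sample ids
# are prefixed with the trial index: the same underlying sample legitimately
# appears in several trials' held-out sets.
pool_trials <- function(trials, idx = seq_along(trials$panels)) {
  stopifnot(inherits(trials, "trial_outputs"), length(idx) >= 1L)
  prefixes <- sprintf("t%d", idx)
  panel <- panel_rbind(trials$panels[idx], prefixes)
  grades <- unlist(lapply(trials$labels[idx], `[[`, "grades"), use.names = FALSE)
  labels <- label_vector(panel$sample_ids, grades, K = trials$K)
  list(panel = panel, labels = labels)
}

#' Repeated weight search with selection by complementary-set error
#'
#' Runs the weight search `n_runs` times.  Each run draws a random subset
#' of `subset_size` trials, pools their held-out samples, and optimizes the
#' weights there by differential evolution; the run's weighting is then
#' scored by its plain misclassification count on the pooled samples of the
#' complementary trials.  The overall winner is the weighting with the
#' lowest complementary error (ties broken by lower fitness on the run's
#' own subset, then by run index), so the selected weighting is the one
#' that extrapolates best beyond the trials it was tuned on.
#'
#' @param trials a `trial_outputs`.
#' @param n_runs number of optimization runs.
#' @param subset_size trials per optimization subset (default: half).
#' @param config a [de_config()] for the per-run search (a per-run
#'   `rng_seed` inside it is ignored; seed the protocol instead).
#' @param rng_seed optional integer seed for the whole protocol.
#' @param progress print a line per run.
#' @return An object of class `weight_search_result`: per-run records
#'   (`subset`, `weights`, `subset_fitness`, `complementary_errors`,
#'   `complementary_n`) plus `selected_weights` and `selected_run`.
#' @export
run_weight_search <- function(trials, n_runs = 100L, subset_size = NULL,
                              config = de_config(), rng_seed = NULL,
                              progress = FALSE) {
  stopifnot(inherits(trials, "trial_outputs"), n_runs >= 1L)
  n_trials <- length(trials$panels)
  if (is.null(subset_size)) subset_size <- n_trials %/% 2L
  stopifnot(subset_size >= 1L, subset_size <= n_trials)
  if (!is.null(config$rng_seed)) {
    warning("per-run DE rng_seed ignored inside run_weight_search; seed the protocol")
    config$rng_seed <- NULL
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  all_idx <- seq_len(n_trials)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    subset <- sort(sample(all_idx, subset_size))
    comp <- setdiff(all_idx, subset)
    opt <- pool_trials(trials, subset)
    fit <- optimize_weights(opt$panel, opt$labels, config)
    if (length(comp) > 0L) {
      held <- pool_trials(trials, comp)
      cs <- combine_panel(held$panel, fit$best_weights)
      comp_err <- sum(cs$dc != held$labels$grades)
      comp_n <- length(held$labels$grades)
    } else {
      comp_err <- NA_integer_; comp_n <- 0L
    }
    runs[[r]] <- list(subset = subset, weights = fit$best_weights,
                      subset_fitness = fit$best_fitness$f,
                      complementary_errors = comp_err,
                      complementary_n = comp_n)
    if (progress)
      message(sprintf("run %d/%d: subset fitness %g, complementary errors %s",
                      r, n_runs, fit$best_fitness$f, comp_err))
  }
  comp_errs <- vapply(runs, `[[`, numeric(1L), "complementary_errors")
  own_fit <- vapply(runs, `[[`, numeric(1L), "subset_fitness")
  sel <- order(comp_errs, own_fit, seq_len(n_runs))[1L]
  stopifnot(all(comp_errs[sel] <= comp_errs, na.rm = TRUE))
  structure(list(runs = runs,
                 selected_run = sel,
                 selected_weights = runs[[sel]]$weights,
                 selected_complementary_errors = comp_errs[sel],
                 n_trials = n_trials, subset_size = as.integer(subset_size)),
            class = "weight_search_result")
}

#' @export
print.weight_search_result <- function(x, ...) {
  cat(sprintf("<weight_search_result> %d runs; selected run %d with %g complementary errors\n",
              length(x$runs), x$selected_run, x$selected_complementary_errors))
  print(x$selected_weights)
  invisible(x)
}

#' Write per-run weight-search records as delimited text
#' @param result a `weight_search_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weight_search <- function(result, path) {
  stopifnot(inherits(result, "weight_search_result"))
  rows <- lapply(seq_along(result$runs), function(r) {
    run <- result$runs[[r]]
    data.frame(run = r,
               subset = paste(run$subset, collapse = " "),
               subset_fitness = run$subset_fitness,
               complementary_errors = run$complementary_errors,
               complementary_n = run$complementary_n,
               selected = as.integer(r == result$selected_run),
               t(setNames(run$weights$w,
                          paste0("w_", seq_along(run$weights$w)))))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a weighting to every trial and summarize accuracy
#'
#' Fuses each trial's held-out panel under `weights`, reports per-trial
#' accuracy in percent with its mean, standard deviation, minimum and
#' maximum over trials, and returns the pooled fused scores and pooled
#' labels for downstream confidence triage.
#'
#' @param trials a `trial_outputs`.
#' @param weights a `weight_vector`.
#' @return An object of class `weighting_evaluation` with fields
#'   `per_trial_accuracy`, `mean`, `sd`, `min`, `max` (percents),
#'   `pooled_accuracy`, `pooled_scores` (a `combined_scores`) and
#'   `pooled_labels`.
#' @export
apply_weighting <- function(trials, weights) {
  stopifnot(inherits(trials, "trial_outputs"))
  if (!inherits(weights, "weight_vector")) weights <- weight_vector(weights)
  if (!is.null(weights$classifier_names) &&
      !identical(weights$classifier_names, trials$classifier_names))
    stop("weight classifier names do not match the trials' classifier stack")
  acc <- vapply(seq_along(trials$panels), function(t) {
    cs <- combine_panel(trials$panels[[t]], weights)
    100 * mean(cs$dc == trials$labels[[t]]$grades)
  }, numeric(1L))
  pooled <- pool_trials(trials)
  cs <- combine_panel(pooled$panel, weights)
  correct <- sum(cs$dc == pooled$labels$grades)
  structure(list(per_trial_accuracy = acc,
                 mean = mean(acc), sd = sd(acc), min = min(acc), max = max(acc),
                 pooled_accuracy = 100 * correct / length(pooled$labels$grades),
                 pooled_correct = correct,
                 pooled_n = length(pooled$labels$grades),
                 pooled_scores = cs,
                 pooled_labels = pooled$labels),
            class = "weighting_evaluation")
}

#' @export
print.weighting_evaluation <- function(x, ...) {
  cat(sprintf("<weighting_evaluation> accuracy %% over %d trials: mean %.2f, sd %.2f, min %.2f, max %.2f\n",
              length(x$per_trial_accuracy), x$mean, x$sd, x$min, x$max))
  cat(sprintf("pooled: %d/%d correct (%.2f%%)\n",
              x$pooled_correct, x$pooled_n, x$pooled_accuracy))
  invisible(x)
}
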