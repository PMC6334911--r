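#' Specification for a synthetic labeled probability-panel study
#'
#' Describes the study conditions the generator emulates: a four-class
#' grade distribution of 62/96/99/100 samples (healthy G0 through grade
#' G3), six classifiers whose target accuracies default to the individual
#' test accuracies observed for the RF / kNN / SVM / LR / NB / FTT+PCA
#' stack (0.905, 0.9389, 0.9504, 0.942, 0.8676, 0.9046), a pairwise
#' error-correlation parameter `rho` realized through a shared per-sample
#' difficulty latent, and a concentration `conc` controlling how sharply
#' each probability row peaks on the classifier's chosen class.
#'
#' @param class_counts integer vector of per-grade sample counts.
#' @param accuracies named or unnamed vector of per-classifier target
#'   accuracies in (0, 1] (1 gives an always-correct classifier).
#' @param rho error-correlation parameter in `[0, 1)`: 0 gives
#'   conditionally independent errors, values near 1 make classifiers fail
#'   on the same (difficult) samples and agree on the same wrong grade.
#' @param conc concentration (> 0) of the probability rows on the chosen
#'   class; rows backing wrong predictions use half this concentration
#'   (errors tend to be less confident).
#' @param rng_seed optional integer seed stored with the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_counts = c(62L, 96L, 99L, 100L),
                           accuracies = c(RF = 0.905, kNN = 0.9389,
                                          SVM = 0.9504, LR = 0.942,
                                          NB = 0.8676, "FTT+PCA" = 0.9046),
                           rho = 0.3, conc = 12, rng_seed = NULL) {
  class_counts <- as.integer(class_counts)
  stopifnot(length(class_counts) >= 2L, all(class_counts >= 0L),
            sum(class_counts) >= 2L,
            all(accuracies > 0), all(accuracies <= 1),
            rho >= 0, rho < 1, conc > 0)
  if (any(class_counts == 0L))
    stop("zero-count class: drop the class or give it samples")
  if (is.null(names(accuracies)))
    names(accuracies) <- paste0("clf", seq_along(accuracies))
  structure(list(class_counts = class_counts,
                 K = length(class_counts),
                 n = sum(class_counts),
                 accuracies = accuracies,
                 rho = rho, conc = conc, rng_seed = rng_seed),
            class = "synthetic_spec")
}

#' Generate grade labels with exact class counts
#'
#' Produces `sum(class_counts)` labels containing exactly the requested
#' number of samples per grade, in seed-reproducible shuffled order.
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed optional seed (overrides the spec's).
#' @return A `label_vector` with sample ids `s0001`, `s0002`, ...
#' @export
generate_labels <- function(spec = synthetic_spec(), rng_seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- if (!is.null(rng_seed)) rng_seed else spec$rng_seed
  if (!is.null(seed)) set.seed(seed)
  grades <- sample(rep(seq_len(spec$K) - 1L, spec$class_counts))
  ids <- sprintf("s%04d", seq_along(grades))
  label_vector(ids, grades, K = spec$K)
}

# One probability row peaked on `chosen`: Dirichlet-style gamma draws with
# extra concentration on the chosen class; if the sampled maximum lands
# elsewhere the two entries are swapped, so the argmax equals `chosen`
# exactly and realized accuracies match their targets.
.peaked_rows <- function(n_rows, K, chosen, conc) {
  g <- matrix(rgamma(n_rows * K, shape = 1), n_rows, K)
  g[cbind(seq_len(n_rows), chosen)] <- rgamma(n_rows, shape = conc + 1)
  rows <- g / rowSums(g)
  amax <- max.col(rows, ties.method = "first")
  swap <- which(amax != chosen)
  if (length(swap)) {
    i <- cbind(swap, amax[swap]); c <- cbind(swap, chosen[swap])
    tmp <- rows[i]; rows[i] <- rows[c]; rows[c] <- tmp
  }
  rows
}

#' Generate a classifier probability panel with controlled accuracy and
#' error correlation
#'
#' Each sample carries a latent difficulty `z_i ~ N(0, 1)` shared across
#' classifiers.  Classifier `j` is correct on sample `i` when
#' `sqrt(rho) z_i + sqrt(1 - rho) e_ij` exceeds the normal quantile of
#' `1 - a_j`, so its marginal accuracy is exactly `a_j` while `rho`
#' controls how strongly errors co-occur on the difficult samples.  Wrong
#' predictions land on a shared per-sample decoy grade with probability
#' `rho` (otherwise a fresh uniform draw among the other grades), so high
#' `rho` also makes wrong classifiers agree on the wrong label.  The
#' emitted row is a unit-sum vector concentrated on the chosen class.
#'
#' @param labels a `label_vector`.
#' @param spec a [synthetic_spec()] (its `K` must match the labels).
#' @param rng_seed optional seed.
#' @return A `probability_panel` with one slice per accuracy in the spec.
#' @export
generate_panel <- function(labels, spec = synthetic_spec(), rng_seed = NULL) {
  stopifnot(inherits(labels, "label_vector"), inherits(spec, "synthetic_spec"))
  if (labels$K != spec$K) stop("labels and spec disagree on K")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- length(labels$grades); K <- spec$K
  M <- length(spec$accuracies)
  truth1 <- labels$grades + 1L
  z <- rnorm(n)
  decoy1 <- vapply(truth1, function(t)
    sample(setdiff(seq_len(K), t), 1L), integer(1L))
  p <- array(NA_real_, dim = c(M, n, K))
  for (j in seq_len(M)) {
    a <- spec$accuracies[j]
    u <- sqrt(spec$rho) * z + sqrt(1 - spec$rho) * rnorm(n)
    correct <- u > qnorm(1 - a)
    chosen <- truth1
    nw <- sum(!correct)
    if (nw > 0L) {
      use_decoy <- runif(nw) < spec$rho
      own <- vapply(truth1[!correct], function(t)
        sample(setdiff(seq_len(K), t), 1L), integer(1L))
      chosen[!correct] <- ifelse(use_decoy, decoy1[!correct], own)
    }
    rows <- matrix(NA_real_, n, K)
    rows[correct, ] <- .peaked_rows(sum(correct), K, chosen[correct], spec$conc)
    if (nw > 0L)
      rows[!correct, ] <- .peaked_rows(nw, K, chosen[!correct], spec$conc / 2)
    p[j, , ] <- rows
  }
  probability_panel(p, names(spec$accuracies), labels$sample_ids)
}

#' Construct a panel with a planted optimal weighting
#'
#' Builds a labeled panel on which the supplied weighting `w_star`
#' classifies every sample correctly while the equal-weight combination
#' misclassifies at least 10% of samples — the recovery oracle for the
#' weight search.  Samples fall into blocks: an easy block where all
#' classifiers are confidently right; a trap block where a low-weight
#' majority of classifiers is confidently wrong on a decoy grade while the
#' high-weight minority is right (equal weights follow the majority,
#' `w_star` follows the weighty minority); and, when the weights allow it,
#' a block where the single heaviest classifier is wrong, which keeps
#' one-classifier weightings from being optimal.  The construction is
#' verified at build time (zero fitness under `w_star`, >= `trap_fraction`
#' equal-weight errors) and retried with fresh noise before failing.
#'
#' @param n number of samples.
#' @param M number of classifiers (>= 2).
#' @param w_star a feasible `weight_vector` (or numeric vector) that must
#'   admit a minority-by-count, majority-by-weight classifier subset.
#' @param K number of classes.
#' @param trap_fraction fraction of samples in the trap block (>= 0.1 to
#'   guarantee the equal-weight failure rate).
#' @param rng_seed optional seed.
#' @return A list with elements `panel`, `labels` and `w_star`.
#' @export
planted_optimum_panel <- function(n, M, w_star, K = 4L, trap_fraction = 0.15,
                                  rng_seed = NULL) {
  if (M < 2L)
    stop("planted optimum needs at least 2 classifiers (no weighting freedom with M=1)")
  if (!inherits(w_star, "weight_vector")) w_star <- weight_vector(w_star)
  if (length(w_star$w) != M) stop("w_star length must equal M")
  stopifnot(n >= 10L, K >= 2L, trap_fraction >= 0.1, trap_fraction < 0.9)
  w <- w_star$w
  ord <- order(w, decreasing = TRUE)
  strong <- NULL
  for (k in seq_len(max(1L, floor((M - 1) / 2)))) {
    H <- ord[seq_len(k)]
    if (sum(w[H]) > sum(w[-H]) + 1e-6) { strong <- H; break }
  }
  if (is.null(strong))
    stop("infeasible w_star: no minority-by-count subset carries a majority of the weight")
  heavy <- ord[1L]
  heavy_wrong_ok <- sum(w[-heavy]) > w[heavy] + 1e-6
  if (!is.null(rng_seed)) set.seed(rng_seed)

  q <- 0.9                                 # confidence of the designed votes
  base_row <- function(chosen1) {
    r <- rep((1 - q) / (K - 1), K); r[chosen1] <- q; r
  }
  build <- function() {
    grades <- sample(seq_len(K) - 1L, n, replace = TRUE)
    n_trap <- ceiling(trap_fraction * n)
    n_supp <- if (heavy_wrong_ok) max(2L, round(0.05 * n)) else 0L
    kind <- rep("easy", n)
    kind[sample.int(n, n_trap + n_supp)] <- rep(c("trap", "supp"),
                                                c(n_trap, n_supp))
    truth1 <- grades + 1L
    decoy1 <- vapply(truth1, function(t)
      sample(setdiff(seq_len(K), t), 1L), integer(1L))
    p <- array(NA_real_, dim = c(M, n, K))
    for (i in seq_len(n)) {
      for (j in seq_len(M)) {
        wrong <- (kind[i] == "trap" && !(j %in% strong)) ||
          (kind[i] == "supp" && j == heavy)
        chosen <- if (wrong) decoy1[i] else truth1[i]
        eta <- runif(1L, 0, 0.05)
        noise <- rgamma(K, 1); noise <- noise / sum(noise)
        p[j, i, ] <- (1 - eta) * base_row(chosen) + eta * noise
      }
    }
    panel <- probability_panel(p, sprintf("clf%d", seq_len(M)),
                               sprintf("s%04d", seq_len(n)))
    labels <- label_vector(panel$sample_ids, grades, K = K)
    list(panel = panel, labels = labels)
  }
  for (attempt in 1:20) {
    out <- build()
    f_star <- ensemble_fitness(out$panel, out$labels, w_star)$f
    eq <- combine_panel(out$panel, repair_weights(rep(1, M)))
    eq_err <- mean(eq$dc != out$labels$grades)
    if (f_star == 0 && eq_err >= 0.1)
      return(list(panel = out$panel, labels = out$labels, w_star = w_star))
  }
  stop("could not construct a planted-optimum panel with the required margins")
}

#' Simulate per-trial held-out panels for the full protocol
#'
#' For each trial of a split plan, draws a fresh probability panel on that
#' trial's held-out samples — emulating a classifier stack independently
#' re-trained on each trial's training split — together with the held-out
#' ground truth.
#'
#' @param plan a [make_splits()] plan over `length(labels$grades)` samples.
#' @param labels a `label_vector` for the full sample set.
#' @param spec a [synthetic_spec()].
#' @param rng_seed optional seed.
#' @return A `trial_outputs`.
#' @export
simulate_trials <- function(plan, labels, spec = synthetic_spec(),
                            rng_seed = NULL) {
  stopifnot(inherits(plan, "split_plan"), inherits(labels, "label_vector"))
  if (plan$n_samples != length(labels$grades))
    stop("plan and labels disagree on the number of samples")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  panels <- vector("list", plan$n_trials)
  labs <- vector("list", plan$n_trials)
  for (t in seq_len(plan$n_trials)) {
    idx <- plan$trials[[t]]$heldout
    labs[[t]] <- label_vector(labels$sample_ids[idx], labels$grades[idx],
                              K = labels$K)
    panels[[t]] <- generate_panel(labs[[t]], spec)
  }
  trial_outputs(panels, labs)
}
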