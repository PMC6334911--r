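#' Control parameters for the differential-evolution weight search
#'
#' Defaults follow the protocol the package implements throughout: a
#' population of 50 candidate weightings evolved for at most 1000
#' generations with crossover probability 0.5 and differential weight 0.6,
#' under the box constraint `[0, 1]` per classifier and the sum constraint
#' `[0.5, 2]`.  The run stops early once the best fitness has been
#' unchanged for `convergence_window` generations while the population
#' fitness spread is below `convergence_tol`.
#'
#' @param population_size number of candidate vectors (>= 4).
#' @param max_iterations generation cap.
#' @param crossover_probability binomial crossover rate `CR` in `(0, 1]`.
#' @param differential_weight scale factor `F` (> 0) on the difference vector.
#' @param lower,upper per-coordinate box bounds.
#' @param sum_lower,sum_upper bounds on the weight total.
#' @param convergence_tol population fitness spread below which the search
#'   may stop early.
#' @param convergence_window generations the best fitness must stay
#'   unchanged before an early stop.
#' @param rng_seed optional integer seed applied at the start of the run.
#' @return An object of class `de_config`.
#' @export
de_config <- function(population_size = 50L, max_iterations = 1000L,
                      crossover_probability = 0.5, differential_weight = 0.6,
                      lower = 0, upper = 1, sum_lower = 0.5, sum_upper = 2,
                      convergence_tol = 1e-8, convergence_window = 50L,
                      rng_seed = NULL) {
  stopifnot(population_size >= 4L,
            crossover_probability > 0, crossover_probability <= 1,
            differential_weight > 0,
            lower < upper, sum_lower < sum_upper,
            max_iterations >= 1L, convergence_window >= 1L,
            convergence_tol >= 0)
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 crossover_probability = crossover_probability,
                 differential_weight = differential_weight,
                 lower = lower, upper = upper,
                 sum_lower = sum_lower, sum_upper = sum_upper,
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 rng_seed = rng_seed),
            class = "de_config")
}

de_result <- function(best_weights, best_fitness, n, generations, history,
                      classifier_names = NULL) {
  structure(list(best_weights = weight_vector(best_weights, classifier_names),
                 best_fitness = structure(list(f = best_fitness, n = n),
                                          class = "fitness_value"),
                 generations_run = generations,
                 fitness_history = history),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> best fitness %g after %d generations\n",
              x$best_fitness$f, x$generations_run))
  print(x$best_weights)
  invisible(x)
}

#' Optimize classifier weights by differential evolution
#'
#' Minimizes the ordinal squared-distance fitness (see
#' [ensemble_fitness()]) over the feasible weight region using the
#' DE/rand/1/bin scheme: uniform box initialization followed by repair,
#' mutation `v = x_r1 + F (x_r2 - x_r3)` with distinct indices, binomial
#' crossover with one guaranteed coordinate, repair of every trial vector,
#' and greedy one-to-one selection (ties keep the parent).  The best
#' fitness trace is non-increasing and the run is fully reproducible from
#' the seed.
#'
#' @param panel a `probability_panel`, aligned with `labels`.
#' @param labels a `label_vector`.
#' @param config a [de_config()].
#' @return An object of class `de_result` with fields `best_weights`,
#'   `best_fitness`, `generations_run` and `fitness_history`.
#' @export
optimize_weights <- function(panel, labels, config = de_config()) {
  stopifnot(inherits(panel, "probability_panel"), inherits(labels, "label_vector"),
            inherits(config, "de_config"))
  if (!identical(panel$sample_ids, labels$sample_ids))
    stop("panel and labels are not aligned; call align_panel() first")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  res <- de_run(panel_flat(panel), labels$grades, panel$K,
                length(panel$classifier_names),
                config$population_size, config$max_iterations,
                config$crossover_probability, config$differential_weight,
                config$lower, config$upper, config$sum_lower, config$sum_upper,
                config$convergence_tol, config$convergence_window)
  de_result(res$best_weights, res$best_fitness, length(labels$grades),
            res$generations, res$history, panel$classifier_names)
}

#' Exhaustive lattice search over the feasible weight region
#'
#' Test oracle: evaluates the ordinal squared-distance fitness at every
#' point of the lattice `{0, step, ..., 1}^M` whose coordinate sum lies in
#' `[0.5, 2]`, and returns the lattice minimum (ties broken
#' lexicographically on the weight vector).  Guarded against lattices
#' larger than 10^7 points.
#'
#' @param panel a `probability_panel`, aligned with `labels`.
#' @param labels a `label_vector`.
#' @param step lattice spacing in `(0, 1]`.
#' @return A `de_result` (with `generations_run = 0` and a singleton
#'   history), plus attribute `n_grid` giving the feasible lattice size.
#' @export
grid_oracle <- function(panel, labels, step = 0.05) {
  stopifnot(inherits(panel, "probability_panel"), inherits(labels, "label_vector"),
            step > 0, step <= 1)
  if (!identical(panel$sample_ids, labels$sample_ids))
    stop("panel and labels are not aligned; call align_panel() first")
  M <- length(panel$classifier_names)
  pts <- seq(0, 1, by = step)
  if (length(pts)^M > 1e7)
    stop(sprintf("grid too large: %d^%d points exceeds the 1e7 guard",
                 length(pts), M))
  grid <- as.matrix(expand.grid(rep(list(pts), M), KEEP.OUT.ATTRS = FALSE))
  sums <- rowSums(grid)
  grid <- grid[sums >= 0.5 - 1e-12 & sums <= 2 + 1e-12, , drop = FALSE]
  if (nrow(grid) == 0L) stop("no feasible lattice points at this step")
  f <- de_eval_population(grid, panel_flat(panel), labels$grades, panel$K)
  cand <- which(f == min(f))
  # lexicographic tie-break on the weight coordinates
  if (length(cand) > 1L) {
    ord <- do.call(order, as.data.frame(grid[cand, , drop = FALSE]))
    cand <- cand[ord[1L]]
  }
  out <- de_result(grid[cand[1L], ], f[cand[1L]], length(labels$grades),
                   0L, f[cand[1L]], panel$classifier_names)
  attr(out, "n_grid") <- nrow(grid)
  out
}
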