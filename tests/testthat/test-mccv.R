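test_that("split plans partition samples with floor-2/3 training sets", {
  plan <- make_splits(357, rng_seed = 1)
  expect_equal(plan$n_train, 238L)
  expect_equal(plan$n_heldout, 119L)
  expect_equal(plan$n_trials * plan$n_heldout, 4760L)
  for (tr in plan$trials) {
    expect_identical(sort(c(tr$train, tr$heldout)), seq_len(357L))
    expect_length(tr$train, 238L)
  }

  small <- make_splits(3, n_trials = 1, train_fraction = 2 / 3, rng_seed = 2)
  expect_length(small$trials[[1]]$train, 2L)
  expect_length(small$trials[[1]]$heldout, 1L)

  expect_identical(make_splits(50, 5, rng_seed = 7),
                   make_splits(50, 5, rng_seed = 7))
  expect_error(make_splits(3, train_fraction = 0.01), "degenerate")
})

make_tiny_trials <- function(n_trials = 4L, n = 16L, seed = 1) {
  spec <- synthetic_spec(class_counts = rep(n %/% 4, 4),
                         accuracies = c(a = 0.95, b = 0.8, c = 0.7),
                         rho = 0, conc = 20)
  labels <- generate_labels(spec, rng_seed = seed)
  plan <- make_splits(n, n_trials, rng_seed = seed + 1)
  simulate_trials(plan, labels, spec, rng_seed = seed + 2)
}

test_that("weight search selects by complementary error with full audit", {
  # a dominant, always-correct classifier drives complementary error to zero
  truth_grades <- rep(0:3, 5)
  mk_trial <- function(seed) {
    set.seed(seed)
    right <- forced_panel(truth_grades)
    noise <- random_panel(1, 20, 4, seed = seed)
    panel <- panel_from_mats(list(matrix(right$p[1, , ], ncol = 4),
                                  matrix(noise$p[1, , ], ncol = 4)),
                             classifier_names = c("oracle", "noise"))
    list(panel = panel,
         labels = label_vector(panel$sample_ids, truth_grades, K = 4L))
  }
  trials <- lapply(1:4, mk_trial)
  to <- trial_outputs(lapply(trials, `[[`, "panel"),
                      lapply(trials, `[[`, "labels"))
  cfg <- de_config(population_size = 10, max_iterations = 60,
                   convergence_window = 10)
  res <- run_weight_search(to, n_runs = 3, subset_size = 2, config = cfg,
                           rng_seed = 5)
  expect_equal(res$selected_complementary_errors, 0)
  comp <- vapply(res$runs, `[[`, numeric(1), "complementary_errors")
  expect_true(all(res$selected_complementary_errors <= comp))

  one <- run_weight_search(to, n_runs = 1, subset_size = 2, config = cfg,
                           rng_seed = 6)
  expect_identical(one$selected_run, 1L)
  expect_identical(one$selected_weights, one$runs[[1]]$weights)

  f <- withr::local_tempfile(fileext = ".csv")
  write_weight_search(res, f)
  audit <- read.csv(f)
  expect_equal(nrow(audit), 3L)
  expect_equal(sum(audit$selected), 1L)
})

test_that("selected weighting beats equal weights on planted trials", {
  w_star <- c(0.95, 0.95, 0.03, 0.03, 0.02, 0.02)
  cfg <- de_config(population_size = 20, max_iterations = 150,
                   convergence_window = 20)
  better <- 0L
  for (rep in 1:3) {
    po <- planted_optimum_panel(80, 6, w_star, rng_seed = rep)
    # carve the one planted panel into 4 disjoint pseudo-trials
    idx <- split(seq_len(80), rep(1:4, each = 20))
    panels <- lapply(idx, function(i) tandemfuse:::panel_subset(po$panel, i))
    labels <- lapply(idx, function(i)
      label_vector(po$labels$sample_ids[i], po$labels$grades[i], K = 4L))
    to <- trial_outputs(panels, labels)
    res <- run_weight_search(to, n_runs = 2, subset_size = 2, config = cfg,
                             rng_seed = rep + 10)
    eq <- apply_weighting(to, repair_weights(rep(1, 6)))
    sel <- apply_weighting(to, res$selected_weights)
    if (sel$pooled_accuracy >= eq$pooled_accuracy) better <- better + 1L
  }
  expect_gte(better, 2L)
})

test_that("weighting evaluation reports trial statistics and pooled recount", {
  trials <- make_tiny_trials(n_trials = 5L, seed = 3)
  w <- repair_weights(rep(1, 3))
  ev <- apply_weighting(trials, w)
  expect_length(ev$per_trial_accuracy, 5L)
  expect_equal(ev$mean, mean(ev$per_trial_accuracy))
  expect_equal(ev$min, min(ev$per_trial_accuracy))
  # pooled accuracy equals a direct recount over the trials
  correct <- 0L; total <- 0L
  for (t in 1:5) {
    cs <- combine_panel(trials$panels[[t]], w)
    correct <- correct + sum(cs$dc == trials$labels[[t]]$grades)
    total <- total + length(trials$labels[[t]]$grades)
  }
  expect_equal(ev$pooled_accuracy, 100 * correct / total)
  expect_equal(ev$pooled_n, total)

  # all-correct trials collapse the accuracy distribution to 100
  truth_grades <- rep(0:3, 4)
  perfect <- lapply(1:3, function(t) forced_panel(truth_grades))
  labs <- lapply(perfect, function(p)
    label_vector(p$sample_ids, truth_grades, K = 4L))
  evp <- apply_weighting(trial_outputs(perfect, labs), weight_vector(1))
  expect_equal(evp$mean, 100)
  expect_equal(evp$sd, 0)
  expect_equal(c(evp$min, evp$max), c(100, 100))
})

test_that("trial containers validate alignment and stacks", {
  trials <- make_tiny_trials(n_trials = 2L, seed = 4)
  bad_labels <- trials$labels
  bad_labels[[2]] <- label_vector(rev(trials$labels[[2]]$sample_ids),
                                  trials$labels[[2]]$grades, K = 4L)
  expect_error(trial_outputs(trials$panels, bad_labels), "aligned")
  expect_error(apply_weighting(trials,
                               weight_vector(c(0.3, 0.3, 0.3),
                                             c("x", "y", "z"))),
               "classifier")
})
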