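test_that("the trusted/unreliable partition follows the threshold rule", {
  sc <- make_scores(p_max = c(0.9, 0.6), dc = c(1L, 2L))
  lab <- label_vector(sc$sample_ids, c(1L, 2L), K = 4L)
  row <- confidence_partition(sc, lab, 0.8)
  expect_equal(row$trusted_results, 1L)
  expect_equal(row$trusted_failures, 0L)
  expect_equal(row$unreliable_results, 1L)
  expect_equal(row$unreliable_failures, 0L)

  # at the K-class uniform value every sample is trusted
  sc2 <- make_scores(p_max = rep(0.25, 4), dc = 0:3)
  lab2 <- label_vector(sc2$sample_ids, 0:3, K = 4L)
  row2 <- confidence_partition(sc2, lab2, 0.25)
  expect_equal(row2$trusted_results, 4L)
  expect_equal(row2$unreliable_results, 0L)

  # all-wrong predictions saturate the trusted failures
  sc3 <- make_scores(p_max = c(0.7, 0.9, 0.55), dc = c(0L, 1L, 2L))
  lab3 <- label_vector(sc3$sample_ids, c(1L, 2L, 3L), K = 4L)
  row3 <- confidence_partition(sc3, lab3, 0.5)
  expect_equal(row3$trusted_failures, row3$trusted_results)
  expect_equal(row3$trusted_correct, 0L)
})

test_that("the sweep covers the 11-point grid with monotone trusted counts", {
  set.seed(21)
  sc <- make_scores(p_max = runif(200, 0.25, 1),
                    dc = sample(0:3, 200, replace = TRUE))
  lab <- label_vector(sc$sample_ids, sample(0:3, 200, replace = TRUE), K = 4L)
  sw <- confidence_sweep(sc, lab)
  expect_equal(nrow(sw$table), 11L)
  expect_equal(sw$table$threshold, seq(0.5, 1, by = 0.05))
  expect_true(all(diff(sw$table$trusted_results) <= 0))
  expect_true(all(diff(sw$table$trusted_failures) <= 0))
  expect_equal(sw$table$trusted_results + sw$table$unreliable_results,
               rep(200L, 11L))

  # boundary: threshold 1 keeps only p_max exactly 1
  sc1 <- make_scores(p_max = c(1, 0.999, 1), dc = c(0L, 1L, 2L))
  lab1 <- label_vector(sc1$sample_ids, c(0L, 1L, 2L), K = 4L)
  sw1 <- confidence_sweep(sc1, lab1, thresholds = 1)
  expect_equal(sw1$table$trusted_results, 2L)
})

test_that("partition invariants hold at exact-boundary top probabilities", {
  sc <- make_scores(p_max = c(0.85, 0.85, 0.8499999), dc = c(0L, 1L, 2L))
  lab <- label_vector(sc$sample_ids, c(0L, 0L, 2L), K = 4L)
  row <- confidence_partition(sc, lab, 0.85)
  sets <- attr(row, "index_sets")
  expect_length(intersect(sets$trusted_results, sets$unreliable_results), 0L)
  expect_setequal(c(sets$trusted_results, sets$unreliable_results), 1:3)
  expect_true(all(sets$trusted_failures %in% sets$trusted_results))
  expect_true(all(sets$unreliable_failures %in% sets$unreliable_results))
  expect_equal(row$trusted_results, 2L)   # >= is trusted, < is unreliable
})

test_that("the Pareto front agrees with an exhaustive dominance check", {
  single <- structure(list(table = confidence_partition(
    make_scores(0.9, 1L), label_vector("s0001", 1L, K = 4L), 0.5),
    n = 1L), class = "confidence_report")
  expect_equal(nrow(pareto_front(single)), 1L)

  two <- structure(list(table = data.frame(
    threshold = c(0.5, 0.6),
    trusted_results = c(80L, 70L), trusted_failures = c(1L, 2L),
    unreliable_results = c(20L, 30L), unreliable_failures = c(5L, 4L),
    trusted_correct = c(79L, 68L),
    trusted_results_pct = c(80, 70), trusted_failures_pct = c(1, 2),
    unreliable_results_pct = c(20, 30), unreliable_failures_pct = c(5, 4),
    trusted_correct_pct = c(79, 68)), n = 100L),
    class = "confidence_report")
  front2 <- pareto_front(two)
  expect_equal(nrow(front2), 1L)
  expect_equal(front2$percent_trusted, 80)

  for (seed in 1:10) {
    set.seed(seed)
    n <- 150
    sc <- make_scores(p_max = runif(n, 0.25, 1),
                      dc = sample(0:3, n, replace = TRUE))
    lab <- label_vector(sc$sample_ids,
                        ifelse(runif(n) < 0.8, sc$dc,
                               sample(0:3, n, replace = TRUE)), K = 4L)
    front <- pareto_front(confidence_sweep(sc, lab))
    # O(n^2) oracle: no kept point dominated, every dropped point dominated
    pts <- unique(data.frame(
      t = confidence_sweep(sc, lab)$table$trusted_results_pct,
      w = confidence_sweep(sc, lab)$table$trusted_failures_pct))
    dominated <- function(i, df) any(df$t >= df$t[i] & df$w <= df$w[i] &
                                       (df$t > df$t[i] | df$w < df$w[i]))
    keep_oracle <- pts[!vapply(seq_len(nrow(pts)), dominated, logical(1), df = pts), ]
    keep_oracle <- keep_oracle[order(keep_oracle$t, keep_oracle$w), ]
    expect_equal(front$percent_trusted, keep_oracle$t)
    expect_equal(front$percent_trusted_wrong, keep_oracle$w)
    expect_true(all(diff(front$percent_trusted) > 0))
  }
})
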