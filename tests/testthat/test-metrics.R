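test_that("a perfect prediction gives a diagonal confusion matrix and 100s", {
  truth <- label_vector(sprintf("s%d", 1:12), rep(0:3, 3), K = 4L)
  rep_ <- classification_report(truth, truth)
  expect_equal(sum(rep_$counts), 12L)
  expect_equal(diag(rep_$counts), setNames(rep(3L, 4), paste0(0:3)),
               ignore_attr = TRUE)
  expect_equal(rep_$accuracy, 100)
  expect_true(all(rep_$classwise$precision == 100))
  expect_true(all(rep_$classwise$balanced_accuracy == 100))
})

test_that("per-class statistics match hand arithmetic on printed formulas", {
  # 2-class: for class 1, TP=3, FP=1, FN=1, TN=5
  pred <- c(rep(1L, 3), 1L, 0L, rep(0L, 5))
  true <- c(rep(1L, 3), 0L, 1L, rep(0L, 5))
  ids <- sprintf("s%d", seq_along(pred))
  rep_ <- classification_report(label_vector(ids, pred, K = 2L),
                                label_vector(ids, true, K = 2L))
  cw1 <- rep_$classwise[rep_$classwise$class == 1L, ]
  expect_equal(cw1$precision, 75)
  expect_equal(cw1$recall, 75)
  expect_equal(percent_round(cw1$specificity), 83.33)
  expect_equal(cw1$f1, 75)
  # K=2: the two balanced accuracies coincide
  expect_equal(rep_$classwise$balanced_accuracy[1],
               rep_$classwise$balanced_accuracy[2])
  # column sums recover the true class counts
  expect_equal(colSums(rep_$counts), setNames(c(6L, 4L), c("0", "1")),
               ignore_attr = TRUE)
})

test_that("classes absent from the truth yield NA recall with a warning", {
  ids <- sprintf("s%d", 1:6)
  pred <- label_vector(ids, c(0L, 0L, 1L, 1L, 2L, 2L), K = 3L)
  true <- label_vector(ids, c(0L, 0L, 1L, 1L, 1L, 0L), K = 3L)
  expect_warning(rep_ <- classification_report(pred, true), "recall undefined")
  expect_true(is.na(rep_$classwise$recall[3]))
})

test_that("presentation rounding is half-up and reproduces printed percents", {
  expect_equal(percent_round(100 * 3107 / 4760), 65.27)
  expect_equal(percent_round(0.125, 2), 0.13)   # half-up, not half-even
  expect_equal(percent_round(2.675, 2), 2.68)
})

test_that("Cohen's kappa matches its definition and an independent library", {
  expect_equal(cohen_kappa(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L)), 1)
  expect_equal(cohen_kappa(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L)), -1)
  for (seed in 1:5) {
    set.seed(seed)
    a <- sample(0:3, 200, replace = TRUE)
    b <- sample(0:3, 200, replace = TRUE)
    ours <- cohen_kappa(a, b, K = 4L)
    ref <- e1071::classAgreement(table(a, b))$kappa
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_warning(k <- cohen_kappa(rep(0L, 5), rep(0L, 5), K = 2L), "degenerate")
  expect_true(is.na(k))
})

test_that("agreement matrices are symmetric with unit diagonal", {
  base <- random_panel(M = 1, n = 40, K = 4, seed = 11)
  dup <- panel_from_mats(list(matrix(base$p[1, , ], ncol = 4),
                              matrix(base$p[1, , ], ncol = 4),
                              matrix(random_panel(1, 40, 4, 12)$p[1, , ],
                                     ncol = 4)))
  ag <- agreement(dup)
  expect_equal(ag$pearson[1, 2], 1)
  expect_equal(ag$kappa[1, 2], 1)
  expect_equal(ag$pearson, t(ag$pearson))
  expect_equal(ag$kappa, t(ag$kappa))
  expect_equal(diag(ag$pearson), rep(1, 3), ignore_attr = TRUE)

  flat <- array(0.25, dim = c(2, 10, 4))
  const <- probability_panel(flat, c("c1", "c2"), sprintf("s%d", 1:10))
  # uniform rows: Pearson loses variance and the kappa marginals degenerate
  ws <- capture_warnings(ag2 <- agreement(const))
  expect_true(any(grepl("zero-variance", ws)))
  expect_true(is.na(ag2$pearson[1, 2]))
})

test_that("patient-level recognition averages per-patient fractions", {
  ids <- c("i1", "i2", "i3")
  pred <- label_vector(ids, c(0L, 1L, 0L), K = 4L)
  true <- label_vector(ids, c(0L, 1L, 1L), K = 4L)
  # patient A: 2/2 correct; patient B: 0/1
  pm <- patient_map(ids, c("A", "A", "B"))
  expect_equal(patient_level_recognition(pred, true, pm), 50)

  # one image per patient reduces to image-level accuracy
  pm1 <- patient_map(ids, c("p1", "p2", "p3"))
  expect_equal(patient_level_recognition(pred, true, pm1),
               100 * mean(pred$grades == true$grades))

  # equal-sized patients: patient-level equals image-level exactly
  set.seed(3)
  n <- 300
  ids2 <- sprintf("s%d", 1:n)
  predg <- sample(0:3, n, replace = TRUE)
  trueg <- sample(0:3, n, replace = TRUE)
  pm2 <- patient_map(ids2, rep(sprintf("p%d", 1:(n / 3)), each = 3))
  expect_equal(patient_level_recognition(label_vector(ids2, predg, K = 4L),
                                         label_vector(ids2, trueg, K = 4L),
                                         pm2),
               100 * mean(predg == trueg))

  pm_bad <- patient_map(c("i1", "i2"), c("A", "A"))
  expect_error(patient_level_recognition(pred, true, pm_bad), "unmapped")
})
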