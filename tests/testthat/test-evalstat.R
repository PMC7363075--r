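# Score aggregation, ROC/AUC, bootstrap CI, stratification, confusion

test_that("lesion and subject scores follow the aggregation rules", {
  expect_identical(lesion_score(c(0.2, 0.4, 0.6)), 0.4)
  expect_identical(lesion_score(rep(1, 70)), 1)
  expect_error(lesion_score(numeric(0)), "no patch")
  expect_identical(subject_score(c(0.1, 0.9)), 0.9)
  expect_identical(subject_score(numeric(0)), 0)
  # permutation invariant, monotone under added lesions
  set.seed(51)
  ls <- runif(6)
  expect_identical(subject_score(ls), subject_score(rev(ls)))
  expect_gte(subject_score(c(ls, 0.5)), subject_score(ls))
})

test_that("AUC equals the pairwise-comparison oracle", {
  expect_identical(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_identical(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(52)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force ties sometimes
    oracle <- {
      pos <- scores[labels == 1]; neg <- scores[labels == 0]
      cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      mean(cmp)
    }
    expect_equal(roc_auc(scores, labels)$auc, oracle, tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(3 * scores), labels)$auc, oracle,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (i in 1:10) {
    labels <- c(0, 1, rbinom(28, 1, 0.4))
    scores <- runif(30)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
  }
})

test_that("ROC points are valid curve coordinates", {
  set.seed(54)
  ev <- roc_auc(runif(40), rbinom(40, 1, 0.5))
  expect_true(all(diff(ev$roc$fpr) >= 0))
  expect_true(all(diff(ev$roc$tpr) >= 0))
  expect_identical(ev$roc$fpr[1], 0)
  expect_identical(tail(ev$roc$tpr, 1), 1)
})

test_that("the bootstrap CI follows the nearest-rank percentile rule", {
  # perfectly separated scores: every resample has AUC 1
  ci <- bootstrap_auc_ci(c(1, 1, 0, 0), c(1, 1, 0, 0), reps = 50, m = 10,
                         seed = 1)
  expect_identical(as.vector(ci), c(1, 1))
  set.seed(55)
  scores <- runif(60); labels <- rbinom(60, 1, 0.5)
  ci2 <- bootstrap_auc_ci(scores, labels, reps = 200, m = 40, seed = 9)
  # endpoints recomputed independently from the bootstrap distribution
  aucs <- sort(attr(ci2, "aucs"))
  expect_identical(ci2[["low"]], aucs[ceiling(0.025 * 200)])
  expect_identical(ci2[["high"]], aucs[ceiling(0.975 * 200)])
  expect_lte(ci2[["low"]], ci2[["high"]])
  expect_true(all(ci2 >= 0 & ci2 <= 1))
  # seeded repeatability
  expect_identical(ci2, bootstrap_auc_ci(scores, labels, reps = 200, m = 40,
                                         seed = 9))
  # wider resamples concentrate the interval (in expectation)
  ci_small <- bootstrap_auc_ci(scores, labels, reps = 200, m = 15, seed = 2)
  ci_big <- bootstrap_auc_ci(scores, labels, reps = 200, m = 55, seed = 2)
  expect_lt(diff(ci_big), diff(ci_small))
  expect_error(bootstrap_auc_ci(1:4, c(1, 1, 1, 1), seed = 1),
               "both classes")
})

test_that("stratified selection balances classes within every stratum", {
  rec <- data.frame(
    subject_id = sprintf("s%02d", 1:24),
    label = c(rep(1, 10), rep(0, 4), rep(1, 2), rep(0, 6), rep(0, 2)),
    scanner_model = c(rep("A", 14), rep("B", 8), rep("C", 2)),
    age = c(rep(45, 14), rep(72, 8), rep(85, 2)))
  out <- stratify_test_set(rec, "scanner", seed = 1)
  tab <- table(out$scanner_model, out$label)
  expect_identical(unname(tab["A", "0"]), 4L)  # min(10, 4)
  expect_identical(unname(tab["A", "1"]), 4L)
  expect_identical(unname(tab["B", "0"]), 2L)
  expect_identical(unname(tab["B", "1"]), 2L)
  expect_false("C" %in% rownames(tab))         # stratum missing a class
  # age-decade stratification adds the decade column and balances it
  out2 <- stratify_test_set(rec, "age_decade", seed = 1)
  for (d in unique(out2$age_decade)) {
    sub <- out2[out2$age_decade == d, ]
    expect_identical(sum(sub$label == 1), sum(sub$label == 0))
  }
  only_h <- rec[rec$label == 0, ]
  expect_error(stratify_test_set(only_h, "scanner", seed = 1), "degenerate")
})

test_that("confusion counts partition the test set at the threshold", {
  cm <- confusion_at_threshold(c(0.9, 0.1), c(1, 0), t = 0.3)
  expect_identical(cm, c(TP = 1L, FP = 0L, FN = 0L, TN = 1L))
  cm2 <- confusion_at_threshold(c(0.1, 0.2), c(1, 0), t = 0.3)
  expect_identical(cm2[["TP"]] + cm2[["FP"]], 0L)
  set.seed(56)
  sc <- runif(25); lb <- rbinom(25, 1, 0.5)
  expect_identical(sum(confusion_at_threshold(sc, lb, 0.42)), 25L)
  # threshold comparison is >=
  expect_identical(confusion_at_threshold(0.3, 1, t = 0.3)[["TP"]], 1L)
})

test_that("deposited-datapoint recomputation reads a scores CSV", {
  tf <- tempfile(fileext = ".csv")
  d <- data.frame(
    score = c(0.9, 0.2, 0.8, 0.1, 0.6, 0.35, NA, NA),
    label = c(1, 0, 1, 0, 1, 0, NA, NA),
    test_set = c(rep("unstratified", 4), "scanner", "scanner", NA, NA),
    dice = c(NA, NA, NA, NA, NA, NA, 0.5, 0.3),
    masking = c(NA, NA, NA, NA, NA, NA, "enabled", "disabled"))
  write.csv(d, tf, row.names = FALSE)
  st <- deposited_datapoint_stats(tf)
  expect_identical(as.integer(st$sizes[c("unstratified", "scanner")]),
                   c(4L, 2L))
  expect_identical(unname(st$confusion), c(2L, 0L, 0L, 2L))
  expect_identical(unname(st$aucs[["unstratified"]]), 1)
  expect_identical(unname(st$mean_dice[["enabled"]]), 0.5)
  unlink(tf)
  expect_error(deposited_datapoint_stats(tf), "not found")
})
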