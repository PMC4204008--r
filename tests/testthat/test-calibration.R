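test_that("ROC sweep handles separable, mixed and degenerate inputs", {
  # perfect separation
  roc <- roc_curve(c(1, 2, 3, 10, 11), c(F, F, F, T, T))
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$optimal_distance, 0)
  expect_equal(roc$optimal_threshold, 10)

  # hand-counted concordance: REM {3,5} vs non-REM {1,4} -> 3/4
  roc <- roc_curve(c(3, 5, 1, 4), c(T, T, F, F))
  expect_equal(roc$auc, 0.75)

  # all values identical: chance
  roc <- roc_curve(rep(2, 10), rep(c(T, F), 5))
  expect_equal(roc$auc, 0.5)

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals brute-force pairwise concordance", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    values <- sample(round(runif(n, 0, 5), 1))  # ties likely
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    expect_equal(roc_curve(values, labels)$auc, auc_oracle(values, labels))
  }
})

test_that("AUC matches pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(37)
  values <- rnorm(60)
  labels <- c(rep(TRUE, 20), rep(FALSE, 40))
  values[labels] <- values[labels] + 1
  ours <- roc_curve(values, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, values, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(roc_curve(exp(values), labels)$auc, ours)
  expect_equal(roc_curve(2 * values + 7, labels)$auc, ours)
})

test_that("the operating point minimizes distance to (0,1)", {
  roc <- structure(list(points = data.frame(
    threshold = c(1, 2), fpr = c(0.1, 0.3), tpr = c(0.8, 0.95))),
    class = "roc_result")
  opt <- optimal_operating_point(roc)
  expect_equal(opt$threshold, 1)   # 0.2236 beats 0.3041
  expect_equal(opt$distance, sqrt(0.1^2 + 0.2^2))

  one <- structure(list(points = data.frame(threshold = 5, fpr = 0.2,
                                            tpr = 0.9)),
                   class = "roc_result")
  expect_equal(optimal_operating_point(one)$threshold, 5)
})

test_that("threshold calibration separates a toy two-epoch set", {
  fx <- data.frame(epoch = 1:8,
                   sefd = c(5, 3, 5.2, 2.8, 5.1, 3.1, 4.9, 3.2),
                   ap = rnorm(8, 15), rp = rnorm(8, -9), valid = TRUE,
                   stage = rep(c("REM", "N2"), 4))
  th <- calibrate_thresholds(fx)
  expect_gt(th$sefd_th, 3.2)
  expect_lte(th$sefd_th, 5)

  fx$stage <- "N2"
  expect_error(calibrate_thresholds(fx), "both REM and non-REM")
})

test_that("calibration recovers the designed synthetic SEFd boundary", {
  fx <- synth_features(305)
  th <- calibrate_thresholds(fx)
  expect_gt(th$sefd_th, 4.25)
  expect_lt(th$sefd_th, 4.75)
  roc <- attr(th, "stage1_roc")
  expect_s3_class(roc, "roc_result")
  expect_gt(roc$auc, 0.95)
})

test_that("per-recording calibration summarizes the threshold spread", {
  sets <- list(a = synth_features(411, n_epochs = 60),
               b = synth_features(412, n_epochs = 60))
  ps <- calibrate_per_recording(sets)
  expect_equal(ps$per_recording$recording, c("a", "b"))
  expect_true(all(ps$per_recording$sefd_th > 0))
  expect_equal(ps$summary["sefd_th", "mean"],
               mean(ps$per_recording$sefd_th))
  expect_true(all(c("mean", "median", "sd") %in% colnames(ps$summary)))
})

test_that("cross-validation partitions subjects and is reproducible", {
  sets <- lapply(1:6, function(s) synth_features(400 + s, n_epochs = 60))
  names(sets) <- sprintf("s%02d", 1:6)

  cv1 <- crossvalidate(sets, k = 3, seed = 9)
  cv2 <- crossvalidate(sets, k = 3, seed = 9)

  # every subject in exactly one test fold
  tested <- unlist(lapply(cv1$folds, `[[`, "test_subjects"))
  expect_setequal(tested, names(sets))
  expect_length(tested, 6)

  expect_equal(cv1$assignments, cv2$assignments)
  expect_equal(cv1$mean_metrics, cv2$mean_metrics)

  # reported mean equals the arithmetic mean of the fold metrics
  per_fold <- do.call(rbind, lapply(cv1$folds, `[[`, "metrics"))
  expect_equal(cv1$mean_metrics, colMeans(per_fold, na.rm = TRUE),
               tolerance = 1e-12)

  expect_error(crossvalidate(sets, k = 1), "k")
  expect_error(crossvalidate(sets, k = 7), "k")
})
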