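test_that("confusion counts follow the REM-positive convention", {
  pred <- c("REM", "REM", "NONREM", "NONREM", "NONREM")
  ref <- c("REM", "REM", "NONREM", "NONREM", "NONREM")
  cc <- confusion(pred, ref)
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(2, 0, 3, 0))

  cc <- confusion(rep("REM", 4), rep("NONREM", 4))
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(0, 4, 0, 0))

  cc <- confusion(character(0), character(0))
  expect_equal(cc$n, 0)

  # NA reference epochs are excluded
  cc <- confusion(c("REM", "REM"), c("REM", NA))
  expect_equal(c(cc$tp, cc$n), c(1, 1))

  expect_error(confusion("REM", c("REM", "REM")), "length")
})

test_that("metric percentages reproduce per-subject report arithmetic", {
  # a test subject with 186 of 187 REM epochs detected
  expect_equal(round(rem_metrics(tp = 186, fn = 1)["sensitivity"], 2),
               c(sensitivity = 99.47))
  # a training subject with 103 true detections out of 158
  expect_equal(round(rem_metrics(tp = 103, fp = 55)["selectivity"], 2),
               c(selectivity = 65.19))

  m <- rem_metrics(tp = 1, tn = 1)
  expect_equal(unname(m), c(100, 100, 100, 100))

  # zero denominators give NA, never 0
  m <- rem_metrics(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(m["sensitivity"]))
  expect_true(is.na(m["selectivity"]))
  expect_equal(unname(m["specificity"]), 100)
})

test_that("Cohen's kappa matches hand arithmetic and e1071", {
  ref <- c(rep("REM", 50), rep("NONREM", 50))
  expect_equal(cohens_kappa(ref, ref), 1.0)

  # agreement exactly at chance: a=b=c=d=25
  pred <- c(rep(c("REM", "NONREM"), 25), rep(c("REM", "NONREM"), 25))
  ref2 <- c(rep("REM", 50), rep("NONREM", 50))
  expect_equal(cohens_kappa(pred, ref2), 0.0)

  # a=40, b=10, c=20, d=30: po=0.7, pe=0.5, kappa=0.4
  pred3 <- c(rep("REM", 40), rep("NONREM", 10), rep("REM", 20),
             rep("NONREM", 30))
  ref3 <- c(rep("REM", 50), rep("NONREM", 50))
  expect_equal(cohens_kappa(pred3, ref3), 0.4)

  skip_if_not_installed("e1071")
  tab <- table(pred3, ref3)
  expect_equal(cohens_kappa(pred3, ref3),
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)

  # constant raters: undefined
  expect_true(is.na(cohens_kappa(rep("REM", 5), rep("REM", 5))))
})

test_that("kappa is invariant under consistent label swapping", {
  set.seed(41)
  for (i in 1:10) {
    pred <- sample(c("REM", "NONREM"), 40, replace = TRUE)
    ref <- sample(c("REM", "NONREM"), 40, replace = TRUE)
    swap <- function(x) ifelse(x == "REM", "NONREM", "REM")
    expect_equal(cohens_kappa(pred, ref),
                 cohens_kappa(swap(pred), swap(ref)), tolerance = 1e-12)
  }
})

test_that("per-stage false positives decompose the total FP exactly", {
  pred <- c("REM", "NONREM")
  stages <- c("W", "N2")
  bd <- stage_fp_breakdown(pred, stages)
  expect_equal(bd$fp[bd$stage == "W"], 1)
  expect_equal(bd$total[bd$stage == "W"], 1)
  expect_equal(bd$fp[bd$stage == "N2"], 0)
  expect_equal(sum(bd$fp), 1)

  set.seed(43)
  for (i in 1:10) {
    n <- 200
    stages <- sample(stage_levels(), n, replace = TRUE)
    pred <- sample(c("REM", "NONREM"), n, replace = TRUE)
    bd <- stage_fp_breakdown(pred, stages)
    cc <- confusion(pred, reference_binary(stages))
    expect_equal(sum(bd$fp), cc$fp)
  }
})

test_that("movement and unscored epochs follow the evaluation policy", {
  stages <- c("REM", "MOVEMENT", "UNSCORED", "N2")
  ref <- reference_binary(stages)
  expect_equal(ref, c("REM", "NONREM", NA, "NONREM"))
  ref2 <- reference_binary(stages, movement_as_wake = FALSE)
  expect_true(is.na(ref2[2]))
  ref3 <- reference_binary(stages, exclude_unscored = FALSE)
  expect_equal(ref3[3], "NONREM")

  # movement epochs count under Wake in the breakdown
  bd <- stage_fp_breakdown(c("NONREM", "REM", "NONREM", "NONREM"), stages)
  expect_equal(bd$fp[bd$stage == "W"], 1)
})

test_that("the Wald interval brackets a detection rate", {
  ci <- proportion_ci(50, 100)
  expect_equal(unname(ci["lower"]), 50 - 1.959964 * 5, tolerance = 1e-4)
  expect_lt(ci["lower"], 50)
  expect_gt(ci["upper"], 50)
  expect_error(proportion_ci(120, 10))
})
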