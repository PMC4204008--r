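# Scoring of predicted REM/non-REM sequences against reference
# hypnograms: confusion counts, the four headline percentages,
# Cohen's kappa, and the per-stage false-positive breakdown.

#' Reduce reference stages to the binary REM task
#'
#' Maps a full stage sequence to `"REM"`/`"NONREM"`, applying the
#' evaluation policy for the two special markers: `MOVEMENT` epochs are
#' treated as Wake (hence non-REM) by default, mirroring AASM practice;
#' `UNSCORED` epochs are excluded (`NA`) by default.
#'
#' @param stages Character vector of canonical stage labels.
#' @param exclude_unscored Drop `UNSCORED` epochs from evaluation
#'   (`NA` in the output)? Default `TRUE`.
#' @param movement_as_wake Treat `MOVEMENT` as Wake (non-REM)? If
#'   `FALSE`, movement epochs are excluded too. Default `TRUE`.
#' @return Character vector of `"REM"`, `"NONREM"` or `NA`.
#' @export
reference_binary <- function(stages, exclude_unscored = TRUE,
                             movement_as_wake = TRUE) {
  out <- ifelse(stages == "REM", "REM", "NONREM")
  if (exclude_unscored) out[stages == "UNSCORED"] <- NA_character_
  if (!movement_as_wake) out[stages == "MOVEMENT"] <- NA_character_
  out
}

#' Confusion counts for REM detection
#'
#' REM is the positive class. Positions where the reference is `NA`
#' (excluded epochs) are dropped from both sequences.
#'
#' @param predictions Character vector of `"REM"`/`"NONREM"`.
#' @param reference Character vector of the same length, `NA` allowed
#'   for excluded epochs.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `tn`,
#'   `fn` and `n` (evaluated epochs).
#' @export
confusion <- function(predictions, reference) {
  if (length(predictions) != length(reference)) {
    stop("predictions and reference must have equal length", call. = FALSE)
  }
  keep <- !is.na(reference)
  p <- predictions[keep] == "REM"
  r <- reference[keep] == "REM"
  out <- list(tp = sum(p & r), fp = sum(p & !r),
              tn = sum(!p & !r), fn = sum(!p & r), n = sum(keep))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  invisible(x)
}

#' Detection metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, selectivity
#' (positive predictive value) `TP/(TP+FP)` and accuracy
#' `(TP+TN)/N`, all as percentages. A metric whose denominator is zero
#' is reported as `NA` rather than 0, so averages over recordings are
#' not silently deflated.
#'
#' @param cc A `confusion_counts` object, or the counts given directly.
#' @param tp,fp,tn,fn Counts, used when `cc` is missing.
#' @return Named numeric vector `sensitivity`, `specificity`,
#'   `selectivity`, `accuracy` in percent.
#' @export
rem_metrics <- function(cc = NULL, tp = 0, fp = 0, tn = 0, fn = 0) {
  if (!is.null(cc)) {
    stopifnot(inherits(cc, "confusion_counts"))
    tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    selectivity = pct(tp, tp + fp),
    accuracy = pct(tp + tn, tp + fp + tn + fn))
}

#' Cohen's kappa for binary REM scoring
#'
#' Chance-corrected agreement between the automatic and the reference
#' scoring of the binary REM/non-REM task:
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e`
#' from the marginal label frequencies.
#'
#' @inheritParams confusion
#' @return Kappa in `[-1, 1]`, or `NA` when both raters are constant
#'   (`p_e = 1`, agreement by chance alone is total).
#' @export
cohens_kappa <- function(predictions, reference) {
  cc <- confusion(predictions, reference)
  n <- cc$n
  if (n == 0) stop("no evaluated epochs", call. = FALSE)
  po <- (cc$tp + cc$tn) / n
  pe <- ((cc$tp + cc$fp) / n) * ((cc$tp + cc$fn) / n) +
    ((cc$tn + cc$fn) / n) * ((cc$tn + cc$fp) / n)
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Per-stage false-positive breakdown
#'
#' For each non-REM stage (W, N1, N2, N3), the number of reference
#' epochs of that stage falsely scored REM, together with the stage's
#' total epoch count. The per-stage false positives always sum to the
#' total FP count of the binary confusion.
#'
#' @param predictions Character vector of `"REM"`/`"NONREM"`.
#' @param stages Full reference stage labels (same length).
#' @param exclude_unscored,movement_as_wake Evaluation policy, see
#'   [reference_binary()].
#' @return Data.frame with columns `stage`, `fp`, `total` and
#'   `fraction` (percent of the stage misclassified as REM).
#' @export
stage_fp_breakdown <- function(predictions, stages,
                               exclude_unscored = TRUE,
                               movement_as_wake = TRUE) {
  if (length(predictions) != length(stages)) {
    stop("predictions and stages must have equal length", call. = FALSE)
  }
  ref <- reference_binary(stages, exclude_unscored, movement_as_wake)
  keep <- !is.na(ref)
  eff_stage <- stages[keep]
  eff_stage[eff_stage == "MOVEMENT"] <- "W"
  pred <- predictions[keep]
  lv <- c("W", "N1", "N2", "N3")
  rows <- lapply(lv, function(s) {
    tot <- sum(eff_stage == s)
    fp <- sum(eff_stage == s & pred == "REM")
    data.frame(stage = s, fp = fp, total = tot,
               fraction = if (tot > 0) 100 * fp / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wald confidence interval for a detection-rate percentage
#'
#' Normal-approximation (Wald) binomial interval
#' `p +/- z * sqrt(p (1 - p) / n)` for a rate reported in percent,
#' e.g. the confidence range of an average sensitivity over all
#' positive epochs.
#'
#' @param pct Rate in percent.
#' @param n Number of trials (epochs) behind the rate.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `lower`, `upper` in percent.
#' @export
proportion_ci <- function(pct, n, conf = 0.95) {
  stopifnot(pct >= 0, pct <= 100, n > 0)
  p <- pct / 100
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(lower = 100 * (p - z * se), upper = 100 * (p + z * se))
}

#' Evaluate a detection result against a reference hypnogram
#'
#' Convenience wrapper combining [confusion()], [rem_metrics()],
#' [cohens_kappa()] and [stage_fp_breakdown()].
#'
#' @param result A `detection_result` from [detect_recording()], or a
#'   character vector of predictions.
#' @param hyp A [hypnogram()] or a character vector of stage labels.
#' @inheritParams reference_binary
#' @return List with `confusion`, `metrics`, `kappa` and `breakdown`.
#' @export
evaluate_detection <- function(result, hyp, exclude_unscored = TRUE,
                               movement_as_wake = TRUE) {
  pred <- if (is.data.frame(result)) result$predicted else result
  stages <- if (inherits(hyp, "hypnogram")) hyp$stages else hyp
  ref <- reference_binary(stages, exclude_unscored, movement_as_wake)
  cc <- confusion(pred, ref)
  list(confusion = cc,
       metrics = rem_metrics(cc),
       kappa = cohens_kappa(pred, ref),
       breakdown = stage_fp_breakdown(pred, stages, exclude_unscored,
                                      movement_as_wake))
}
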