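# Threshold calibration from labelled data. Stage 1: ROC sweep over the
# observed SEFd values with the operating point closest to the (0,1)
# corner. Stage 2: quantile grid search over (ap_max, rp_min, rp_max)
# restricted to stage-1 candidates, scored by the same distance
# objective over all epochs. Plus subject-wise k-fold cross-validation.

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the sorted unique feature values
#' (decision rule: value `>= threshold` is positive), plus an anchor
#' above the maximum where nothing is positive. AUC is computed by
#' trapezoidal integration and equals the probability that a random
#' positive outranks a random negative (ties counted half).
#'
#' @param values Numeric per-epoch feature values.
#' @param labels Logical or character: `TRUE`/`"REM"` marks the
#'   positive class.
#' @return Object of class `roc_result`: list with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`, sorted by threshold), `auc`,
#'   `optimal_threshold` and `optimal_distance`.
#' @export
roc_curve <- function(values, labels) {
  if (is.character(labels)) labels <- labels == "REM"
  stopifnot(is.logical(labels), length(values) == length(labels))
  keep <- !is.na(values)
  values <- values[keep]; labels <- labels[keep]
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  th <- sort(unique(values))
  th <- c(th, max(th) + 1)     # anchor: no epoch positive
  tpr <- vapply(th, function(t) sum(values >= t & labels) / npos, numeric(1))
  fpr <- vapply(th, function(t) sum(values >= t & !labels) / nneg, numeric(1))
  points <- data.frame(threshold = th, fpr = fpr, tpr = tpr)
  # trapezoid over the curve traced from (0,0) (high threshold) to (1,1)
  ord <- order(points$fpr, points$tpr)
  xs <- points$fpr[ord]; ys <- points$tpr[ord]
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  res <- structure(list(points = points, auc = auc), class = "roc_result")
  opt <- optimal_operating_point(res)
  res$optimal_threshold <- opt$threshold
  res$optimal_distance <- opt$distance
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d points, AUC %.4f, optimal threshold %.4g (d = %.4f)\n",
              nrow(x$points), x$auc, x$optimal_threshold, x$optimal_distance))
  invisible(x)
}

#' Optimal ROC operating point
#'
#' The threshold of the curve point closest (Euclidean distance in ROC
#' space) to the perfect-classification corner (0, 1), weighting
#' sensitivity and specificity equally. Distance ties are broken
#' toward higher specificity (lower false-positive rate), then toward
#' the lower threshold.
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @return List with `threshold`, `distance`, `tpr` and `fpr` of the
#'   selected point.
#' @export
optimal_operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  p <- roc$points
  if (nrow(p) == 0) stop("empty ROC curve", call. = FALSE)
  d <- sqrt(p$fpr^2 + (1 - p$tpr)^2)
  ord <- order(d, p$fpr, p$threshold)
  i <- ord[1]
  list(threshold = p$threshold[i], distance = d[i],
       tpr = p$tpr[i], fpr = p$fpr[i])
}

#' Calibrate the two-stage classifier thresholds
#'
#' Stage 1: `sefd_th` is the optimal operating point of the ROC curve
#' of the smoothed SEFd values against the binary REM labels. Stage 2:
#' among the stage-1 candidate epochs, `ap_max` is searched over
#' quantiles of the candidates' AP values and `(rp_min, rp_max)` over
#' quantile pairs of their RP values, each grid extended by the option
#' of leaving the bound inactive (`Inf`/`-Inf`); the triple minimizing
#' the distance to (0,1) of the resulting sensitivity/specificity over
#' all epochs is selected. Ties are broken toward higher specificity,
#' then the wider acceptance region, so a stage-2 bound is only placed
#' where it removes false positives on the training data.
#'
#' @param features An `epoch_features` data.frame with a `stage` column
#'   (or explicit `labels`).
#' @param labels Optional logical/character REM labels overriding
#'   `features$stage`.
#' @param grid_points Number of quantile grid points per stage-2
#'   parameter (default 41).
#' @return A [rem_thresholds()] with attribute `"stage1_roc"` (the
#'   SEFd `roc_result`).
#' @export
calibrate_thresholds <- function(features, labels = NULL, grid_points = 41) {
  stopifnot(is.data.frame(features))
  if (is.null(labels)) labels <- features$stage == "REM"
  if (is.character(labels)) labels <- labels == "REM"
  ok <- features$valid & !is.na(features$sefd) & !is.na(labels)
  if (length(unique(labels[ok])) < 2) {
    stop("calibration needs both REM and non-REM epochs", call. = FALSE)
  }
  roc1 <- roc_curve(features$sefd[ok], labels[ok])
  sefd_th <- roc1$optimal_threshold

  cand <- ok & features$sefd >= sefd_th
  if (sum(cand) < 2 || all(is.na(features$ap[cand]))) {
    stop("degenerate stage-1 candidate set; inspect the SEFd ROC curve",
         call. = FALSE)
  }
  probs <- seq(0, 1, length.out = grid_points)
  # candidate-value quantiles, plus the option of leaving a bound
  # inactive: a bound placed at the exact observed extremum would clip
  # unseen recordings for no training gain
  ap_grid <- c(sort(unique(stats::quantile(features$ap[cand], probs,
                                           na.rm = TRUE, names = FALSE))),
               Inf)
  rp_grid <- c(-Inf,
               sort(unique(stats::quantile(features$rp[cand], probs,
                                           na.rm = TRUE, names = FALSE))),
               Inf)
  npos <- sum(labels[ok]); nneg <- sum(!labels[ok])
  cpos <- labels[cand]
  cap <- features$ap[cand]; crp <- features$rp[cand]

  best <- NULL
  for (ap_max in ap_grid) {
    ap_ok <- !is.na(cap) & cap <= ap_max
    for (i in seq_along(rp_grid)) {
      rp_min <- rp_grid[i]
      if (i == length(rp_grid)) break
      rp_lo_ok <- !is.na(crp) & crp >= rp_min
      for (j in (i + 1):length(rp_grid)) {
        rp_max <- rp_grid[j]
        sel <- ap_ok & rp_lo_ok & crp <= rp_max
        tp <- sum(sel & cpos); fp <- sum(sel & !cpos)
        sens <- tp / npos
        fpr <- fp / nneg
        d <- sqrt(fpr^2 + (1 - sens)^2)
        # ties: higher specificity, then the wider (less clipping-prone)
        # acceptance region, bound by bound
        key <- c(d, fpr, -ap_max, rp_min, -rp_max)
        if (is.null(best) || keys_less(key, best$key)) {
          best <- list(key = key, ap_max = ap_max, rp_min = rp_min,
                       rp_max = rp_max)
        }
      }
    }
  }
  th <- rem_thresholds(sefd_th = sefd_th, ap_max = best$ap_max,
                       rp_max = best$rp_max, rp_min = best$rp_min)
  attr(th, "stage1_roc") <- roc1
  th
}

keys_less <- function(a, b, tol = 1e-12) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - tol) return(TRUE)
    if (a[k] > b[k] + tol) return(FALSE)
  }
  FALSE
}

#' Per-recording ("patient-specific") threshold calibration
#'
#' Calibrates thresholds independently for each recording and
#' summarizes their spread. Not the default operating mode (a
#' zero-configuration device uses one fixed profile), but useful to
#' judge how much subject adaptation could help.
#'
#' @param feature_sets Named list of labelled `epoch_features`
#'   data.frames, one per recording.
#' @return List with `per_recording` (data.frame of the four
#'   thresholds per recording) and `summary` (mean, median and SD per
#'   threshold; infinite inactive bounds are excluded from the
#'   summaries).
#' @export
calibrate_per_recording <- function(feature_sets) {
  stopifnot(length(feature_sets) >= 1)
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- sprintf("subject%02d", seq_along(feature_sets))
  }
  rows <- lapply(names(feature_sets), function(nm) {
    th <- calibrate_thresholds(feature_sets[[nm]])
    data.frame(recording = nm, sefd_th = th$sefd_th, ap_max = th$ap_max,
               rp_max = th$rp_max, rp_min = th$rp_min,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  summarize <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) return(c(mean = NA_real_, median = NA_real_,
                                 sd = NA_real_))
    c(mean = mean(x), median = stats::median(x), sd = stats::sd(x))
  }
  list(per_recording = per,
       summary = t(vapply(per[c("sefd_th", "ap_max", "rp_max", "rp_min")],
                          summarize, numeric(3))))
}

#' Subject-wise k-fold cross-validation
#'
#' Partitions recordings (subjects) into `k` folds, calibrates
#' thresholds on the pooled epochs of the training folds and evaluates
#' on the held-out fold, so no subject contributes to both sides.
#'
#' @param feature_sets Named list of `epoch_features` data.frames, one
#'   per recording, each with stage labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List with `folds` (per-fold list: `test_subjects`,
#'   `thresholds`, `metrics`), `mean_metrics` (unweighted mean over
#'   folds) and `assignments` (subject to fold).
#' @export
crossvalidate <- function(feature_sets, k = 5, seed = 1) {
  n <- length(feature_sets)
  if (k < 2 || k > n) stop("need 2 <= k <= number of recordings",
                           call. = FALSE)
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- sprintf("subject%02d", seq_len(n))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assignment <- sample(rep(seq_len(k), length.out = n))
  names(assignment) <- names(feature_sets)
  folds <- lapply(seq_len(k), function(f) {
    test_idx <- which(assignment == f)
    train <- do.call(rbind, feature_sets[-test_idx])
    th <- calibrate_thresholds(train)
    pooled <- list(tp = 0, fp = 0, tn = 0, fn = 0, n = 0)
    per_rec <- lapply(feature_sets[test_idx], function(fx) {
      det <- detect_recording(fx, th)
      ref <- reference_binary(fx$stage)
      cc <- confusion(det$predicted, ref)
      pooled$tp <<- pooled$tp + cc$tp; pooled$fp <<- pooled$fp + cc$fp
      pooled$tn <<- pooled$tn + cc$tn; pooled$fn <<- pooled$fn + cc$fn
      rem_metrics(cc)
    })
    class(pooled) <- "confusion_counts"
    list(test_subjects = names(feature_sets)[test_idx],
         thresholds = th,
         metrics = rem_metrics(pooled),
         per_recording = per_rec)
  })
  mm <- colMeans(do.call(rbind, lapply(folds, `[[`, "metrics")), na.rm = TRUE)
  list(folds = folds, mean_metrics = mm, assignments = assignment)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
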