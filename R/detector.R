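# Two-stage fixed-threshold REM classifier. Stage 1 marks candidate
# REM epochs by SEFd; stage 2 confirms candidates by absolute and
# relative band power. Stage-2 features only matter for candidates,
# which is what keeps the method cheap on wearable hardware.

#' Classifier thresholds
#'
#' The four parameters of the two-stage classifier. Defaults are the
#' best-performing fixed operating point found on the training cohort:
#' SEFd threshold 4.54 Hz, maximum absolute power 15.5 dB, relative
#' power window -13.03 to -6.08 dB.
#'
#' @param sefd_th Stage-1 SEFd threshold (Hz); an epoch is a candidate
#'   REM epoch iff its smoothed SEFd is at least this.
#' @param ap_max Stage-2 maximum absolute band power (dB).
#' @param rp_max,rp_min Stage-2 relative band power window (dB),
#'   `rp_min < rp_max`.
#' @return An object of class `rem_thresholds`.
#' @export
rem_thresholds <- function(sefd_th = 4.54, ap_max = 15.5,
                           rp_max = -6.08, rp_min = -13.03) {
  if (!(rp_min < rp_max)) stop("rp_min must be below rp_max", call. = FALSE)
  if (sefd_th < 0) stop("sefd_th must be non-negative", call. = FALSE)
  structure(list(sefd_th = sefd_th, ap_max = ap_max,
                 rp_max = rp_max, rp_min = rp_min),
            class = "rem_thresholds")
}

#' @export
print.rem_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<rem_thresholds> SEFd >= %.3g Hz; AP <= %.4g dB; ",
                     "%.4g <= RP <= %.4g dB\n"),
              x$sefd_th, x$ap_max, x$rp_min, x$rp_max))
  invisible(x)
}

#' Classify a single epoch
#'
#' Stage 1: the epoch is a candidate REM epoch iff `sefd >= sefd_th`.
#' Stage 2: a candidate is scored REM iff additionally `ap <= ap_max`
#' and `rp_min <= rp <= rp_max`. All inequalities are inclusive.
#' Invalid feature rows short-circuit to non-REM.
#'
#' @param sefd,ap,rp Epoch feature values (smoothed SEFd in Hz, AP and
#'   RP in dB).
#' @param th A [rem_thresholds()].
#' @param valid Logical; `FALSE` forces non-REM with no candidate flag.
#' @return List with `label` (`"REM"` or `"NONREM"`) and `candidate`
#'   (logical).
#' @export
classify_epoch <- function(sefd, ap, rp, th = rem_thresholds(),
                           valid = TRUE) {
  stopifnot(inherits(th, "rem_thresholds"))
  if (!isTRUE(valid) || is.na(sefd)) {
    return(list(label = "NONREM", candidate = FALSE))
  }
  cand <- sefd >= th$sefd_th
  if (!cand) return(list(label = "NONREM", candidate = FALSE))
  rem <- !is.na(ap) && !is.na(rp) &&
    ap <= th$ap_max && rp >= th$rp_min && rp <= th$rp_max
  list(label = if (rem) "REM" else "NONREM", candidate = TRUE)
}

#' Detect REM epochs over a whole recording
#'
#' Vectorized application of [classify_epoch()] to a feature table.
#' Stage-2 conditions are only evaluated for stage-1 candidates.
#'
#' @param features An `epoch_features` data.frame from
#'   [extract_features()] (columns `sefd`, `ap`, `rp`, `valid`).
#' @param th A [rem_thresholds()].
#' @return A data.frame of class `detection_result` with columns
#'   `epoch`, `candidate` and `predicted` (`"REM"`/`"NONREM"`).
#' @export
detect_recording <- function(features, th = rem_thresholds()) {
  stopifnot(is.data.frame(features), inherits(th, "rem_thresholds"))
  n <- nrow(features)
  candidate <- rep(FALSE, n)
  predicted <- rep("NONREM", n)
  if (n > 0) {
    ok <- features$valid & !is.na(features$sefd)
    candidate <- ok & features$sefd >= th$sefd_th
    idx <- which(candidate)
    if (length(idx) > 0) {
      pass <- features$ap[idx] <= th$ap_max &
        features$rp[idx] >= th$rp_min &
        features$rp[idx] <= th$rp_max
      pass[is.na(pass)] <- FALSE
      predicted[idx[pass]] <- "REM"
    }
  }
  out <- data.frame(
    epoch = if (n > 0) features$epoch else integer(0),
    candidate = candidate,
    predicted = predicted,
    stringsAsFactors = FALSE
  )
  class(out) <- c("detection_result", "data.frame")
  out
}
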