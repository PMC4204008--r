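# End-to-end orchestration: EDF in, features/predictions/summary out.
# These functions are the surface the command-line script
# (inst/exec/remsefd) wraps.

features_from_edf <- function(edf_path, channel, config,
                              hypnogram_path = NULL) {
  rec <- read_edf_signal(edf_path, channel)
  hyp <- NULL
  if (!is.null(hypnogram_path)) {
    dialect <- if (grepl("\\.edf$", hypnogram_path, ignore.case = TRUE)) {
      "edfplus"
    } else "plain"
    hyp <- read_hypnogram(hypnogram_path, dialect = dialect,
                          stage_map = config$stage_map,
                          epoch_seconds = config$epoch_seconds)
  }
  grid <- preprocess(rec, hyp)
  extract_features(grid, band = config$band,
                   smooth_width = config$smooth_width)
}

#' Run REM detection on one EDF recording
#'
#' Reads the named channel, preprocesses, extracts features, applies
#' the two-stage classifier with the configured thresholds and writes
#' three artifacts next to `out_prefix`: `<prefix>_features.csv`,
#' `<prefix>_predictions.csv` and `<prefix>_summary.json` (the summary
#' carries epoch counts and, when a hypnogram is given, the evaluation
#' metrics).
#'
#' @param edf_path Path to the EDF recording.
#' @param channel EEG channel label.
#' @param out_prefix Output path prefix.
#' @param config A [run_config()].
#' @param hypnogram_path Optional reference hypnogram (plain text, or
#'   an EDF+ annotation file if the extension is `.edf`).
#' @return Invisibly, a list with `features`, `detection` and
#'   `summary`.
#' @export
run_detect <- function(edf_path, channel, out_prefix,
                       config = run_config(), hypnogram_path = NULL) {
  features <- features_from_edf(edf_path, channel, config, hypnogram_path)
  det <- detect_recording(features, config$thresholds)
  write_features(features, paste0(out_prefix, "_features.csv"),
                 predictions = det)
  utils::write.csv(det, paste0(out_prefix, "_predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  summary <- list(
    edf = edf_path, channel = channel,
    epochs = nrow(features),
    invalid_epochs = sum(!features$valid),
    candidates = sum(det$candidate),
    rem_detected = sum(det$predicted == "REM"),
    thresholds = unclass(config$thresholds)
  )
  if (!all(is.na(features$stage))) {
    ev <- evaluate_detection(det, features$stage,
                             config$exclude_unscored,
                             config$movement_as_wake)
    summary$metrics <- as.list(ev$metrics)
    summary$kappa <- ev$kappa
  }
  jsonlite::write_json(summary, paste0(out_prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = features, detection = det, summary = summary))
}

#' Train on one set of recordings and evaluate on another
#'
#' Calibrates the thresholds on the pooled epochs of the training
#' recordings only, then scores the test recordings with those frozen
#' thresholds. Train and test sets must be disjoint.
#'
#' @param train_sets,test_sets Named lists of `epoch_features`
#'   data.frames with stage labels (e.g. from [features_from_edf] via
#'   [run_detect()], or directly from [extract_features()]).
#' @param config A [run_config()] (evaluation policy).
#' @return List with `thresholds`, `per_recording` (metrics
#'   data.frame mirroring per-subject report tables), `average`
#'   (unweighted means), `pooled` (metrics on summed counts), `kappa`
#'   and `breakdown` (per-stage false positives over the test set).
#' @export
run_train_eval <- function(train_sets, test_sets, config = run_config()) {
  if (is.data.frame(train_sets)) train_sets <- list(train = train_sets)
  if (is.data.frame(test_sets)) test_sets <- list(test = test_sets)
  overlap <- intersect(names(train_sets), names(test_sets))
  if (length(overlap) > 0) {
    stop("train and test sets overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  th <- calibrate_thresholds(do.call(rbind, train_sets))
  pooled <- list(tp = 0, fp = 0, tn = 0, fn = 0, n = 0)
  all_pred <- character(0); all_stage <- character(0)
  rows <- lapply(names(test_sets), function(nm) {
    fx <- test_sets[[nm]]
    det <- detect_recording(fx, th)
    ref <- reference_binary(fx$stage, config$exclude_unscored,
                            config$movement_as_wake)
    cc <- confusion(det$predicted, ref)
    pooled$tp <<- pooled$tp + cc$tp; pooled$fp <<- pooled$fp + cc$fp
    pooled$tn <<- pooled$tn + cc$tn; pooled$fn <<- pooled$fn + cc$fn
    pooled$n <<- pooled$n + cc$n
    all_pred <<- c(all_pred, det$predicted)
    all_stage <<- c(all_stage, fx$stage)
    m <- rem_metrics(cc)
    data.frame(recording = nm, rem_total = cc$tp + cc$fn,
               rem_detected = cc$tp + cc$fp, tp = cc$tp,
               sensitivity = m["sensitivity"], specificity = m["specificity"],
               selectivity = m["selectivity"], accuracy = m["accuracy"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  per_recording <- do.call(rbind, rows)
  class(pooled) <- "confusion_counts"
  ref_all <- reference_binary(all_stage, config$exclude_unscored,
                              config$movement_as_wake)
  list(
    thresholds = th,
    per_recording = per_recording,
    average = colMeans(per_recording[, c("sensitivity", "specificity",
                                         "selectivity", "accuracy")],
                       na.rm = TRUE),
    pooled = rem_metrics(pooled),
    kappa = cohens_kappa(all_pred, ref_all),
    breakdown = stage_fp_breakdown(all_pred, all_stage,
                                   config$exclude_unscored,
                                   config$movement_as_wake)
  )
}
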