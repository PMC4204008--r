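# Run configuration: analysis band, thresholds, epoch geometry, stage
# symbol mapping and the evaluation exclusion policy, loadable from
# YAML with the shipped defaults.

#' Default run configuration
#'
#' Bundles the analysis defaults: 8-16 Hz band, the fixed classifier
#' thresholds, 30-s epochs of 2-s subepochs, 9-point SEFd smoothing,
#' the default stage-symbol map, and the evaluation policy (unscored
#' epochs excluded, movement scored as Wake).
#'
#' @param band A [band_config()].
#' @param thresholds A [rem_thresholds()].
#' @param epoch_seconds,subepoch_seconds Epoch geometry in seconds.
#' @param smooth_width SEFd moving-average width (odd).
#' @param stage_map Named symbol-to-stage map.
#' @param exclude_unscored,movement_as_wake Evaluation policy flags.
#' @param seed Integer seed for all randomized steps.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(band = band_config(),
                       thresholds = rem_thresholds(),
                       epoch_seconds = 30,
                       subepoch_seconds = 2,
                       smooth_width = 9,
                       stage_map = default_stage_map(),
                       exclude_unscored = TRUE,
                       movement_as_wake = TRUE,
                       seed = 1) {
  stopifnot(inherits(band, "band_config"),
            inherits(thresholds, "rem_thresholds"),
            epoch_seconds > 0, subepoch_seconds > 0,
            epoch_seconds %% subepoch_seconds == 0,
            smooth_width >= 1, smooth_width %% 2 == 1)
  structure(list(band = band, thresholds = thresholds,
                 epoch_seconds = epoch_seconds,
                 subepoch_seconds = subepoch_seconds,
                 smooth_width = smooth_width, stage_map = stage_map,
                 exclude_unscored = exclude_unscored,
                 movement_as_wake = movement_as_wake,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys override the shipped defaults. The
#' recognized keys are `band` (list `f1`, `f2`), `thresholds` (list
#' `sefd_th`, `ap_max`, `rp_max`, `rp_min`), `epoch_seconds`,
#' `subepoch_seconds`, `smooth_width`, `stage_map` (mapping),
#' `exclude_unscored`, `movement_as_wake`, `seed`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A [run_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  defaults <- run_config()
  band <- if (!is.null(y$band)) band_config(y$band$f1, y$band$f2)
  else defaults$band
  th <- defaults$thresholds
  if (!is.null(y$thresholds)) {
    t <- utils::modifyList(unclass(th), y$thresholds)
    th <- rem_thresholds(t$sefd_th, t$ap_max, t$rp_max, t$rp_min)
  }
  smap <- defaults$stage_map
  if (!is.null(y$stage_map)) smap <- unlist(y$stage_map)
  pick <- function(key) if (!is.null(y[[key]])) y[[key]] else defaults[[key]]
  run_config(band = band, thresholds = th,
             epoch_seconds = pick("epoch_seconds"),
             subepoch_seconds = pick("subepoch_seconds"),
             smooth_width = pick("smooth_width"),
             stage_map = smap,
             exclude_unscored = pick("exclude_unscored"),
             movement_as_wake = pick("movement_as_wake"),
             seed = pick("seed"))
}
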