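#' Canonical sleep-stage labels
#'
#' The stage vocabulary used throughout the package: the five AASM
#' stages plus markers for unscored and movement epochs.
#'
#' @return Character vector of the seven canonical stage symbols.
#' @export
stage_levels <- function() {
  c("W", "N1", "N2", "N3", "REM", "UNSCORED", "MOVEMENT")
}

#' Construct a hypnogram
#'
#' Per-epoch sleep-stage labels with a fixed epoch duration.
#'
#' @param stages Character vector of stage labels drawn from
#'   [stage_levels()].
#' @param epoch_seconds Epoch duration in seconds (default 30, the
#'   standard polysomnography scoring unit).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_seconds = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), stage_levels())
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      epoch_seconds <= 0) {
    stop("`epoch_seconds` must be a single positive number", call. = FALSE)
  }
  structure(list(stages = stages, epoch_seconds = as.numeric(epoch_seconds)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = stage_levels()))
  cat(sprintf("<hypnogram> %d epochs of %g s\n", length(x$stages),
              x$epoch_seconds))
  print(tab[tab > 0])
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Default stage-symbol mapping
#'
#' Maps file symbols to canonical stages. Covers AASM letters
#' (`W`, `N1`, `N2`, `N3`, `R`/`REM`), R&K digits (`0` wake, `1`-`3`
#' stages 1-3, `4` stage 4 collapsed into N3, `5` REM), and the
#' Sleep-EDF annotation strings (`Sleep stage W`, `Sleep stage R`,
#' `Movement time`, ...). Unscored markers (`?`, `-1`,
#' `Sleep stage ?`) map to `UNSCORED`, movement (`MT`,
#' `Movement time`) to `MOVEMENT`.
#'
#' @return Named character vector: `names` are file symbols, values are
#'   canonical stages.
#' @export
default_stage_map <- function() {
  c(
    "W" = "W", "N1" = "N1", "N2" = "N2", "N3" = "N3",
    "R" = "REM", "REM" = "REM",
    # R&K digits; stages S3 and S4 both collapse into AASM N3
    "0" = "W", "1" = "N1", "2" = "N2", "3" = "N3", "4" = "N3", "5" = "REM",
    "MT" = "MOVEMENT", "MOVEMENT" = "MOVEMENT",
    "?" = "UNSCORED", "-1" = "UNSCORED", "UNSCORED" = "UNSCORED",
    "Sleep stage W" = "W", "Sleep stage 1" = "N1", "Sleep stage 2" = "N2",
    "Sleep stage 3" = "N3", "Sleep stage 4" = "N3", "Sleep stage R" = "REM",
    "Sleep stage ?" = "UNSCORED", "Movement time" = "MOVEMENT"
  )
}

map_stage_symbols <- function(symbols, stage_map, context = "hypnogram") {
  idx <- match(symbols, names(stage_map))
  if (anyNA(idx)) {
    line <- which(is.na(idx))[1L]
    stop(sprintf("%s: unmapped stage symbol \"%s\" at entry %d",
                 context, symbols[line], line), call. = FALSE)
  }
  unname(stage_map[idx])
}

#' Read a hypnogram file
#'
#' Two dialects are supported. `"plain"` is one stage symbol per line;
#' `"edfplus"` reads the `EDF Annotations` signal of an EDF+ file and
#' converts the stage annotations to per-epoch labels.
#'
#' @param path Path to the hypnogram file.
#' @param dialect `"plain"` or `"edfplus"`.
#' @param stage_map Named character vector mapping file symbols to
#'   canonical stages; defaults to [default_stage_map()].
#' @param epoch_seconds Epoch duration in seconds.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("plain", "edfplus"),
                           stage_map = default_stage_map(),
                           epoch_seconds = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "plain") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    stages <- map_stage_symbols(lines, stage_map, context = path)
    hypnogram(stages, epoch_seconds)
  } else {
    read_edfplus_hypnogram(path, stage_map, epoch_seconds)
  }
}

#' Write a hypnogram as plain text
#'
#' One canonical stage symbol per line; the lossless counterpart of
#' `read_hypnogram(dialect = "plain")` with the identity mapping.
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  writeLines(hyp$stages, path)
  invisible(path)
}
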