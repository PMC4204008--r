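# CSV serialization of feature tables and detection results.

#' Write an epoch feature table to CSV
#'
#' One row per epoch: index, smoothed SEFd, AP, RP, validity flag,
#' and, when available, the predicted and reference labels. Values are
#' written with enough precision that a read-back reproduces them to
#' at least six decimals.
#'
#' @param features An `epoch_features` data.frame from
#'   [extract_features()].
#' @param path Output path.
#' @param predictions Optional `detection_result` (or character vector)
#'   to include as a `predicted` column.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, predictions = NULL) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0) {
    stop("refusing to write an empty feature table", call. = FALSE)
  }
  out <- data.frame(
    epoch = features$epoch,
    sefd = features$sefd,
    ap = features$ap,
    rp = features$rp,
    valid = features$valid,
    stringsAsFactors = FALSE
  )
  if (!is.null(predictions)) {
    out$predicted <- if (is.data.frame(predictions)) predictions$predicted
    else predictions
  }
  if (!is.null(features$stage) && !all(is.na(features$stage))) {
    out$reference <- features$stage
  }
  utils::write.csv(format(out, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back an epoch feature table
#'
#' @param path CSV written by [write_features()].
#' @return Data.frame with the stored columns; numeric columns parsed
#'   back to numeric.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("sefd", "ap", "rp"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("valid" %in% names(df)) df$valid <- as.logical(df$valid)
  df
}
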