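# Minimal EDF/EDF+ support: fixed-width ASCII header, 16-bit little-endian
# samples, and TAL parsing for EDF+ annotation signals. Only the subset
# needed for single-channel sleep EEG plus hypnogram annotations.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: ", x, call. = FALSE)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = 6), 1, width)
  edf_pad(s, width)
}

read_edf_header <- function(con) {
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  h <- list()
  h$version <- trimws(rd(8))
  h$patient <- trimws(rd(80))
  h$recording <- trimws(rd(80))
  h$startdate <- rd(8)
  h$starttime <- rd(8)
  h$header_bytes <- as.integer(trimws(rd(8)))
  h$reserved <- trimws(rd(44))
  h$n_records <- as.integer(trimws(rd(8)))
  h$record_seconds <- as.numeric(trimws(rd(8)))
  h$ns <- as.integer(trimws(rd(4)))
  if (is.na(h$ns) || h$ns < 1) stop("malformed EDF header", call. = FALSE)
  ns <- h$ns
  fld <- function(w) {
    vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  }
  h$label <- fld(16)
  h$transducer <- fld(80)
  h$phys_dim <- fld(8)
  h$phys_min <- as.numeric(fld(8))
  h$phys_max <- as.numeric(fld(8))
  h$dig_min <- as.numeric(fld(8))
  h$dig_max <- as.numeric(fld(8))
  h$prefilter <- fld(80)
  h$spr <- as.integer(fld(8))   # samples per data record, per signal
  h$sig_reserved <- fld(32)
  if (anyNA(h$spr) || anyNA(h$phys_min) || anyNA(h$phys_max) ||
      anyNA(h$dig_min) || anyNA(h$dig_max)) {
    stop("malformed EDF signal header", call. = FALSE)
  }
  h
}

#' Read one signal from an EDF/EDF+ file
#'
#' Parses the EDF header, locates the named channel and returns its
#' samples rescaled to physical units, together with the sampling rate
#' derived from the samples-per-record and record-duration header
#' fields.
#'
#' @param path Path to an EDF or EDF+ file.
#' @param channel Channel label to extract (exact match against the EDF
#'   signal labels).
#' @return An [eeg_record()].
#' @export
read_edf_signal <- function(path, channel) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  idx <- match(channel, h$label)
  if (is.na(idx)) {
    stop(sprintf("channel \"%s\" not found in %s (available: %s)",
                 channel, path, paste(h$label, collapse = ", ")),
         call. = FALSE)
  }
  n_rec <- h$n_records
  out <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(h$ns)) {
      vals <- readBin(con, "integer", n = h$spr[s], size = 2,
                      signed = TRUE, endian = "little")
      if (s == idx) out[[r]] <- vals
    }
  }
  dig <- unlist(out)
  gain <- (h$phys_max[idx] - h$phys_min[idx]) / (h$dig_max[idx] - h$dig_min[idx])
  phys <- (dig - h$dig_min[idx]) * gain + h$phys_min[idx]
  fs <- h$spr[idx] / h$record_seconds
  eeg_record(phys, fs = fs, channel = channel)
}

#' Write signals to an EDF file
#'
#' Encodes one or more [eeg_record()] signals as 16-bit EDF. The
#' physical range of each signal is set to its (symmetric) data range,
#' so the round-trip quantization error is at most one step of
#' `(phys_max - phys_min) / (dig_max - dig_min)`.
#'
#' @param records A single [eeg_record()] or a list of them. All must
#'   share a duration that is an integer number of `record_seconds`.
#' @param path Output path.
#' @param record_seconds Duration of one EDF data record (default 1 s).
#' @return `path`, invisibly.
#' @export
write_edf <- function(records, path, record_seconds = 1) {
  if (inherits(records, "eeg_record")) records <- list(records)
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, logical(1), "eeg_record")))
  durs <- vapply(records, duration, numeric(1))
  if (length(unique(round(durs, 9))) != 1) {
    stop("all signals must have equal duration", call. = FALSE)
  }
  n_rec <- durs[1] / record_seconds
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop("duration must be an integer multiple of record_seconds",
         call. = FALSE)
  }
  n_rec <- as.integer(round(n_rec))
  ns <- length(records)
  spr <- vapply(records, function(r) as.integer(round(r$fs * record_seconds)),
                integer(1))
  dig_min <- -32768; dig_max <- 32767
  pr <- lapply(records, function(r) {
    m <- max(abs(r$samples), 1e-6)
    c(-m, m)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x) writeChar(x, con, eos = NULL)
  header_bytes <- 256L + 256L * ns
  w(edf_pad("0", 8))
  w(edf_pad("X X X X", 80))
  w(edf_pad("Startdate 01-JAN-2000 X X X", 80))
  w(edf_pad("01.01.00", 8))
  w(edf_pad("00.00.00", 8))
  w(edf_pad(header_bytes, 8))
  w(edf_pad("", 44))
  w(edf_pad(n_rec, 8))
  w(edf_num(record_seconds, 8))
  w(edf_pad(ns, 4))
  for (r in records) w(edf_pad(r$channel, 16))
  for (r in records) w(edf_pad("", 80))
  for (r in records) w(edf_pad("uV", 8))
  for (p in pr) w(edf_num(p[1], 8))
  for (p in pr) w(edf_num(p[2], 8))
  for (r in records) w(edf_pad(dig_min, 8))
  for (r in records) w(edf_pad(dig_max, 8))
  for (r in records) w(edf_pad("", 80))
  for (s in spr) w(edf_pad(s, 8))
  for (r in records) w(edf_pad("", 32))
  # digitize with the written (string-rounded) physical range so that the
  # reader reconstructs with the same gain we quantized with
  pr_written <- lapply(pr, function(p) {
    c(as.numeric(trimws(edf_num(p[1], 8))), as.numeric(trimws(edf_num(p[2], 8))))
  })
  dig <- lapply(seq_len(ns), function(i) {
    p <- pr_written[[i]]
    gain <- (p[2] - p[1]) / (dig_max - dig_min)
    d <- round((records[[i]]$samples - p[1]) / gain + dig_min)
    as.integer(pmin(pmax(d, dig_min), dig_max))
  })
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      sel <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      writeBin(dig[[s]][sel], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# --- EDF+ annotations (TALs) ------------------------------------------------

parse_tals <- function(raw_bytes) {
  # TAL: +onset[\x15duration]\x14text\x14[text\x14...]\x00
  chunks <- split_raw(raw_bytes, as.raw(0L))
  out <- list()
  for (ch in chunks) {
    if (length(ch) == 0) next
    fields <- split_raw(ch, as.raw(20L))  # 0x14
    if (length(fields) < 1) next
    head <- rawToChar(fields[[1]])
    parts <- strsplit(head, "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(onset)) next
    dur <- if (length(parts) > 1) suppressWarnings(as.numeric(parts[2])) else NA_real_
    texts <- vapply(fields[-1], rawToChar, character(1))
    texts <- texts[nzchar(texts)]
    for (tx in texts) {
      out[[length(out) + 1L]] <- list(onset = onset, duration = dur, text = tx)
    }
  }
  out
}

split_raw <- function(x, sep) {
  idx <- which(x == sep)
  starts <- c(1L, idx + 1L)
  ends <- c(idx - 1L, length(x))
  lapply(seq_along(starts), function(i) {
    if (starts[i] > ends[i]) raw(0) else x[starts[i]:ends[i]]
  })
}

read_edfplus_hypnogram <- function(path, stage_map, epoch_seconds) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  idx <- match("EDF Annotations", h$label)
  if (is.na(idx)) stop("no \"EDF Annotations\" signal in ", path, call. = FALSE)
  anns <- list()
  for (r in seq_len(h$n_records)) {
    for (s in seq_len(h$ns)) {
      nbytes <- 2L * h$spr[s]
      b <- readBin(con, "raw", n = nbytes)
      if (s == idx) anns <- c(anns, parse_tals(b))
    }
  }
  if (length(anns) == 0) stop("no stage annotations found in ", path,
                              call. = FALSE)
  ord <- order(vapply(anns, `[[`, numeric(1), "onset"))
  anns <- anns[ord]
  total_end <- max(vapply(anns, function(a) {
    a$onset + if (is.na(a$duration)) epoch_seconds else a$duration
  }, numeric(1)))
  n_epochs <- as.integer(round(total_end / epoch_seconds))
  stages <- rep(NA_character_, n_epochs)
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    stage <- map_stage_symbols(a$text, stage_map,
                               context = sprintf("%s (annotation %d)", path, i))
    dur <- if (is.na(a$duration)) epoch_seconds else a$duration
    e0 <- as.integer(floor(a$onset / epoch_seconds)) + 1L
    e1 <- as.integer(round((a$onset + dur) / epoch_seconds))
    if (e1 >= e0) stages[e0:min(e1, n_epochs)] <- stage
  }
  stages[is.na(stages)] <- "UNSCORED"
  hypnogram(stages, epoch_seconds)
}

#' Write a hypnogram as an EDF+ annotation file
#'
#' Produces a minimal EDF+ file containing only an `EDF Annotations`
#' signal, one data record per epoch, each carrying a stage annotation
#' (`Sleep stage W`, `Sleep stage R`, ...). Primarily used to exercise
#' the EDF+ hypnogram reading path end to end.
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edfplus_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  to_text <- c(W = "Sleep stage W", N1 = "Sleep stage 1", N2 = "Sleep stage 2",
               N3 = "Sleep stage 3", REM = "Sleep stage R",
               UNSCORED = "Sleep stage ?", MOVEMENT = "Movement time")
  es <- hyp$epoch_seconds
  # per record: a timekeeping TAL and a stage TAL, each NUL-terminated
  tals <- lapply(seq_along(hyp$stages), function(i) {
    onset <- (i - 1) * es
    c(charToRaw(sprintf("+%s\x14\x14", format(onset))), as.raw(0L),
      charToRaw(sprintf("+%s\x15%s\x14%s\x14", format(onset), format(es),
                        to_text[[hyp$stages[i]]])), as.raw(0L))
  })
  nbytes <- max(lengths(tals)) + 2L
  if (nbytes %% 2L == 1L) nbytes <- nbytes + 1L
  spr <- nbytes %/% 2L
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x) writeChar(x, con, eos = NULL)
  w(edf_pad("0", 8)); w(edf_pad("X X X X", 80))
  w(edf_pad("Startdate 01-JAN-2000 X X X", 80))
  w(edf_pad("01.01.00", 8)); w(edf_pad("00.00.00", 8))
  w(edf_pad(256L + 256L, 8)); w(edf_pad("EDF+C", 44))
  w(edf_pad(length(tals), 8)); w(edf_num(es, 8)); w(edf_pad(1L, 4))
  w(edf_pad("EDF Annotations", 16)); w(edf_pad("", 80)); w(edf_pad("", 8))
  w(edf_num(0, 8)); w(edf_num(1, 8)); w(edf_pad(-32768, 8)); w(edf_pad(32767, 8))
  w(edf_pad("", 80)); w(edf_pad(spr, 8)); w(edf_pad("", 32))
  for (b in tals) {
    writeBin(c(b, raw(nbytes - length(b))), con)
  }
  invisible(path)
}
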