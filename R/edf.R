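#' Continuous multichannel recording with an event list
#'
#' @param signal numeric `channel x sample` matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names optional channel labels.
#' @param events data frame with columns `sample` (0-based onset sample
#'   index) and `label` (integer class id); may have zero rows.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(signal, fs, channel_names = NULL,
                                 events = NULL) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  if (!is.numeric(fs) || fs <= 0)
    stop("continuous_recording: 'fs' must be > 0")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%03d", seq_len(nrow(signal)))
  if (is.null(events))
    events <- data.frame(sample = integer(0), label = integer(0))
  if (!all(c("sample", "label") %in% names(events)))
    stop("continuous_recording: 'events' needs columns 'sample' and 'label'")
  if (nrow(events) && (any(events$sample < 0) ||
                       any(events$sample >= ncol(signal))))
    stop("continuous_recording: event sample indices outside the recording")
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 events = events),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("ContinuousRecording: %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$events)))
  invisible(x)
}

# --- EDF primitives -------------------------------------------------------
# EDF stores 16-bit little-endian integers in fixed-size data records, with
# an ASCII header of 256 + 256*ns bytes. EDF+ annotations travel in a signal
# labelled "EDF Annotations" as 0-terminated "time-stamped annotation lists"
# (TALs): "+onset[\x15duration]\x14text\x14...\x00".

# print a number into at most 8 ASCII chars (digital samples outside the
# rounded physical range are clamped at write time)
edf_num <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= 8) return(s)
  }
  stop("EDF numeric field cannot be represented in 8 chars: ", x)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF field too wide: ", x)
  formatC(x, width = -width, flag = " ")
}

#' Read a European Data Format (EDF/EDF+) file
#'
#' Loads all ordinary signal channels at their native sampling rate and maps
#' an "EDF Annotations" channel, when present, to the recording's event
#' list: each annotation becomes an event at sample `round(onset * fs)` with
#' the annotation text parsed as an integer label (non-numeric texts are
#' coded as factor levels). All ordinary channels must share one sampling
#' rate. Physical values are reconstructed from the stored digital values
#' via the per-channel calibration fields.
#'
#' @param path path to an EDF file.
#' @return A [continuous_recording]. When the file carries no annotations a
#'   warning is emitted and the event list is empty.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("read_edf: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    if (length(raw) < n) stop("read_edf: parse error at offset ",
                              seek(con), ": truncated header")
    trimws(rawToChar(raw))
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("read_edf: parse error: non-numeric ", what,
                       " field '", x, "'")
    v
  }
  rd(8)                      # version
  rd(80); rd(80)             # patient, recording id
  rd(8); rd(8)               # start date, time
  header_bytes <- num(rd(8), "header-bytes")
  rd(44)                     # reserved
  n_records <- num(rd(8), "record-count")
  record_dur <- num(rd(8), "record-duration")
  ns <- num(rd(4), "signal-count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                       # transducer
  for (i in seq_len(ns)) rd(8)                        # dimension
  pmin <- vapply(seq_len(ns), function(i) num(rd(8), "phys-min"), 0)
  pmax <- vapply(seq_len(ns), function(i) num(rd(8), "phys-max"), 0)
  dmin <- vapply(seq_len(ns), function(i) num(rd(8), "dig-min"), 0)
  dmax <- vapply(seq_len(ns), function(i) num(rd(8), "dig-max"), 0)
  for (i in seq_len(ns)) rd(80)                       # prefilter
  spr <- vapply(seq_len(ns), function(i) num(rd(8), "samples-per-record"), 0)
  for (i in seq_len(ns)) rd(32)                       # reserved
  if (header_bytes != 256 + 256 * ns)
    stop("read_edf: parse error: header size field inconsistent with ns")

  is_ann <- labels == "EDF Annotations"
  rec_words <- sum(spr)
  expected <- header_bytes + 2 * rec_words * n_records
  if (file.size(path) < expected)
    stop("read_edf: parse error at offset ", file.size(path),
         ": file truncated (expected ", expected, " bytes)")

  sig_idx <- which(!is_ann)
  if (length(sig_idx) == 0L) stop("read_edf: no ordinary signal channels")
  if (length(unique(spr[sig_idx])) != 1L)
    stop("read_edf: channels with differing sampling rates are not supported")
  fs <- spr[sig_idx[1]] / record_dur
  n_samples <- spr[sig_idx[1]] * n_records
  signal <- matrix(0, length(sig_idx), n_samples)
  ann_raw <- raw(0)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        bytes <- readBin(con, "raw", 2 * spr[i])
        ann_raw <- c(ann_raw, bytes)
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                       endian = "little")
        j <- match(i, sig_idx)
        phys <- (dig - dmin[i]) * (pmax[i] - pmin[i]) /
          (dmax[i] - dmin[i]) + pmin[i]
        signal[j, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
      }
    }
  }
  events <- data.frame(sample = integer(0), label = integer(0))
  if (any(is_ann)) {
    events <- parse_edf_annotations(ann_raw, fs)
  } else {
    warning("read_edf: no annotations channel; event list is empty")
  }
  continuous_recording(signal, fs, channel_names = trimws(labels[sig_idx]),
                       events = events)
}

parse_edf_annotations <- function(ann_raw, fs) {
  # TALs are separated by NUL bytes; split the raw stream on them first
  # (rawToChar refuses embedded NULs).
  nul <- which(ann_raw == as.raw(0))
  starts <- c(1L, nul + 1L)
  ends <- c(nul - 1L, length(ann_raw))
  onset <- numeric(0); text <- character(0)
  for (ci in seq_along(starts)) {
    if (starts[ci] > ends[ci]) next
    tal <- rawToChar(ann_raw[starts[ci]:ends[ci]])
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) next  # timekeeping TAL
    stamp <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]][1]
    onset <- c(onset, as.numeric(stamp))
    text <- c(text, parts[2])
  }
  lab <- suppressWarnings(as.integer(text))
  if (length(lab) && any(is.na(lab)))
    lab <- as.integer(factor(text))
  data.frame(sample = as.integer(round(onset * fs)),
             label = if (length(lab)) lab else integer(0))
}

#' Write a recording to EDF+ format
#'
#' Emits one EDF+ file with one data record per second when the recording's
#' length is an integer number of seconds, otherwise a single record
#' covering the whole recording. Events are written as an "EDF Annotations"
#' channel (all annotations land in the first record, as EDF+ permits).
#' Signals are quantized to the 16-bit digital range over each channel's
#' physical range, so the write/read round-trip is exact to about 1 part in
#' 3e4 of the channel range.
#'
#' @param rec a [continuous_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  nc <- nrow(rec$signal); n <- ncol(rec$signal); fs <- rec$fs
  if (n %% fs == 0 && n / fs > 1) {
    n_records <- n / fs; record_dur <- 1; spr_sig <- fs
  } else {
    n_records <- 1; record_dur <- n / fs; spr_sig <- n
  }
  has_ann <- TRUE  # always write an annotations channel (EDF+C requires one)
  # each TAL is NUL-terminated; R strings cannot hold NULs, so assemble raw
  tal_bytes <- function(tals) {
    out <- raw(0)
    for (tl in tals) out <- c(out, charToRaw(tl), as.raw(0))
    out
  }
  tals <- "+0\x14\x14"
  if (nrow(rec$events))
    tals <- c(tals, sprintf("+%.6g\x15%g\x14%s\x14", rec$events$sample / fs,
                            0, as.character(rec$events$label)))
  tals_raw <- tal_bytes(tals)
  spr_ann <- max(16, ceiling(length(tals_raw) / 2) + 8)
  ns <- nc + 1L

  phys_lo <- apply(rec$signal, 1, min); phys_hi <- apply(rec$signal, 1, max)
  flat <- phys_hi - phys_lo < 1e-12
  phys_lo[flat] <- phys_lo[flat] - 1; phys_hi[flat] <- phys_hi[flat] + 1
  # calibration fields are 8 ASCII chars; use the printed (rounded) values
  # for quantization too, so header and samples agree exactly
  phys_lo <- as.numeric(vapply(phys_lo, edf_num, ""))
  phys_hi <- as.numeric(vapply(phys_hi, edf_num, ""))
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("synthetic recording", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("EDF+C", 44)
  wr(n_records, 8); wr(format(record_dur, digits = 7), 8); wr(ns, 4)
  for (i in seq_len(nc)) wr(substr(rec$channel_names[i], 1, 16), 16)
  wr("EDF Annotations", 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(nc)) wr("uV", 8); wr("", 8)
  for (i in seq_len(nc)) wr(edf_num(phys_lo[i]), 8); wr(-1, 8)
  for (i in seq_len(nc)) wr(edf_num(phys_hi[i]), 8); wr(1, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(nc)) wr(spr_sig, 8); wr(spr_ann, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * spr_sig + 1):(r * spr_sig)
    for (i in seq_len(nc)) {
      dig <- round((rec$signal[i, idx] - phys_lo[i]) / (phys_hi[i] - phys_lo[i]) *
                     (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
    tal_raw <- if (r == 1) tals_raw else
      tal_bytes(sprintf("+%g\x14\x14", (r - 1) * record_dur))
    buf <- raw(2 * spr_ann)
    buf[seq_along(tal_raw)] <- tal_raw
    writeBin(buf, con)
  }
  invisible(path)
}
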