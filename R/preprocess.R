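#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass, run forward and backward
#' ([signal::filtfilt()]) so the net phase response is zero, independently
#' to every channel of a continuous recording. The default 0.3-30 Hz band
#' removes DC drift and high-frequency muscle activity while keeping the
#' frequencies that dominate visually evoked responses.
#'
#' @param rec a [continuous_recording].
#' @param lo lower band edge in Hz (default 0.3).
#' @param hi upper band edge in Hz (default 30).
#' @return A [continuous_recording] of identical geometry.
#' @export
bandpass_filter <- function(rec, lo = 0.3, hi = 30) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop("bandpass_filter: need 0 < lo < hi < fs/2 (got lo=", lo,
         ", hi=", hi, ", fs/2=", nyq, ")")
  bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  out <- rec$signal
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- signal::filtfilt(bf, rec$signal[ch, ])
  continuous_recording(out, rec$fs, rec$channel_names, rec$events)
}

#' Cut fixed-length epochs around events
#'
#' Extracts one trial per event, a half-open window
#' `[onset, onset + round(window_s * fs))` in 0-based sample indices
#' starting at the event sample. At 250 Hz a 1-s window therefore yields
#' exactly 250 samples. Epoching is pure: the same recording and events
#' always produce an identical epoch set.
#'
#' @param rec a [continuous_recording] whose `events` hold 0-based onset
#'   samples and integer labels.
#' @param window_s window length in seconds (default 1).
#' @param events optional event data frame overriding `rec$events`.
#' @return An [epoch_set] with one trial per event.
#' @export
epoch_extract <- function(rec, window_s = 1, events = NULL) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (is.null(events)) events <- rec$events
  if (nrow(events) == 0L) stop("epoch_extract: no events to epoch")
  n_win <- round(window_s * rec$fs)
  if (n_win < 1) stop("epoch_extract: window too short")
  ends <- events$sample + n_win            # 0-based, exclusive
  bad <- which(ends > ncol(rec$signal))
  if (length(bad))
    stop("epoch_extract: events too close to the recording end, dropped: ",
         paste(bad, collapse = ", "))
  n <- nrow(events)
  data <- array(0, c(n, nrow(rec$signal), n_win))
  for (i in seq_len(n)) {
    s0 <- events$sample[i]                 # 0-based onset
    data[i, , ] <- rec$signal[, (s0 + 1):(s0 + n_win), drop = FALSE]
  }
  epoch_set(data, labels = events$label, fs = rec$fs,
            channel_names = rec$channel_names)
}
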