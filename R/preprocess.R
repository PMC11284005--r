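#' Band-pass and notch filter specification
#'
#' Defaults follow the standard Holter pre-filtering choices: a zero-phase
#' second-order IIR band-pass with a 0.67--100 Hz passband (removing baseline
#' wander and high-frequency noise) and a 50 Hz notch for European power-line
#' interference.
#'
#' @param passband_low,passband_high band edges, Hz.
#' @param order band-pass section order (2 = one biquad; applied
#'   forward-backward, so the effective attenuation is doubled).
#' @param notch_freq,notch_q notch centre frequency (Hz) and quality factor.
#' @return A `vt_filter_spec` list.
#' @export
filter_spec <- function(passband_low = 0.67, passband_high = 100, order = 2,
                        notch_freq = 50, notch_q = 30) {
  if (passband_low <= 0 || passband_high <= passband_low)
    vt_abort("need 0 < passband_low < passband_high")
  if (order %% 2 != 0) vt_abort("order must be even (biquad sections)")
  structure(list(passband_low = passband_low, passband_high = passband_high,
                 order = order, notch_freq = notch_freq, notch_q = notch_q),
            class = "vt_filter_spec")
}

# Second-order IIR notch (constrained biquad), centre w0, quality q.
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

#' Apply zero-phase band-pass and notch filtering to a recording
#'
#' Each lead is passed forward-backward (zero phase) through one band-pass
#' biquad and then through a 50 Hz notch biquad.  When the sampling rate
#' leaves less than the requested upper band edge below Nyquist
#' (`fs < 200` Hz for the default 100 Hz edge), the edge is clipped to
#' `0.45 * fs`; when `fs <= 2 * notch_freq` the notch is skipped.  Both
#' adjustments emit a warning.
#'
#' @param recording a `vt_recording`.
#' @param spec a [filter_spec()].
#' @return The recording with filtered `signal` (same length).
#' @export
apply_filters <- function(recording, spec = filter_spec()) {
  fs <- recording$fs
  if (fs <= 2 * spec$passband_low) vt_abort("fs must exceed 2 * passband_low")
  hi <- spec$passband_high
  if (fs < 200 && hi > 0.45 * fs) {
    hi <- 0.45 * fs
    vt_warn(sprintf("passband_high clipped to %.1f Hz (fs = %g Hz)", hi, fs))
  }
  bp <- signal::butter(spec$order / 2, c(spec$passband_low, hi) / (fs / 2),
                       type = "pass")
  do_notch <- fs > 2 * spec$notch_freq
  if (!do_notch) vt_warn("notch skipped: fs <= 2 * notch_freq")
  nc <- if (do_notch) notch_coefs(spec$notch_freq, fs, spec$notch_q) else NULL
  for (ld in seq_len(ncol(recording$signal))) {
    x <- filtfilt_cpp(bp$b, bp$a, recording$signal[, ld])
    if (do_notch) x <- filtfilt_cpp(nc$b, nc$a, x)
    recording$signal[, ld] <- x
  }
  recording$filtered <- TRUE
  recording
}

#' Split a recording into consecutive 30-minute windows
#'
#' Produces the maximal set of disjoint, consecutive, full windows starting
#' at sample 0; a trailing partial window is discarded so every window has
#' identical length.  `contains_vt` flags overlap with annotated VT events.
#'
#' @param recording a `vt_recording`.
#' @param duration_min window length in minutes.
#' @return Data frame (class `vt_windows`) with 0-based half-open sample
#'   intervals, one row per window; zero rows (with a warning) when the
#'   recording is shorter than one window.
#' @export
split_windows <- function(recording, duration_min = 30) {
  win_len <- round(duration_min * 60 * recording$fs)
  n <- nrow(recording$signal)
  k <- n %/% win_len
  if (k == 0L) {
    vt_warn("recording shorter than one window; no windows produced")
  }
  idx <- seq_len(k) - 1L
  start <- idx * win_len
  end <- start + win_len
  contains_vt <- vapply(seq_along(idx), function(i) {
    any(vapply(recording$vt_events, function(ev)
      ev[1L] < end[i] && ev[2L] > start[i], logical(1)))
  }, logical(1))
  out <- data.frame(
    recording_id = rep(recording$recording_id, k),
    patient_id = rep(recording$patient_id, k),
    window_index = idx, start_sample = start, end_sample = end,
    duration_min = rep(duration_min, k),
    lead_used = rep(NA_integer_, k), bsqi = rep(NA_real_, k),
    quality_ok = rep(NA, k), contains_vt = contains_vt,
    stringsAsFactors = FALSE)
  class(out) <- c("vt_windows", "data.frame")
  out
}
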