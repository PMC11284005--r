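# The 22 per-beat waveform measures.  Durations in ms, amplitudes in mV
# relative to the beat's isoelectric level (median just before QRS onset),
# areas in mV*ms, slopes in mV/s.
MOR_MEASURES <- c("Pdur", "PRint", "QRSint", "QTint", "QTc_Bazett",
                  "QTc_Fridericia", "JTint", "Tdur", "Pamp", "Qamp", "Rwave",
                  "Samp", "Tamp", "QRSArea", "Tarea", "Parea", "STlevel",
                  "RslopeUp", "RslopeDown", "RSamp", "TRratio", "Jamp")
MOR_STATS <- c("mean", "median", "min", "max", "iqr")
RATIO_NAMES <- c("Nratio", "Sratio", "Vratio", "Fratio", "NoneRatio")

mor_feature_names <- function() {
  c(as.vector(t(outer(MOR_STATS, MOR_MEASURES, paste0))), RATIO_NAMES)
}

per_beat_measures <- function(beats, x, fs) {
  n <- nrow(beats)
  M <- matrix(NA_real_, n, length(MOR_MEASURES),
              dimnames = list(NULL, MOR_MEASURES))
  ok <- !is.na(beats$qrs_on) & !is.na(beats$qrs_off)
  if (!any(ok)) return(M)
  d <- c(0, diff(x)) * fs
  ms_of <- function(a, b) (b - a) / fs * 1000
  at <- function(i) ifelse(is.na(i), NA_real_, x[i + 1L])
  iso <- beats$iso
  rr_prev_s <- c(NA, diff(beats$r_sample)) / fs

  M[, "QRSint"] <- ifelse(ok, beats$qrs_dur_ms, NA)
  M[, "Rwave"] <- ifelse(ok, x[beats$r_sample + 1L] - iso, NA)
  M[, "Qamp"] <- at(beats$q_peak) - iso
  M[, "Samp"] <- at(beats$s_peak) - iso
  M[, "Tamp"] <- at(beats$t_peak) - iso
  M[, "Pamp"] <- at(beats$p_peak) - iso
  M[, "Jamp"] <- at(beats$qrs_off) - iso
  M[, "RSamp"] <- M[, "Rwave"] - M[, "Samp"]
  M[, "TRratio"] <- ifelse(M[, "Rwave"] != 0, M[, "Tamp"] / M[, "Rwave"], NA)

  M[, "Pdur"] <- ms_of(beats$p_on, beats$p_off)
  M[, "PRint"] <- ms_of(beats$p_on, beats$qrs_on)
  qt <- ms_of(beats$qrs_on, beats$t_off)
  M[, "QTint"] <- qt
  M[, "JTint"] <- ms_of(beats$qrs_off, beats$t_off)
  rr_ok <- !is.na(rr_prev_s) & rr_prev_s > 0
  M[, "QTc_Bazett"] <- ifelse(rr_ok, qt / sqrt(rr_prev_s), NA)
  M[, "QTc_Fridericia"] <- ifelse(rr_ok, qt / rr_prev_s^(1 / 3), NA)
  M[, "Tdur"] <- 2 * ms_of(beats$t_peak, beats$t_off)

  # ST level over 60-80 ms past QRS offset
  st0 <- pmin(length(x) - 1L, beats$qrs_off + round(0.06 * fs))
  st1 <- pmin(length(x) - 1L, beats$qrs_off + round(0.08 * fs))
  M[, "STlevel"] <- vapply(seq_len(n), function(b) {
    if (!ok[b]) return(NA_real_)
    mean(x[(st0[b]:st1[b]) + 1L]) - iso[b]
  }, numeric(1))

  # integrals and slopes need per-beat variable-length segments
  samp_ms <- 1000 / fs
  for (b in which(ok)) {
    qon <- beats$qrs_on[b] + 1L; qoff <- beats$qrs_off[b] + 1L
    seg <- abs(x[qon:qoff] - iso[b])
    M[b, "QRSArea"] <- trapz(seq_along(seg) * samp_ms, seg)
    if (!is.na(beats$t_off[b]) && beats$t_off[b] > beats$qrs_off[b]) {
      seg <- abs(x[qoff:(beats$t_off[b] + 1L)] - iso[b])
      M[b, "Tarea"] <- trapz(seq_along(seg) * samp_ms, seg)
    }
    if (!is.na(beats$p_on[b]) && !is.na(beats$p_off[b]) &&
        beats$p_off[b] > beats$p_on[b]) {
      seg <- abs(x[(beats$p_on[b] + 1L):(beats$p_off[b] + 1L)] - iso[b])
      M[b, "Parea"] <- trapz(seq_along(seg) * samp_ms, seg)
    }
    r1 <- beats$r_sample[b] + 1L
    if (!is.na(beats$q_peak[b]) && beats$q_peak[b] + 1L < r1)
      M[b, "RslopeUp"] <- max(d[(beats$q_peak[b] + 1L):r1])
    if (!is.na(beats$s_peak[b]) && beats$s_peak[b] + 1L > r1)
      M[b, "RslopeDown"] <- min(d[r1:(beats$s_peak[b] + 1L)])
  }
  M
}

#' Morphological feature set for one window
#'
#' Summarises each of the 22 per-beat waveform measures by its mean, median,
#' minimum, maximum and interquartile range over the window's classifiable
#' beats (beats labelled `none` are excluded from waveform statistics but
#' counted in `NoneRatio`), and appends the five beat-type ratios --- 115
#' features in total.  With fewer than 5 measurable beats the waveform
#' summaries are `NA` but ratios are still computed.
#'
#' @param beats classified delineation table ([classify_beats()] output).
#' @param x the window's analysed-lead signal, mV.
#' @param fs sampling frequency, Hz.
#' @return Named numeric vector of length 115.
#' @export
mor_features <- function(beats, x, fs) {
  nms <- mor_feature_names()
  out <- na_set(nms)
  nb <- nrow(beats)
  if (nb > 0L) {
    lab <- beats$label
    out["Nratio"] <- mean(lab == "N"); out["Sratio"] <- mean(lab == "S")
    out["Vratio"] <- mean(lab == "V"); out["Fratio"] <- mean(lab == "F")
    out["NoneRatio"] <- mean(lab == "none")
  }
  usable <- beats[beats$label != "none", , drop = FALSE]
  if (nrow(usable) >= 5L) {
    M <- per_beat_measures(usable, x, fs)
    for (m in MOR_MEASURES) {
      col <- M[, m]; col <- col[!is.na(col)]
      if (length(col) >= 5L) {
        srt <- sort.int(col)
        k <- length(srt)
        med <- if (k %% 2L) srt[(k + 1L) %/% 2L]
               else (srt[k %/% 2L] + srt[k %/% 2L + 1L]) / 2
        out[paste0("mean", m)] <- mean(col)
        out[paste0("median", m)] <- med
        out[paste0("min", m)] <- srt[1L]
        out[paste0("max", m)] <- srt[k]
        out[paste0("iqr", m)] <- iqr7(col)
      }
    }
  }
  out
}
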