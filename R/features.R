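#' Names of the HRV, MOR and PI feature columns
#'
#' @return Character vectors: 23 HRV, 115 MOR and 4 PI feature names.
#' @export
feature_names <- function() {
  hrv <- c("AVNN", "SDNN", "RMSSD", "pNN20", "pNN50", "SEM",
           "PIP", "IALS", "PSS", "PAS",
           "TOT_PWR", "VLF_PWR", "LF_PWR", "HF_PWR", "LF_HF", "LF_NORM",
           "HF_NORM",
           "SD1", "SD2", "SD1_SD2", "SampEn", "DFA_alpha1", "DFA_alpha2")
  list(hrv = hrv, mor = mor_feature_names(),
       pi = c("age", "sex", "bmi", "smoking"))
}

#' Full feature vector for one window
#'
#' Detects beats (energy detector on the analysed lead), delineates and
#' classifies them, then computes the 23 HRV and 115 morphological features.
#'
#' @param x filtered single-lead window signal, mV.
#' @param fs sampling frequency, Hz.
#' @param detections optional pre-computed 0-based R samples for the window.
#' @return Named numeric vector of 138 features, plus attribute `"beats"`
#'   with the classified beat table.
#' @export
window_features <- function(x, fs, detections = NULL) {
  if (is.null(detections)) detections <- detect_qrs_primary(x, fs)
  delin <- delineate(x, fs, detections)
  beats <- classify_beats(delin, x, fs)
  # sub-sample R times for the RR series: at low sampling rates the +/- half
  # sample quantisation otherwise dominates the small-increment statistics
  # (fragmentation indices especially)
  rr <- compute_rr(data.frame(r_sample = refine_subsample(x, beats$r_sample),
                              label = beats$label), fs)
  out <- c(hrv_features(rr), mor_features(beats, x, fs))
  attr(out, "beats") <- beats
  out
}

# Parabolic (three-point) apex interpolation of |x| around integer peaks;
# returns fractional 0-based sample positions.
refine_subsample <- function(x, r0) {
  n <- length(x)
  i <- r0 + 1L
  y1 <- abs(x[pmax(i - 1L, 1L)])
  y2 <- abs(x[i])
  y3 <- abs(x[pmin(i + 1L, n)])
  den <- y1 - 2 * y2 + y3
  ok <- i > 1L & i < n & abs(den) > 1e-12
  d <- ifelse(ok, 0.5 * (y1 - y3) / den, 0)
  r0 + clip(d, -0.5, 0.5)
}

#' Extract features for the retained windows of one recording
#'
#' @param recording a filtered `vt_recording`.
#' @param windows retained, scored window rows for this recording
#'   (`lead_used` filled).
#' @param detections optional list (one entry per window row) of cached
#'   window-relative 0-based R samples from [score_windows()].
#' @return Data frame: keys, ground-truth window PVC fraction when available,
#'   then the 138 window features.
#' @export
extract_features <- function(recording, windows, detections = NULL) {
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    x <- recording$signal[(w$start_sample + 1L):w$end_sample, w$lead_used]
    fv <- window_features(x, recording$fs, detections[[i]])
    gt_pvc <- NA_real_
    ann <- recording$annotations
    if (!is.null(ann)) {
      inw <- ann$sample >= w$start_sample & ann$sample < w$end_sample
      if (any(inw)) gt_pvc <- mean(ann$label[inw] == "V")
    }
    rows[[i]] <- data.frame(patient_id = w$patient_id,
                            recording_id = w$recording_id,
                            window_index = w$window_index,
                            gt_pvc_fraction = gt_pvc,
                            t(fv), stringsAsFactors = FALSE,
                            check.names = FALSE)
  }
  do.call(rbind, rows)
}

#' Assemble the cohort-level window feature table
#'
#' One row per retained window: keys, class label, PI features broadcast
#' from the recording (sex/smoking encoded 0/1), 23 HRV and 115 MOR
#' features.  Missing values stay `NA` (imputation happens inside model
#' training, fitted on training folds only).  No feature column is derived
#' from the class label.
#'
#' @param feature_rows list (or rbind) of [extract_features()] outputs.
#' @param recordings_meta data frame `recording_id`, `class_label`, `age`,
#'   `sex`, `bmi`, `smoking`.
#' @return Data frame of class `vt_features`, deterministically ordered by
#'   (patient, recording, window).
#' @export
assemble_features <- function(feature_rows, recordings_meta) {
  ft <- if (is.data.frame(feature_rows)) feature_rows
        else do.call(rbind, feature_rows)
  key <- paste(ft$recording_id, ft$window_index)
  if (anyDuplicated(key)) vt_abort("duplicate (recording, window) keys")
  m <- match(ft$recording_id, recordings_meta$recording_id)
  if (anyNA(m)) vt_abort("recording metadata missing for some windows")
  ft$class_label <- recordings_meta$class_label[m]
  ft$age <- recordings_meta$age[m]
  ft$sex <- as.integer(recordings_meta$sex[m] == "M")
  ft$bmi <- recordings_meta$bmi[m]
  ft$smoking <- as.integer(as.logical(recordings_meta$smoking[m]))
  ft <- ft[order(ft$patient_id, ft$recording_id, ft$window_index), ]
  rownames(ft) <- NULL
  class(ft) <- c("vt_features", "data.frame")
  ft
}

#' Column view of a feature table for a model variant
#'
#' @param features a `vt_features` table.
#' @param variant one of `"PI"`, `"HRV"`, `"MOR"`, `"HRV+MOR"`,
#'   `"PI+HRV+MOR"`.
#' @return Character vector of feature column names in the variant.
#' @export
variant_columns <- function(features,
                            variant = c("HRV+MOR", "PI", "HRV", "MOR",
                                        "PI+HRV+MOR")) {
  variant <- match.arg(variant)
  fn <- feature_names()
  cols <- switch(variant,
    "PI" = fn$pi, "HRV" = fn$hrv, "MOR" = fn$mor,
    "HRV+MOR" = c(fn$hrv, fn$mor),
    "PI+HRV+MOR" = c(fn$pi, fn$hrv, fn$mor))
  intersect(cols, names(features))
}
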