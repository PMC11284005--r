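#' Beat-agreement signal quality index (bsqi)
#'
#' Agreement between two QRS detection lists on the same segment, scored as
#' the F1 of a one-to-one matching within a time tolerance: matched pairs are
#' true positives, detections left unmatched in `det_b` are false positives
#' and in `det_a` false negatives; `bsqi = 2 TP / (2 TP + FP + FN)`.  The
#' matching is the greedy earliest-first sweep over both sorted lists (match
#' when within tolerance, otherwise advance the earlier detection), which
#' attains the maximum matching cardinality for points on a line with a
#' uniform tolerance.  Two empty lists score 1 by convention.
#'
#' @param det_a,det_b sorted (ascending) sample indices from two detectors.
#' @param tol_ms matching tolerance, ms.
#' @param fs sampling frequency, Hz.
#' @param variant `"f1"` (default) or `"jaccard"` (`TP / (TP + FP + FN)`).
#' @return Score in `[0, 1]`.
#' @export
bsqi <- function(det_a, det_b, tol_ms = 150, fs, variant = c("f1", "jaccard")) {
  variant <- match.arg(variant)
  if (is.unsorted(det_a) || is.unsorted(det_b))
    vt_abort("detection lists must be sorted ascending")
  na <- length(det_a); nb <- length(det_b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  tol <- tol_ms / 1000 * fs
  tp <- 0L; i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    d <- det_a[i] - det_b[j]
    if (abs(d) <= tol) {
      tp <- tp + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  fp <- nb - tp; fn <- na - tp
  if (variant == "f1") 2 * tp / (2 * tp + fp + fn) else tp / (tp + fp + fn)
}

#' Score every window of a recording with bsqi
#'
#' Runs both QRS detectors on each lead of each window; the window's bsqi is
#' the best over leads, `lead_used` records which lead won, and
#' `quality_ok = bsqi > threshold`.  Windows shorter than 10 s score 0.
#' The winning lead's primary-detector R peaks are kept (attribute
#' `"detections"`, window-relative 0-based) for downstream beat analysis.
#'
#' @param windows a `vt_windows` table from [split_windows()].
#' @param recording the (filtered) `vt_recording` the windows came from.
#' @param tol_ms bsqi matching tolerance, ms.
#' @param threshold high-quality cut-off (strict `>`).
#' @return The windows table with `bsqi`, `lead_used`, `quality_ok` filled.
#' @export
score_windows <- function(windows, recording, tol_ms = 150, threshold = 0.8) {
  fs <- recording$fs
  dets <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    s0 <- windows$start_sample[i]; s1 <- windows$end_sample[i]
    if ((s1 - s0) / fs < 10) {
      windows$bsqi[i] <- 0; windows$quality_ok[i] <- FALSE
      next
    }
    best <- -1; best_lead <- 1L; best_det <- integer(0)
    for (ld in seq_len(ncol(recording$signal))) {
      x <- recording$signal[(s0 + 1L):s1, ld]
      da <- detect_qrs_primary(x, fs)
      db <- detect_qrs_secondary(x, fs)
      q <- bsqi(da, db, tol_ms, fs)
      if (q > best) { best <- q; best_lead <- ld; best_det <- da }
    }
    windows$bsqi[i] <- best
    windows$lead_used[i] <- best_lead
    windows$quality_ok[i] <- best > threshold
    dets[[i]] <- best_det
  }
  attr(windows, "detections") <- dets
  windows
}

#' Apply the window- and recording-level exclusion rules
#'
#' Drops windows whose bsqi is not strictly above the threshold, drops
#' windows overlapping annotated VT events in C1 recordings (the classifier
#' must only ever see sinus rhythm), and drops whole recordings with fewer
#' than `min_good_windows` high-quality windows.
#'
#' @param windows scored windows (possibly several recordings).
#' @param labels data frame `recording_id`, `class_label`.
#' @param threshold bsqi threshold (windows with bsqi exactly at the
#'   threshold are excluded).
#' @param min_good_windows minimum high-quality windows per recording.
#' @return List: `retained` (window rows kept), `report` (per-recording
#'   quality report) and `manifest` (cohort-level conservation counts).
#' @export
apply_exclusions <- function(windows, labels, threshold = 0.8,
                             min_good_windows = 6) {
  stopifnot(all(!is.na(windows$bsqi)))
  lab <- stats::setNames(labels$class_label, labels$recording_id)
  windows$hq <- windows$bsqi > threshold
  windows$vt_excl <- windows$hq & windows$contains_vt &
    lab[windows$recording_id] == "C1"

  rep_rows <- lapply(split(windows, windows$recording_id), function(w) {
    data.frame(recording_id = w$recording_id[1L],
               n_windows_total = nrow(w),
               n_windows_excluded_quality = sum(!w$hq),
               n_windows_excluded_vt = sum(w$vt_excl),
               n_high_quality = sum(w$hq),
               recording_excluded = sum(w$hq) < min_good_windows,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  excluded_recs <- report$recording_id[report$recording_excluded]

  in_excl_rec <- windows$recording_id %in% excluded_recs
  retained <- windows[!in_excl_rec & windows$hq & !windows$vt_excl, ]
  manifest <- list(
    windows_total = nrow(windows),
    windows_retained = nrow(retained),
    windows_excluded_quality = sum(!windows$hq & !in_excl_rec),
    windows_excluded_vt = sum(windows$vt_excl & !in_excl_rec),
    windows_in_excluded_recordings = sum(in_excl_rec),
    recordings_total = nrow(report),
    recordings_excluded = length(excluded_recs))
  retained$hq <- NULL; retained$vt_excl <- NULL
  list(retained = retained, report = report, manifest = manifest)
}
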