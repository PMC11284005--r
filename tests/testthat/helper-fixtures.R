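# Shared fixtures and independent oracles.  Fixtures are memoised within a
# test run so several test files can reuse the same simulated data.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# A baseline patient profile with explicit values for every field.
base_profile <- function(...) {
  p <- list(patient_id = "PX", class_label = "C0", age = 60, sex = "M",
            bmi = 26, smoking = FALSE, mean_hr = 70, rr_sd = 40,
            frag_coeff = 0.1, lf_amp = 20, hf_amp = 15, pvc_prob = 0,
            pvc_coupling = 0.6, r_amp = 1, pvc_width_factor = 2,
            noise_level = 0.02, n_bad_segments = 0L)
  utils::modifyList(p, list(...))
}

# Wrap a signal matrix as a minimal recording.
as_recording <- function(signal, fs, id = "R1", patient = "P1",
                         vt_events = list(), class_label = "C0") {
  structure(list(patient_id = patient, recording_id = id,
                 signal = as.matrix(signal), fs = fs,
                 class_label = class_label,
                 pi = list(age = 60, sex = "M", bmi = 26, smoking = FALSE),
                 vt_events = vt_events, annotations = NULL, gt = NULL),
            class = "vt_recording")
}

# Build a vt_rr object directly from a vector of intervals (ms).
rr_series <- function(x, valid = NULL, labels = NULL) {
  structure(list(intervals_ms = x,
                 valid = valid %||% (x >= 300 & x <= 2500),
                 labels = labels %||% rep("N", length(x)),
                 times_s = cumsum(x) / 1000),
            class = "vt_rr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A clean half-hour recording (5% PVCs) processed through filtering, with
# classified beats -- reused by beat-analysis and feature tests.
clean_beat_fixture <- function() memo("clean_beats", {
  p <- base_profile(pvc_prob = 0.05)
  gt <- generate_rr_series(p, 1 / 6, seed = 42)
  ecg <- synthesize_ecg(gt, p, 128, seed = 43)
  rec <- as_recording(ecg$signal, 128)
  rec <- suppressWarnings(apply_filters(rec, filter_spec()))
  x <- rec$signal[, 1]
  det <- detect_qrs_primary(x, 128)
  beats <- classify_beats(delineate(x, 128, det), x, 128)
  list(profile = p, gt = gt, ann = ecg$annotations, x = x, fs = 128,
       det = det, beats = beats)
})

# Match detections/beats to ground-truth annotations (sample tolerance).
match_ann <- function(beat_samples, ann_samples, tol = 10) {
  vapply(ann_samples, function(s) {
    i <- which.min(abs(beat_samples - s))
    if (abs(beat_samples[i] - s) <= tol) i else NA_integer_
  }, integer(1))
}

# --- independent oracles -------------------------------------------------

# Maximum-cardinality one-to-one matching of two sorted detection lists
# within a tolerance, by O(n m) dynamic programming (LCS-style).
oracle_max_matching <- function(a, b, tol) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  dp <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      best <- max(dp[i, j + 1L], dp[i + 1L, j])
      if (abs(a[i] - b[j]) <= tol) best <- max(best, dp[i, j] + 1L)
      dp[i + 1L, j + 1L] <- best
    }
  }
  dp[na + 1L, nb + 1L]
}

oracle_bsqi <- function(a, b, tol) {
  if (!length(a) && !length(b)) return(1)
  if (!length(a) || !length(b)) return(0)
  tp <- oracle_max_matching(a, b, tol)
  2 * tp / (2 * tp + (length(b) - tp) + (length(a) - tp))
}

# Brute-force AUROC: pairwise positive-vs-negative comparisons, ties = 1/2.
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# A synthetic window-level feature table with a known informative structure
# (no ECG needed): Vratio and PIP carry class signal, PI fields do not.
make_feature_table <- function(n_c0 = 30, n_c1 = 10, windows = 4, seed = 1) {
  set.seed(seed)
  n <- n_c0 + n_c1
  fn <- feature_names()
  rows <- list()
  for (i in seq_len(n)) {
    cl <- if (i <= n_c0) "C0" else "C1"
    pvc <- if (cl == "C0") abs(rnorm(1, 0.005, 0.003)) else abs(rnorm(1, 0.06, 0.02))
    frag <- if (cl == "C0") rnorm(1, 0.55, 0.04) else rnorm(1, 0.68, 0.04)
    for (w in seq_len(windows)) {
      v <- stats::setNames(rnorm(length(fn$hrv) + length(fn$mor)),
                           c(fn$hrv, fn$mor))
      v["Vratio"] <- max(0, pvc + rnorm(1, 0, 0.004))
      v["PIP"] <- clip_num(frag + rnorm(1, 0, 0.02), 0, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%03d", i),
        recording_id = sprintf("P%03d_R01", i),
        window_index = w - 1L, gt_pvc_fraction = pvc,
        class_label = cl, age = rnorm(1, 65, 10),
        sex = rbinom(1, 1, 0.5), bmi = rnorm(1, 27, 4),
        smoking = rbinom(1, 1, 0.25),
        t(v), stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vt_features", "data.frame")
  out
}

clip_num <- function(x, lo, hi) pmin(pmax(x, lo), hi)
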