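# Beat morphology: five Gaussian bumps per beat.  Offsets/widths in ms
# relative to the R peak, amplitudes as fractions of the profile's R
# amplitude.  The QRS complex (Q, R, S) spans about 80 ms between its outer
# 3-sigma bounds for a normal beat; ventricular beats are rendered without a
# P wave, with QRS widths multiplied by pvc_width_factor (> 120 ms wide at
# defaults) and with inverted S/T polarity.
wave_table <- function(r_amp, ventricular = FALSE, width_factor = 1) {
  w <- data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    mu    = c(-180, -25, 0, 25, 280),
    sigma = c(25, 5, 11, 5, 55),
    amp   = c(0.12, -0.12, 1.00, -0.18, 0.28) * r_amp,
    stringsAsFactors = FALSE)
  if (ventricular) {
    w <- w[w$wave != "P", ]
    qrs <- w$wave %in% c("Q", "R", "S")
    w$sigma[qrs] <- w$sigma[qrs] * width_factor
    w$mu[qrs] <- w$mu[qrs] * width_factor
    w$amp[w$wave == "S"] <- 1.1 * r_amp    # tall inverted, dominant S
    w$amp[w$wave == "T"] <- -w$amp[w$wave == "T"]
    w$amp[w$wave == "R"] <- 0.7 * w$amp[w$wave == "R"]
    w$amp[w$wave == "Q"] <- -0.05 * r_amp
  }
  w
}

# QRS span (ms) between outer 3-sigma bounds of the rendered Q and S bumps.
rendered_qrs_span <- function(width_factor = 1) {
  w <- wave_table(1, ventricular = width_factor > 1, width_factor = width_factor)
  q <- w[w$wave == "Q", ]; s <- w[w$wave == "S", ]
  (s$mu + 3 * s$sigma) - (q$mu - 3 * q$sigma)
}

#' Render a synthetic ECG from a ground-truth beat series
#'
#' Each beat is drawn as a sum of Gaussian bumps (P, Q, R, S, T for normal
#' beats; no P, widened QRS and inverted S/T for ventricular beats).  Additive
#' noise comprises a 0.25 Hz baseline wander, white noise at the profile's
#' `noise_level` (mV RMS) and a 50 Hz power-line sinusoid; `n_bad_segments`
#' episodes of 20-fold amplified white noise are inserted at random positions
#' to emulate poor-contact stretches.  Leads are gain-scaled copies of one
#' source waveform with independent noise realisations.
#'
#' @param gt a `vt_ground_truth` from [generate_rr_series()].
#' @param profile the matching patient profile row.
#' @param fs sampling frequency, Hz (>= 100).
#' @param n_leads number of leads.
#' @param lead_gains per-lead multiplicative gains.
#' @param seed integer seed for the noise.
#' @param bad_segment_s duration of each injected low-quality episode, s.
#' @return List with `signal` (samples x leads matrix, mV), `fs`,
#'   `annotations` (data frame `sample` 0-based, `label`), `bad_segments`
#'   (list of 0-based sample intervals).
#' @export
synthesize_ecg <- function(gt, profile, fs, n_leads = 3,
                           lead_gains = c(1, 0.7, 0.5), seed = 1L,
                           bad_segment_s = 120) {
  if (fs < 100) vt_abort("fs too low to render QRS complexes (need >= 100 Hz)")
  profile <- as.list(profile)
  n_samp <- round(gt$duration_s * fs)
  with_seed(seed, {
    clean <- numeric(n_samp)
    r_samp0 <- round(gt$beat_times_s * fs)   # 0-based R-peak samples
    keep <- r_samp0 >= 0 & r_samp0 < n_samp
    r_samp0 <- r_samp0[keep]
    labs <- gt$beat_labels[keep]

    wf <- profile$pvc_width_factor
    wn <- wave_table(profile$r_amp, FALSE)
    wv <- wave_table(profile$r_amp, TRUE, wf)
    for (b in seq_along(r_samp0)) {
      w <- if (labs[b] == "V") wv else wn
      for (k in seq_len(nrow(w))) {
        mu_s <- r_samp0[b] + w$mu[k] * fs / 1000
        sd_s <- w$sigma[k] * fs / 1000
        lo <- max(0L, floor(mu_s - 4 * sd_s))
        hi <- min(n_samp - 1L, ceiling(mu_s + 4 * sd_s))
        if (hi < lo) next
        idx <- lo:hi
        clean[idx + 1L] <- clean[idx + 1L] +
          w$amp[k] * exp(-((idx - mu_s)^2) / (2 * sd_s^2))
      }
    }

    # annotate ventricular beats at their dominant rendered deflection (the
    # tall inverted S), which is what any R-peak detector will lock onto
    ann_samp <- r_samp0
    if (any(labs == "V")) {
      s_mu <- wv$mu[wv$wave == "S"]
      ann_samp[labs == "V"] <- pmin(r_samp0[labs == "V"] +
                                      round(s_mu * fs / 1000), n_samp - 1L)
    }

    t <- (seq_len(n_samp) - 1L) / fs
    noise_gain <- rep(1, n_samp)
    bad <- list()
    nb <- profile$n_bad_segments
    if (nb > 0) {
      len <- round(bad_segment_s * fs)
      for (i in seq_len(nb)) {
        start <- sample.int(max(n_samp - len, 1L), 1L) - 1L
        end <- min(start + len, n_samp)
        noise_gain[(start + 1L):end] <- 20
        bad[[length(bad) + 1L]] <- c(start, end)
      }
    }
    sig <- matrix(0, n_samp, n_leads)
    for (ld in seq_len(n_leads)) {
      wander <- 0.08 * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))
      mains <- 0.015 * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
      white <- stats::rnorm(n_samp, 0, profile$noise_level) * noise_gain
      sig[, ld] <- lead_gains[ld] * clean + wander + mains + white
    }
    list(signal = sig, fs = fs,
         annotations = data.frame(sample = ann_samp, label = labs,
                                  stringsAsFactors = FALSE),
         bad_segments = bad)
  })
}

#' Inject ventricular tachycardia runs into a recording
#'
#' Replaces stretches of sinus beats with runs of `run_length_beats`
#' consecutive ventricular beats at `run_rate_bpm` (> 100 b.p.m., the VT
#' definition: at least three consecutive ventricular complexes above
#' 100 b.p.m.), keeping the total duration fixed, then re-renders the ECG.
#'
#' @param recording a `vt_recording` (see [simulate_recording()]).
#' @param gt its `vt_ground_truth`.
#' @param n_runs number of runs to insert (0 = no change).
#' @param run_length_beats beats per run (>= 3).
#' @param run_rate_bpm instantaneous rate inside the run (> 100).
#' @param seed integer seed for run placement.
#' @return List `recording`, `gt` with `vt_runs` filled (0-based sample
#'   intervals) and labels updated.
#' @export
inject_vt_runs <- function(recording, gt, n_runs, run_length_beats = 5,
                           run_rate_bpm = 150, seed = 1L) {
  if (n_runs == 0) return(list(recording = recording, gt = gt))
  if (run_length_beats < 3) vt_abort("a VT run needs >= 3 beats")
  if (run_rate_bpm <= 100) vt_abort("VT run rate must exceed 100 b.p.m.")
  run_rr <- 60000 / run_rate_bpm
  run_ms <- run_length_beats * run_rr
  if (run_ms >= gt$duration_s * 1000) vt_abort("run longer than recording")

  with_seed(seed, {
    rr <- gt$rr_ms; lab <- gt$beat_labels
    n <- length(rr)
    starts <- sort(sample(seq(10L, n - 2L * run_length_beats - 10L),
                          n_runs))
    if (any(diff(starts) < 3L * run_length_beats))
      starts <- seq(10L, by = 3L * run_length_beats + 10L,
                    length.out = n_runs)
    for (s in rev(starts)) {
      # replace sinus intervals covering ~run_ms with the run
      removed <- 0; j <- s
      while (removed < run_ms && j <= length(rr)) {
        removed <- removed + rr[j]; j <- j + 1L
      }
      filler <- max(removed - run_ms, 0)
      new_rr <- rep(run_rr, run_length_beats)
      new_lab <- rep("V", run_length_beats)
      if (filler >= 300) {
        new_rr <- c(new_rr, filler); new_lab <- c(new_lab, "N")
      } else if (filler > 0 && length(rr) >= j) {
        rr[j] <- rr[j] + filler
      }
      rr <- c(rr[seq_len(s - 1L)], new_rr, rr[seq(j, length(rr))])
      lab <- c(lab[seq_len(s - 1L)], new_lab, lab[seq(j, length(lab))])
    }
    bt <- cumsum(rr) / 1000
    gt$rr_ms <- rr
    gt$beat_labels <- lab
    gt$beat_times_s <- bt
    gt$realized_pvc_fraction <- mean(lab == "V")
    gt$vt_runs <- vt_runs_from_labels(bt, lab, rr, recording$fs)
    rec2 <- synthesize_ecg(gt, recording$profile, recording$fs,
                           n_leads = ncol(recording$signal),
                           seed = derive_seed(seed, "revt"))
    recording$signal <- rec2$signal
    recording$annotations <- rec2$annotations
    recording$vt_events <- gt$vt_runs
    list(recording = recording, gt = gt)
  })
}

# Locate runs of >= 3 consecutive V beats at instantaneous rate > 100 b.p.m.
vt_runs_from_labels <- function(beat_times_s, labels, rr_ms, fs) {
  fast_v <- labels == "V" & rr_ms < 600
  runs <- rle(fast_v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values & runs$lengths >= 3L)) {
    i0 <- starts[k]; i1 <- ends[k]
    out[[length(out) + 1L]] <- c(
      floor((beat_times_s[i0] - rr_ms[i0] / 1000) * fs),
      ceiling(beat_times_s[i1] * fs))
  }
  out
}

#' Simulate one complete recording for a patient profile
#'
#' Chains [generate_rr_series()], optional [inject_vt_runs()] and
#' [synthesize_ecg()] into a `vt_recording`.
#'
#' @param profile one profile row.
#' @param duration_hr,fs recording geometry.
#' @param seed integer seed.
#' @param recording_id identifier string.
#' @param n_vt_runs VT runs to inject (C1 fixtures).
#' @return A `vt_recording`: list with `patient_id`, `recording_id`, `signal`
#'   (samples x leads, mV), `fs`, `class_label`, `pi`, `vt_events`,
#'   `annotations`, `profile` and `gt`.
#' @export
simulate_recording <- function(profile, duration_hr, fs, seed = 1L,
                               recording_id = NULL, n_vt_runs = 0) {
  profile <- as.list(profile)
  if (is.null(recording_id)) recording_id <- paste0(profile$patient_id, "_R01")
  gt <- generate_rr_series(profile, duration_hr, derive_seed(seed, "rr"))
  ecg <- synthesize_ecg(gt, profile, fs, seed = derive_seed(seed, "ecg"))
  rec <- structure(list(
    patient_id = profile$patient_id, recording_id = recording_id,
    signal = ecg$signal, fs = fs, class_label = profile$class_label,
    pi = list(age = profile$age, sex = profile$sex, bmi = profile$bmi,
              smoking = profile$smoking),
    vt_events = list(), annotations = ecg$annotations,
    bad_segments = ecg$bad_segments,
    profile = profile, gt = gt), class = "vt_recording")
  if (n_vt_runs > 0) {
    res <- inject_vt_runs(rec, gt, n_vt_runs, seed = derive_seed(seed, "vt"))
    rec <- res$recording; rec$gt <- res$gt
  }
  rec
}

#' Simulate a labelled synthetic Holter cohort
#'
#' Draws profiles with [sample_cohort()] and renders every recording.  C1
#' recordings receive injected VT runs with probability `spec$vt_run_prob`
#' (these segments are what the downstream window-exclusion rule removes, so
#' that classification only ever sees sinus-rhythm windows).
#'
#' @param spec a [cohort_spec()].
#' @param progress print a dot per recording.
#' @return A `vt_cohort`: list with `profiles` and `recordings`.
#' @export
simulate_cohort <- function(spec, progress = FALSE) {
  profiles <- sample_cohort(spec)
  recs <- list()
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    for (r in seq_len(spec$recordings_per_patient)) {
      rid <- sprintf("%s_R%02d", prof$patient_id, r)
      rseed <- derive_seed(spec$seed, rid)
      nvt <- 0L
      if (prof$class_label == "C1") {
        nvt <- with_seed(derive_seed(rseed, "nvt"),
                         stats::rbinom(1L, 2L, spec$vt_run_prob))
      }
      recs[[rid]] <- simulate_recording(prof, spec$duration_hr, spec$fs,
                                        seed = rseed, recording_id = rid,
                                        n_vt_runs = nvt)
      if (progress) cat(".")
    }
  }
  if (progress) cat("\n")
  structure(list(spec = spec, profiles = profiles, recordings = recs),
            class = "vt_cohort")
}

#' @export
print.vt_cohort <- function(x, ...) {
  cat("Synthetic Holter cohort:", nrow(x$profiles), "patients (",
      sum(x$profiles$class_label == "C0"), "C0 /",
      sum(x$profiles$class_label == "C1"), "C1 ),",
      length(x$recordings), "recordings of",
      x$spec$duration_hr, "h at", x$spec$fs, "Hz\n")
  invisible(x)
}

#' @export
print.vt_recording <- function(x, ...) {
  cat(sprintf("ECG recording %s (patient %s, %s): %d leads x %d samples @ %g Hz, %d beats (%.1f%% V)\n",
              x$recording_id, x$patient_id, x$class_label, ncol(x$signal),
              nrow(x$signal), x$fs, nrow(x$annotations),
              100 * mean(x$annotations$label == "V")))
  invisible(x)
}
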