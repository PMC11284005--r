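# Two algorithmically independent QRS detectors.  Both return 0-based sample
# indices of R peaks, strictly increasing, with a 250 ms refractory period.

REFRACTORY_S <- 0.25

pick_peaks <- function(idx, val, min_dist)
  pick_peaks_cpp(as.integer(idx), as.numeric(val), as.integer(min_dist))

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] >= x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
}

# Refine a detection to the largest absolute excursion of the analysed
# signal within +/- `half_ms` of the candidate.
refine_r <- function(x, cand, fs, half_ms = 75)
  refine_r_cpp(x, as.integer(cand), as.integer(round(half_ms / 1000 * fs)))

#' Energy-based QRS detector (Pan--Tompkins family)
#'
#' Band-pass 5--15 Hz, differentiate, square, moving-window integrate
#' (150 ms), then adaptive signal/noise threshold tracking with a 250 ms
#' refractory period.  Thresholds adapt to the running peak amplitudes, so
#' detections are invariant to rescaling the input.
#'
#' @param x single-lead signal, mV.
#' @param fs sampling frequency, Hz.
#' @return 0-based R-peak sample indices (strictly increasing).
#' @export
detect_qrs_primary <- function(x, fs) {
  if (length(x) < 2 * fs) vt_abort("need at least 2 s of signal")
  if (max(abs(x)) == 0) return(integer(0))
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- filtfilt_cpp(bp$b, bp$a, x)
  if (all(!is.finite(xf)) || max(abs(xf)) == 0) return(integer(0))
  en <- c(0, diff(xf))^2
  w <- max(3L, round(0.15 * fs))
  mwi <- rollmean_cpp(en, w)
  cand <- local_maxima(mwi)
  if (!length(cand)) return(integer(0))
  refr <- round(REFRACTORY_S * fs)
  cand <- pick_peaks(cand, mwi[cand], round(0.2 * fs))

  head_n <- min(length(mwi), round(2 * fs))
  spki <- max(mwi[seq_len(head_n)]); npki <- mean(mwi[seq_len(head_n)])
  if (spki <= 0) return(integer(0))
  aa <- adaptive_accept_cpp(as.integer(cand), mwi, spki, npki, refr)
  acc <- aa$accepted
  thr_at <- aa$thr_at
  if (!length(acc)) return(integer(0))
  # search-back: re-examine long gaps at half threshold (catches beats with
  # low slope energy, e.g. wide ventricular complexes)
  if (length(acc) > 3L) {
    med_rr <- stats::median(diff(acc))
    repeat {
      gaps <- which(diff(acc) > 1.66 * med_rr)
      added <- FALSE
      for (g in gaps) {
        lo <- acc[g] + refr; hi <- acc[g + 1L] - refr
        k <- which(cand > lo & cand < hi & mwi[cand] > 0.5 * thr_at)
        if (length(k)) {
          best <- cand[k[which.max(mwi[cand[k]])]]
          acc <- sort(c(acc, best)); added <- TRUE
        }
      }
      if (!added) break
    }
  }
  r <- refine_r(xf, acc, fs)
  sort(unique(r)) - 1L
}

#' Curve-length QRS detector
#'
#' Length transform of the robustly normalised signal (rolling sum of chord
#' lengths over a 130 ms window, baseline-subtracted), thresholded per 10 s
#' block at a fixed fraction of the block's upper length quantile; 250 ms
#' refractory.  Shares no filtering or threshold logic with
#' [detect_qrs_primary()].
#'
#' @inheritParams detect_qrs_primary
#' @return 0-based R-peak sample indices.
#' @export
detect_qrs_secondary <- function(x, fs) {
  if (length(x) < 2 * fs) vt_abort("need at least 2 s of signal")
  s <- stats::mad(x)
  if (s == 0) return(integer(0))
  z <- (x - stats::median(x)) / s
  cc <- 0.2  # chord constant, normalised units: suppresses baseline jitter
  chord <- sqrt(cc^2 + diff(z)^2) - cc
  w <- max(3L, round(0.13 * fs))
  L <- rollmean_cpp(c(0, chord), w) * w

  n <- length(L)
  block <- round(10 * fs)
  thr <- numeric(n)
  for (b0 in seq(1L, n, by = block)) {
    b1 <- min(b0 + block - 1L, n)
    thr[b0:b1] <- 0.5 * stats::quantile(L[b0:b1], 0.98, names = FALSE)
  }
  cand <- local_maxima(L)
  cand <- cand[L[cand] > thr[cand]]
  if (!length(cand)) return(integer(0))
  cand <- pick_peaks(cand, L[cand], round(REFRACTORY_S * fs))
  r <- refine_r(z, cand, fs)
  sort(unique(r)) - 1L
}
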