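# Rule-based five-class beat classifier.  The published clustering-based
# classifier is replaced by a deterministic rule set over three quantities
# available per beat: QRS duration, prematurity (previous RR over the local
# median of recent normal RRs) and correlation with a running template of
# the dominant QRS morphology.

# Extract fixed-length, zero-mean, unit-energy QRS segments centred on R.
beat_segments <- function(x, fs, r_samples) {
  half <- round(0.125 * fs)
  n <- length(x)
  t(vapply(r_samples + 1L, function(r) {
    lo <- r - half; hi <- r + half
    if (lo < 1L || hi > n) return(rep(NA_real_, 2L * half + 1L))
    seg <- x[lo:hi] - mean(x[lo:hi])
    e <- sqrt(sum(seg^2))
    if (e == 0) rep(0, length(seg)) else seg / e
  }, numeric(2L * half + 1L)))
}

#' Classify beats as N, S, V, F or none
#'
#' Labels are assigned by fixed rules: `none` when fiducials are absent;
#' `V` (ventricular) when the QRS is wide (> 120 ms), premature
#' (prematurity < 0.90) and morphologically unlike the running template
#' (correlation < 0.8); `S` (supraventricular) when premature with a narrow
#' QRS; `F` (fusion) when wide with intermediate template correlation
#' (0.8--0.95); otherwise `N`.  The running template is an exponentially
#' weighted mean (alpha = 0.05) of beats correlating > 0.9 with it,
#' initialised from the medoid of the first ten beats; the local RR
#' reference is the median over the eight preceding N-labelled beats.
#'
#' @param delin output of [delineate()].
#' @param x the window's analysed-lead signal, mV.
#' @param fs sampling frequency, Hz.
#' @param wide_ms QRS-width threshold, ms.
#' @param premature prematurity threshold.
#' @param corr_v,corr_f template-correlation thresholds for V and F.
#' @return `delin` with columns `template_corr`, `prematurity`, `label`.
#' @export
classify_beats <- function(delin, x, fs, wide_ms = 120, premature = 0.90,
                           corr_v = 0.8, corr_f = 0.95) {
  nb <- nrow(delin)
  tc <- prem_v <- rep(NA_real_, nb)
  lab_v <- rep("none", nb)
  finish <- function() {
    delin$template_corr <- tc
    delin$prematurity <- prem_v
    delin$label <- lab_v
    delin
  }
  if (nb < 2L) return(finish())

  segs <- beat_segments(x, fs, delin$r_sample)
  ok_seg <- stats::complete.cases(segs)
  rr <- c(NA_real_, diff(delin$r_sample)) / fs * 1000

  # template initialisation: medoid of the first 10 usable beats
  first <- which(ok_seg)[seq_len(min(10L, sum(ok_seg)))]
  if (length(first) < 2L) return(finish())
  cm <- stats::cor(t(segs[first, , drop = FALSE]))
  template <- segs[first[which.max(rowMeans(cm))], ]
  template <- template / sqrt(sum(template^2))

  recent_nn <- rr[!is.na(rr)]
  recent_nn <- recent_nn[seq_len(min(10L, length(recent_nn)))]
  med_q <- function(v) {
    s <- sort.int(v); m <- length(s)
    if (m %% 2L) s[(m + 1L) %/% 2L] else (s[m %/% 2L] + s[m %/% 2L + 1L]) / 2
  }
  alpha <- 0.05
  for (b in seq_len(nb)) {
    has_fid <- !is.na(delin$qrs_on[b]) && !is.na(delin$qrs_off[b]) &&
      isTRUE(delin$ctx_ok[b])
    corr <- if (ok_seg[b]) sum(segs[b, ] * template) else NA_real_
    prem <- if (!is.na(rr[b]) && length(recent_nn))
      rr[b] / med_q(recent_nn) else NA_real_
    tc[b] <- corr
    prem_v[b] <- prem

    lab <- if (!has_fid || is.na(corr)) {
      "none"
    } else {
      dur <- delin$qrs_dur_ms[b]
      prem_ok <- !is.na(prem) && prem < premature
      if (dur > wide_ms && prem_ok && corr < corr_v) "V"
      else if (prem_ok && dur <= wide_ms) "S"
      else if (dur > wide_ms && corr >= corr_v && corr < corr_f) "F"
      else "N"
    }
    lab_v[b] <- lab

    if (lab == "N" && !is.na(rr[b])) {
      recent_nn <- c(recent_nn, rr[b])
      if (length(recent_nn) > 8L) recent_nn <- recent_nn[-1L]
    }
    if (!is.na(corr) && corr > 0.9) {
      template <- (1 - alpha) * template + alpha * segs[b, ]
      template <- template / sqrt(sum(template^2))
    }
  }
  finish()
}
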