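#' Delineate fiducial points around detected R peaks
#'
#' For each R peak: QRS onset/offset by a sustained slope-threshold search
#' (first point, moving outward from R, where the absolute derivative stays
#' below 5% of the local peak slope) within +/-100 ms of R; Q and S troughs
#' as the minima between onset/offset and R; the T end by the tangent method
#' (steepest post-peak slope extrapolated to the isoelectric level) in the
#' 80--400 ms window after QRS offset; the P wave as the largest positive
#' interior bump in the 200 ms before QRS onset, declared absent when below
#' the local noise floor.  The isoelectric level is the median of the short
#' segment just before QRS onset.  Beats within 150 ms of a window edge get
#' no fiducials (they will be labelled `none`).
#'
#' @param x single-lead filtered signal for one window, mV.
#' @param fs sampling frequency, Hz.
#' @param r_samples 0-based R-peak sample indices within the window.
#' @return Data frame, one row per beat: 0-based fiducials (`NA` when
#'   absent), `qrs_dur_ms`, `iso` (mV).
#' @export
delineate <- function(x, fs, r_samples) {
  n <- length(x)
  # slope from a lightly smoothed copy (~12 ms moving average): residual
  # high-frequency noise otherwise dominates the small-slope search
  smw <- max(3L, round(0.012 * fs))
  xs <- rollmean_cpp(x, smw)
  d <- c(0, diff(xs)) * fs  # mV/s
  # window-wide baseline slope noise: QRS complexes occupy a minority of
  # the samples, so the median absolute slope tracks the noise floor
  slope_noise <- stats::median(abs(d))
  # amplitude noise: residual of the light smoothing
  amp_noise <- stats::median(abs(x - xs))
  # median without S3 dispatch, for the many tiny segments below
  med_q <- function(v) {
    s <- sort.int(v); m <- length(s)
    if (m %% 2L) s[(m + 1L) %/% 2L] else (s[m %/% 2L] + s[m %/% 2L + 1L]) / 2
  }
  ms <- function(k) max(1L, round(k / 1000 * fs))
  w100 <- ms(100); w150 <- ms(150); w200 <- ms(200)
  # the quiet run must outlast the slope dip at a slow (wide-QRS) apex,
  # which can stay below threshold for ~15 ms; true iso-electric segments
  # are quiet for > 50 ms
  sus <- max(3L, round(0.025 * fs))

  nb <- length(r_samples)
  p_on <- p_peak <- p_off <- qrs_on <- q_peak <- s_peak <- qrs_off <-
    t_peak <- t_off <- rep(NA_integer_, nb)
  qrs_dur_ms <- iso_v <- rep(NA_real_, nb)
  ctx_ok <- rep(FALSE, nb)

  for (b in seq_len(nb)) {
    r <- r_samples[b] + 1L  # 1-based
    if (r - w150 < 1L || r + w150 > n) next

    lo <- max(1L, r - w100); hi <- min(n, r + w100)
    ad <- abs(d[lo:hi])
    # 5% of the local peak slope, floored at the baseline slope noise;
    # the floor is capped relative to the beat so low-amplitude beats in
    # heavy noise degrade to edge-clamped (wide) bounds rather than to
    # spurious apex-dip boundaries
    thr <- max(0.05 * max(ad), min(2.5 * slope_noise, 0.2 * max(ad)))
    below <- ad < thr
    idx <- seq_along(below)
    run <- idx - cummax(idx * !below)   # consecutive below-thr run ending here
    rrel <- r - lo + 1L
    # onset: rightmost pre-R position ending a sustained quiet run
    cand <- which(run >= sus)
    onc <- cand[cand < rrel - 2L]
    on_found <- length(onc) > 0L
    q_on <- if (on_found) lo + max(onc) - 1L else lo
    # offset: leftmost post-R position where a sustained quiet run completes;
    # the run of length `sus` ending at k starts at k - sus + 1
    offc <- cand[cand - sus + 1L > rrel + 2L]
    off_found <- length(offc) > 0L
    q_off <- if (off_found) lo + (min(offc) - sus + 1L) - 1L else hi

    iso_lo <- max(1L, q_on - ms(35)); iso_hi <- max(1L, q_on - ms(5))
    iso <- med_q(x[iso_lo:iso_hi])

    qp <- if (q_on < r) q_on + which.min(x[q_on:r]) - 1L else NA_integer_
    sp <- if (q_off > r) r + which.min(x[r:q_off]) - 1L else NA_integer_

    # T wave: tangent method
    tp <- toff <- NA_integer_
    t0 <- q_off + ms(80); t1 <- min(n, q_off + ms(400))
    if (t1 > t0 + ms(40)) {
      seg <- x[t0:t1] - iso
      tpk <- t0 + which.max(abs(seg)) - 1L
      if (tpk < t1 - 2L) {
        m <- tpk + which.max(abs(d[tpk:t1])) - 1L  # steepest return to baseline
        sl <- d[m]
        if (abs(sl) > 1e-9) {
          cross <- m + round((x[m] - iso) / -sl * fs)
          toff <- as.integer(clip(cross, tpk, t1))
          tp <- tpk
        }
      }
    }

    # P wave: largest positive interior local maximum before QRS onset.
    # The search never reaches into the previous beat's T wave (350 ms
    # post previous R), so premature beats do not pick up a spurious P.
    pon <- ppk <- poff <- NA_integer_
    p0 <- max(1L, q_on - w200)
    if (b > 1L) p0 <- max(p0, r_samples[b - 1L] + 1L + ms(350))
    p1 <- max(1L, q_on - ms(10))
    if (p1 > p0 + 4L) {
      seg <- x[p0:p1] - iso
      lm <- local_maxima(seg)
      lm <- lm[lm > 2L & lm < length(seg) - 1L]
      if (length(lm)) {
        pk <- lm[which.max(seg[lm])]
        amp <- seg[pk]
        noise_floor <- max(0.04, 5 * amp_noise)
        if (amp > noise_floor) {
          ppk <- p0 + pk - 1L
          lowamp <- which(seg < 0.1 * amp)
          onl <- lowamp[lowamp < pk]; offl <- lowamp[lowamp > pk]
          pon <- p0 + (if (length(onl)) max(onl) else 1L) - 1L
          poff <- p0 + (if (length(offl)) min(offl) else length(seg)) - 1L
        }
      }
    }

    qrs_on[b] <- q_on - 1L; qrs_off[b] <- q_off - 1L
    q_peak[b] <- qp - 1L; s_peak[b] <- sp - 1L
    t_peak[b] <- tp - 1L; t_off[b] <- toff - 1L
    p_on[b] <- pon - 1L; p_peak[b] <- ppk - 1L; p_off[b] <- poff - 1L
    qrs_dur_ms[b] <- (q_off - q_on) / fs * 1000
    iso_v[b] <- iso
    # a beat with no detectable iso-electric neighbourhood on either side
    # sits in locally unusable signal (e.g. a noise burst)
    ctx_ok[b] <- on_found || off_found
  }
  data.frame(r_sample = r_samples, p_on = p_on, p_peak = p_peak,
             p_off = p_off, qrs_on = qrs_on, q_peak = q_peak,
             s_peak = s_peak, qrs_off = qrs_off, t_peak = t_peak,
             t_off = t_off, qrs_dur_ms = qrs_dur_ms, iso = iso_v,
             ctx_ok = ctx_ok)
}
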