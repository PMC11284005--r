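#' Build an RR interval series from beat annotations
#'
#' Intervals are successive R-peak differences; a range filter marks
#' intervals outside 300--2500 ms invalid (they are excluded from every HRV
#' statistic but keep their place in the series).  Each interval carries the
#' label of its terminating beat.
#'
#' @param annotations data frame with `r_sample` (0-based) and optionally
#'   `label`.
#' @param fs sampling frequency, Hz.
#' @return An `vt_rr` list: `intervals_ms`, `valid`, `labels`, `times_s`
#'   (time of the terminating beat).
#' @export
compute_rr <- function(annotations, fs) {
  r <- annotations$r_sample
  if (length(r) < 2L)
    return(structure(list(intervals_ms = numeric(0), valid = logical(0),
                          labels = character(0), times_s = numeric(0)),
                     class = "vt_rr"))
  x <- diff(r) / fs * 1000
  lab <- if (!is.null(annotations$label)) annotations$label[-1L]
         else rep(NA_character_, length(x))
  structure(list(intervals_ms = x, valid = x >= 300 & x <= 2500,
                 labels = lab, times_s = r[-1L] / fs),
            class = "vt_rr")
}

# Successive differences over adjacent valid pairs.
valid_diffs <- function(rr) {
  x <- rr$intervals_ms; v <- rr$valid
  i <- which(v[-length(v)] & v[-1L])
  x[i + 1L] - x[i]
}

na_set <- function(nms) stats::setNames(rep(NA_real_, length(nms)), nms)

#' Time-domain HRV features
#'
#' @param rr a `vt_rr` series.
#' @return Named vector: `AVNN`, `SDNN`, `RMSSD`, `pNN20`, `pNN50`, `SEM`
#'   (all from valid intervals; `NA` with fewer than 10).
#' @export
hrv_time <- function(rr) {
  nms <- c("AVNN", "SDNN", "RMSSD", "pNN20", "pNN50", "SEM")
  x <- rr$intervals_ms[rr$valid]
  if (length(x) < 10L) return(na_set(nms))
  d <- valid_diffs(rr)
  sdnn <- stats::sd(x)
  c(AVNN = mean(x), SDNN = sdnn,
    RMSSD = if (length(d)) sqrt(mean(d^2)) else NA_real_,
    pNN20 = if (length(d)) mean(abs(d) > 20) else NA_real_,
    pNN50 = if (length(d)) mean(abs(d) > 50) else NA_real_,
    SEM = sdnn / sqrt(length(x)))
}

#' Heart-rate-fragmentation features
#'
#' Counts sign reversals and alternation runs in the increment series
#' `dNN_i = NN_{i+1} - NN_i` (a zero increment is treated as a sign change):
#' `PIP` is the fraction of intervals that are inflection points; `IALS` the
#' inverse mean length of acceleration/deceleration segments (maximal runs
#' of constant nonzero increment sign); `PSS` the fraction of increments in
#' segments shorter than 3; `PAS` the fraction of increments in strictly
#' alternating stretches of length at least 4.
#'
#' @param rr a `vt_rr` series.
#' @return Named vector `PIP`, `IALS`, `PSS`, `PAS` (fractions in `[0, 1]`).
#' @export
hrv_fragmentation <- function(rr) {
  nms <- c("PIP", "IALS", "PSS", "PAS")
  x <- rr$intervals_ms[rr$valid]
  n <- length(x)
  if (n < 10L) return(na_set(nms))
  s <- sign(diff(x))
  m <- length(s)

  change <- s[-1L] != s[-m] | s[-1L] == 0 | s[-m] == 0
  pip <- sum(change) / n

  nz <- s != 0
  runs <- rle(ifelse(nz, s, 0))
  seg_len <- runs$lengths[runs$values != 0]
  ials <- if (length(seg_len)) 1 / mean(seg_len) else 0
  pss <- if (length(seg_len)) sum(seg_len[seg_len < 3L]) / m else 0

  alt_break <- s[-1L] != -s[-m] | s[-1L] == 0 | s[-m] == 0
  alt_id <- cumsum(c(TRUE, alt_break))
  alt_len <- tabulate(alt_id)
  pas <- sum(alt_len[alt_len >= 4L]) / m

  c(PIP = pip, IALS = ials, PSS = pss, PAS = pas)
}

#' Lomb--Scargle periodogram for unevenly sampled series
#'
#' Classical Lomb normalisation with the time-shift invariance term, scaled
#' to an approximate one-sided spectral density (integrating the density over
#' the evaluated band recovers about the series variance).
#'
#' @param t sample times, s.
#' @param x values (e.g. RR in ms).
#' @param freqs evaluation frequencies, Hz.
#' @return Named list `freq`, `power` (density, x-units squared per Hz).
#' @export
lomb_psd <- function(t, x, freqs) {
  xc <- x - mean(x)
  pw <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2))
  }, numeric(1))
  span <- diff(range(t))
  list(freq = freqs, power = pw * 2 * span / length(t))
}

#' Frequency-domain HRV features
#'
#' Band powers from the Lomb--Scargle periodogram of the valid RR intervals
#' at their (uneven) beat times, integrated by the trapezoidal rule over
#' VLF 0.0033--0.04 Hz, LF 0.04--0.15 Hz and HF 0.15--0.4 Hz.
#'
#' @param rr a `vt_rr` series (needs at least 5 min of valid intervals).
#' @return Named vector `TOT_PWR`, `VLF_PWR`, `LF_PWR`, `HF_PWR` (ms^2),
#'   `LF_HF`, `LF_NORM`, `HF_NORM` (percent of LF+HF).
#' @export
hrv_frequency <- function(rr) {
  nms <- c("TOT_PWR", "VLF_PWR", "LF_PWR", "HF_PWR", "LF_HF", "LF_NORM",
           "HF_NORM")
  v <- rr$valid
  x <- rr$intervals_ms[v]; t <- rr$times_s[v]
  if (length(x) < 10L || sum(x) / 1000 < 300) return(na_set(nms))
  freqs <- seq(0.0033, 0.4, by = 0.001)
  ps <- lomb_psd(t, x, freqs)
  band <- function(lo, hi) {
    i <- ps$freq >= lo & ps$freq <= hi
    trapz(ps$freq[i], ps$power[i])
  }
  vlf <- band(0.0033, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.4)
  c(TOT_PWR = vlf + lf + hf, VLF_PWR = vlf, LF_PWR = lf, HF_PWR = hf,
    LF_HF = lf / hf, LF_NORM = 100 * lf / (lf + hf),
    HF_NORM = 100 * hf / (lf + hf))
}

# Exact white-noise expectation of the mean squared linearly detrended
# residual of integrated noise in a box of length s; used as a finite-size
# correction so the white-noise scaling exponent is exactly 1/2 at every
# box size (small boxes are otherwise biased upward).
dfa_expected_f2 <- local({
  cache <- new.env(parent = emptyenv())
  function(s) {
    key <- as.character(s)
    if (!is.null(cache[[key]])) return(cache[[key]])
    tt <- seq_len(s); X <- cbind(1, tt)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    C <- outer(tt, tt, pmin)
    M <- diag(s) - H
    v <- sum(diag(M %*% C %*% t(M))) / s
    cache[[key]] <- v
    v
  }
})

# Detrended fluctuation analysis slope over the given box sizes, with the
# finite-size correction applied to each F(s).
dfa_slope <- function(y, scales) {
  n <- length(y)
  scales <- scales[scales * 2 <= n]
  if (length(scales) < 3L) return(NA_real_)
  fl <- vapply(scales, function(s) {
    m <- n %/% s
    yy <- matrix(y[seq_len(m * s)], nrow = s)
    tt <- seq_len(s)
    fit <- stats::lm.fit(cbind(1, tt), yy)
    sqrt(mean(fit$residuals^2)) * sqrt(s / dfa_expected_f2(s))
  }, numeric(1))
  ok <- fl > 0
  if (sum(ok) < 3L) return(NA_real_)
  unname(stats::coef(stats::lm(log(fl[ok]) ~ log(scales[ok])))[2L])
}

#' Nonlinear HRV features
#'
#' Poincare descriptors (`SD1 = RMSSD / sqrt(2)`, `SD2` from the SDNN
#' identity), sample entropy (m = 2, r = 0.2 SDNN) and detrended fluctuation
#' slopes over boxes 4--11 (`DFA_alpha1`) and 12--64 (`DFA_alpha2`).
#'
#' @param rr a `vt_rr` series (SampEn/DFA need at least 100 valid intervals).
#' @return Named vector `SD1`, `SD2`, `SD1_SD2`, `SampEn`, `DFA_alpha1`,
#'   `DFA_alpha2`.
#' @export
hrv_nonlinear <- function(rr) {
  nms <- c("SD1", "SD2", "SD1_SD2", "SampEn", "DFA_alpha1", "DFA_alpha2")
  x <- rr$intervals_ms[rr$valid]
  if (length(x) < 10L) return(na_set(nms))
  d <- valid_diffs(rr)
  sd1 <- if (length(d)) sqrt(mean(d^2) / 2) else NA_real_
  sdnn <- stats::sd(x)
  sd2 <- sqrt(max(2 * sdnn^2 - sd1^2, 0))
  out <- c(SD1 = sd1, SD2 = sd2,
           SD1_SD2 = if (is.na(sd2) || sd2 == 0) NA_real_ else sd1 / sd2,
           SampEn = NA_real_, DFA_alpha1 = NA_real_, DFA_alpha2 = NA_real_)
  if (length(x) >= 100L && sdnn > 0) {
    out["SampEn"] <- sampen_cpp(x, 2L, 0.2 * sdnn)
    y <- cumsum(x - mean(x))
    out["DFA_alpha1"] <- dfa_slope(y, 4:11)
    out["DFA_alpha2"] <- dfa_slope(y, 12:64)
  }
  out
}

#' All 23 HRV features for one window
#'
#' @param rr a `vt_rr` series.
#' @return Named numeric vector of the full HRV battery (time domain,
#'   fragmentation, frequency domain, nonlinear).
#' @export
hrv_features <- function(rr) {
  c(hrv_time(rr), hrv_fragmentation(rr), hrv_frequency(rr),
    hrv_nonlinear(rr))
}
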