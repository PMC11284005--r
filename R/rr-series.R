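#' Generate a ground-truth RR interval series for one recording
#'
#' The sinus RR series is built from an order-1 autoregressive process on the
#' RR increments with coefficient `frag_coeff` (negative values produce
#' frequent acceleration/deceleration reversals, i.e. a fragmented rhythm),
#' integrated with a slow leak so the series stays stationary around the mean
#' RR, and rescaled to the profile's intrinsic variability `rr_sd`.  Sinusoidal
#' low-frequency (0.1 Hz) and high-frequency (0.25 Hz) modulations of
#' amplitude `lf_amp` / `hf_amp` are added.  Each beat independently becomes a
#' premature ventricular beat with probability `pvc_prob`: its own interval is
#' shortened to `pvc_coupling` times the current RR and the following interval
#' is lengthened so the pair sums to twice the local mean RR (a full
#' compensatory pause).  Intervals are finally clamped to the physiological
#' range 300--2500 ms.
#'
#' @param profile one row of a [sample_cohort()] table (or a list with the
#'   same fields).
#' @param duration_hr recording duration in hours.
#' @param seed integer seed.
#' @return An object of class `vt_ground_truth`: list with `rr_ms`,
#'   `beat_times_s` (cumulative, first beat at one RR), `beat_labels`
#'   (`"N"`/`"V"`), `vt_runs` (empty list), `realized_pvc_fraction` and
#'   `duration_s`.
#' @export
generate_rr_series <- function(profile, duration_hr, seed = 1L) {
  if (duration_hr <= 0) vt_abort("duration must be positive")
  profile <- as.list(profile)
  with_seed(seed, {
    mean_rr <- 60000 / profile$mean_hr
    duration_ms <- duration_hr * 3600 * 1000
    n <- ceiling(duration_ms / mean_rr * 1.3) + 50L

    phi <- profile$frag_coeff
    if (profile$rr_sd > 0) {
      e <- stats::rnorm(n)
      d <- as.numeric(stats::filter(e, phi, method = "recursive"))
      y <- as.numeric(stats::filter(d, 0.98, method = "recursive"))
      y <- y / stats::sd(y) * profile$rr_sd
    } else y <- numeric(n)

    t_nom <- seq_len(n) * mean_rr / 1000  # nominal beat times, s
    rr <- mean_rr + y +
      profile$lf_amp * sin(2 * pi * 0.1 * t_nom) +
      profile$hf_amp * sin(2 * pi * 0.25 * t_nom)

    lab <- rep("N", n)
    if (profile$pvc_prob > 0) {
      v <- which(stats::runif(n) < profile$pvc_prob)
      v <- v[v > 9L & v < n]                # need local history and a pause slot
      v <- v[c(TRUE, diff(v) > 1L)]         # no back-to-back PVC pairs
      for (i in v) {
        local_mean <- mean(rr[(i - 8L):(i - 1L)])
        rr[i] <- profile$pvc_coupling * rr[i]
        rr[i + 1L] <- 2 * local_mean - rr[i]
        lab[i] <- "V"
      }
    }
    rr <- clip(rr, 300, 2500)

    cum <- cumsum(rr)
    keep <- which.min(abs(cum - duration_ms))
    rr <- rr[seq_len(keep)]
    lab <- lab[seq_len(keep)]

    structure(list(
      rr_ms = rr,
      beat_times_s = cumsum(rr) / 1000,
      beat_labels = lab,
      vt_runs = list(),
      realized_pvc_fraction = mean(lab == "V"),
      duration_s = duration_hr * 3600
    ), class = "vt_ground_truth")
  })
}
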