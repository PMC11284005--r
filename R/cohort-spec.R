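#' Describe a synthetic Holter cohort
#'
#' A cohort specification holds the patient counts, recording geometry and the
#' class-conditional parameter distributions from which patient profiles are
#' drawn.  The defaults encode the working assumptions of the screening
#' problem: ventricular ectopy (PVC burden) is roughly ten-fold more frequent
#' in VT (C1) patients, their RR-increment series is more fragmented (lag-1
#' increment autocorrelation shifted by -0.3), and patient-information fields
#' (age, sex, BMI, smoking) carry no class signal.  All class shifts are
#' multiplied by `effect_size_scale`, so `effect_size_scale = 0` yields a null
#' cohort in which C0 and C1 are statistically identical.
#'
#' @param n_c0,n_c1 number of patients per class.
#' @param recordings_per_patient recordings per patient (Holters may repeat).
#' @param duration_hr recording duration in hours.
#' @param fs sampling frequency in Hz.
#' @param effect_size_scale non-negative multiplier applied to every C1 - C0
#'   parameter shift.
#' @param seed integer seed; the whole cohort is deterministic given the spec.
#' @param params optional list overriding entries of the default parameter
#'   table (see Details).
#' @param vt_run_prob probability that a C1 recording receives injected VT
#'   runs (kept out of analysed windows downstream by the exclusion rules).
#'
#' @details Each parameter entry is a list with a `dist` field (`"norm"`,
#'   `"lnorm"`, `"unif"`, `"bern"` or `"pois"`), its C0 parameters, an additive
#'   C1 location `shift` (applied on the log scale for `lnorm`) and optional
#'   `lo`/`hi` clamps.
#'
#' @return An object of class `vt_cohort_spec`.
#' @export
cohort_spec <- function(n_c0 = 160, n_c1 = 40, recordings_per_patient = 1,
                        duration_hr = 1, fs = 128, effect_size_scale = 1,
                        seed = 1L, params = list(), vt_run_prob = 0.3) {
  if (n_c0 < 0 || n_c1 < 0) vt_abort("patient counts must be >= 0")
  if (recordings_per_patient < 1) vt_abort("recordings_per_patient must be >= 1")
  if (effect_size_scale < 0) vt_abort("effect_size_scale must be >= 0")
  if (duration_hr <= 0 || fs <= 0) vt_abort("duration and fs must be positive")

  defaults <- list(
    age          = list(dist = "norm", mean = 65, sd = 12, shift = 0, lo = 18, hi = 95),
    sex          = list(dist = "bern", p = 0.6, shift = 0),
    bmi          = list(dist = "norm", mean = 27, sd = 4, shift = 0, lo = 16, hi = 45),
    smoking      = list(dist = "bern", p = 0.25, shift = 0),
    mean_hr      = list(dist = "norm", mean = 75, sd = 8, shift = 5, lo = 45, hi = 140),
    rr_sd        = list(dist = "norm", mean = 40, sd = 10, shift = 0, lo = 5, hi = 90),
    frag_coeff   = list(dist = "norm", mean = 0.10, sd = 0.15, shift = -0.30,
                        lo = -0.95, hi = 0.95),
    lf_amp       = list(dist = "norm", mean = 20, sd = 5, shift = 0, lo = 0, hi = 60),
    hf_amp       = list(dist = "norm", mean = 15, sd = 5, shift = 0, lo = 0, hi = 60),
    pvc_prob     = list(dist = "lnorm", meanlog = log(0.005), sdlog = 0.6,
                        shift = log(0.05 / 0.005), lo = 0, hi = 0.3),
    pvc_coupling = list(dist = "unif", min = 0.45, max = 0.75, shift = 0),
    r_amp        = list(dist = "norm", mean = 1.0, sd = 0.2, shift = 0, lo = 0.4, hi = 2),
    pvc_width_factor = list(dist = "unif", min = 1.8, max = 2.4, shift = 0),
    noise_level  = list(dist = "unif", min = 0.01, max = 0.05, shift = 0),
    n_bad_segments = list(dist = "pois", lambda = 0.3, shift = 0)
  )
  for (nm in names(params)) {
    if (!nm %in% names(defaults)) vt_abort("unknown profile parameter: ", nm)
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], params[[nm]])
  }
  validate_param_table(defaults)

  structure(list(n_c0 = n_c0, n_c1 = n_c1,
                 recordings_per_patient = recordings_per_patient,
                 duration_hr = duration_hr, fs = fs,
                 effect_size_scale = effect_size_scale, seed = as.integer(seed),
                 params = defaults, vt_run_prob = vt_run_prob),
            class = "vt_cohort_spec")
}

validate_param_table <- function(params) {
  for (nm in names(params)) {
    p <- params[[nm]]
    bad <- switch(p$dist,
      norm  = p$sd < 0,
      lnorm = p$sdlog < 0,
      unif  = p$min > p$max,
      bern  = p$p < 0 || p$p > 1,
      pois  = p$lambda < 0,
      TRUE)
    if (isTRUE(bad)) vt_abort("invalid distribution parameters for '", nm, "'")
  }
  invisible(params)
}

draw_param <- function(p, n, class_shift) {
  x <- switch(p$dist,
    norm  = stats::rnorm(n, p$mean + class_shift, p$sd),
    lnorm = stats::rlnorm(n, p$meanlog + class_shift, p$sdlog),
    unif  = stats::runif(n, p$min, p$max) + class_shift,
    bern  = stats::rbinom(n, 1L, clip(p$p + class_shift, 0, 1)),
    pois  = stats::rpois(n, max(p$lambda + class_shift, 0)),
    vt_abort("unknown distribution: ", p$dist))
  if (!is.null(p$lo)) x <- clip(x, p$lo, p$hi)
  x
}

#' Draw patient profiles for a cohort
#'
#' Samples `n_c0 + n_c1` patient profiles from the class-conditional
#' distributions of the spec; deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame with one row per patient (class `vt_profiles`),
#'   columns `patient_id`, `class_label` and every profile parameter.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "vt_cohort_spec"))
  with_seed(derive_seed(spec$seed, "profiles"), {
    n <- spec$n_c0 + spec$n_c1
    lab <- rep(c("C0", "C1"), c(spec$n_c0, spec$n_c1))
    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      class_label = lab, stringsAsFactors = FALSE)
    for (nm in names(spec$params)) {
      p <- spec$params[[nm]]
      shift <- ifelse(lab == "C1", p$shift * spec$effect_size_scale, 0)
      # draw per class so scale = 0 gives identical marginals
      x <- numeric(n)
      for (cl in unique(lab)) {
        idx <- which(lab == cl)
        x[idx] <- draw_param(p, length(idx), shift[idx][1L])
      }
      out[[nm]] <- x
    }
    out$sex <- ifelse(out$sex == 1, "M", "F")
    out$smoking <- out$smoking == 1
    out$n_bad_segments <- as.integer(out$n_bad_segments)
    if (any(out$mean_hr < 30 | out$mean_hr > 180))
      vt_abort("mean_hr outside [30, 180]")
    class(out) <- c("vt_profiles", "data.frame")
    out
  })
}
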