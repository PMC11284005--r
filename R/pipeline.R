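#' Default pipeline configuration
#'
#' Houses the pipeline's fixed constants: 0.67--100 Hz band-pass, 50 Hz
#' notch, 30-min windows, bsqi threshold 0.8, six-good-window recording
#' rule, 4 inner folds x 10 outer repeats, 50 search iterations.
#'
#' @param ... overrides for any config field.
#' @return A `vt_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    passband_low = 0.67, passband_high = 100, filter_order = 2,
    notch_freq = 50, notch_q = 30,
    window_min = 30, bsqi_threshold = 0.8, bsqi_tol_ms = 150,
    min_good_windows = 6,
    variant = "HRV+MOR", outer_repeats = 10, inner_folds = 4,
    search_iterations = 50, n_test_c1 = 10, n_test_c0 = 130,
    seed = 1L,
    cohort = list(n_c0 = 160, n_c1 = 40, duration_hr = 1, fs = 128,
                  effect_size_scale = 1))
  utils::modifyList(cfg, list(...))
}

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults, collects every inconsistency (not just the first) and
#' applies the passband-vs-Nyquist clipping rule.
#'
#' @param config partial configuration list.
#' @return Normalised `vt_config`; errors carry the full problem list.
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  errs <- character(0)
  if (cfg$bsqi_threshold < 0 || cfg$bsqi_threshold > 1)
    errs <- c(errs, "bsqi_threshold must be in [0,1]")
  if (cfg$window_min <= 0) errs <- c(errs, "window_min must be positive")
  if (cfg$min_good_windows < 0)
    errs <- c(errs, "min_good_windows must be >= 0")
  if (cfg$passband_low <= 0 || cfg$passband_high <= cfg$passband_low)
    errs <- c(errs, "need 0 < passband_low < passband_high")
  if (cfg$outer_repeats < 1) errs <- c(errs, "outer_repeats must be >= 1")
  if (cfg$search_iterations < 1)
    errs <- c(errs, "search_iterations must be >= 1")
  fs <- cfg$cohort$fs
  if (!is.null(fs) && fs < 200 && cfg$passband_high > 0.45 * fs) {
    vt_warn(sprintf("passband_high %g Hz clipped to %.1f Hz for fs = %g",
                    cfg$passband_high, 0.45 * fs, fs))
    cfg$passband_high <- 0.45 * fs
  }
  if (length(errs)) vt_abort(paste(errs, collapse = "; "))
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

#' Filter, window, quality-score and featurise a cohort
#'
#' The per-recording stage chain: band-pass + notch filtering, 30-min
#' windowing, dual-detector bsqi scoring, exclusion rules, feature
#' extraction on retained windows.
#'
#' @param cohort a `vt_cohort` (or list of `vt_recording`s).
#' @param config a validated `vt_config`.
#' @param progress print a dot per recording.
#' @return List: `features` (`vt_features`), `manifest` (exclusion
#'   accounting), `quality` (per-recording report), `windows` (scored).
#' @export
process_cohort <- function(cohort, config = validate_config(), progress = FALSE) {
  recs <- if (inherits(cohort, "vt_cohort")) cohort$recordings else cohort
  fspec <- filter_spec(config$passband_low, config$passband_high,
                       config$filter_order, config$notch_freq, config$notch_q)
  acc <- list(windows = list(), features = list(), meta = list())
  for (rid in names(recs)) {
    acc <- accumulate_recording(acc, recs[[rid]], fspec, config)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  finalise_cohort(acc, config)
}

# Filter, window, score and featurise one recording, appending to the
# accumulator (signal data is not retained).
accumulate_recording <- function(acc, rec, fspec, config) {
  rid <- rec$recording_id
  recf <- suppressWarnings(apply_filters(rec, fspec))
  w <- suppressWarnings(split_windows(recf, config$window_min))
  if (nrow(w)) {
    w <- score_windows(w, recf, config$bsqi_tol_ms, config$bsqi_threshold)
    keep <- w$bsqi > config$bsqi_threshold
    if (any(keep))
      acc$features[[rid]] <- extract_features(recf, w[keep, , drop = FALSE],
                                              attr(w, "detections")[keep])
    attr(w, "detections") <- NULL
    acc$windows[[rid]] <- w
  }
  acc$meta[[rid]] <- data.frame(
    recording_id = rec$recording_id, patient_id = rec$patient_id,
    class_label = rec$class_label, age = rec$pi$age, sex = rec$pi$sex,
    bmi = rec$pi$bmi, smoking = rec$pi$smoking, stringsAsFactors = FALSE)
  acc
}

finalise_cohort <- function(acc, config) {
  windows <- do.call(rbind, acc$windows)
  rownames(windows) <- NULL
  meta <- do.call(rbind, acc$meta)
  rownames(meta) <- NULL
  excl <- apply_exclusions(windows, meta, config$bsqi_threshold,
                           config$min_good_windows)
  feats <- do.call(rbind, acc$features)
  key <- paste(excl$retained$recording_id, excl$retained$window_index)
  feats <- feats[paste(feats$recording_id, feats$window_index) %in% key, ]
  features <- assemble_features(feats, meta)
  list(features = features, manifest = excl$manifest, quality = excl$report,
       windows = windows, meta = meta)
}

#' Simulate and process a cohort one recording at a time
#'
#' Streaming variant of [simulate_cohort()] + [process_cohort()]: each
#' recording is rendered, filtered, scored and featurised, then its signal
#' is discarded, so arbitrarily large cohorts fit in memory.  Bit-identical
#' to the two-step route for the same spec and config.
#'
#' @param spec a [cohort_spec()].
#' @param config a validated `vt_config`.
#' @param progress print a dot per recording.
#' @return As [process_cohort()].
#' @export
simulate_and_process <- function(spec, config = validate_config(),
                                 progress = FALSE) {
  profiles <- sample_cohort(spec)
  fspec <- filter_spec(config$passband_low, config$passband_high,
                       config$filter_order, config$notch_freq, config$notch_q)
  acc <- list(windows = list(), features = list(), meta = list())
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    for (r in seq_len(spec$recordings_per_patient)) {
      rid <- sprintf("%s_R%02d", prof$patient_id, r)
      rseed <- derive_seed(spec$seed, rid)
      nvt <- 0L
      if (prof$class_label == "C1")
        nvt <- with_seed(derive_seed(rseed, "nvt"),
                         stats::rbinom(1L, 2L, spec$vt_run_prob))
      rec <- simulate_recording(prof, spec$duration_hr, spec$fs,
                                seed = rseed, recording_id = rid,
                                n_vt_runs = nvt)
      acc <- accumulate_recording(acc, rec, fspec, config)
      if (progress) cat(".")
    }
  }
  if (progress) cat("\n")
  out <- finalise_cohort(acc, config)
  out$profiles <- profiles
  out
}

#' Run the full pipeline: simulate, extract, train, evaluate
#'
#' End-to-end orchestration on a synthetic cohort: simulate (or accept) the
#' cohort, process every recording, build the outer split plan and evaluate
#' the configured model variant(s).  Stage outputs are cached in `out_dir`
#' keyed by the config hash, and a manifest records the counts at every
#' exclusion step.
#'
#' @param config configuration list (see [pipeline_config()]).
#' @param cohort optional pre-built `vt_cohort`; otherwise simulated from
#'   `config$cohort`.
#' @param out_dir optional run directory for cached artefacts and reports.
#' @param progress print progress dots.
#' @return List: `report` (a `vt_eval`), `manifest`, `quality`, `features`,
#'   `config`.
#' @export
run_pipeline <- function(config = list(), cohort = NULL, out_dir = NULL,
                         progress = FALSE) {
  cfg <- validate_config(config)
  hash <- config_hash(cfg)
  cache <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cache <- file.path(out_dir, paste0("stage_features_", hash, ".rds"))
  }
  if (!is.null(cache) && file.exists(cache) && is.null(cohort)) {
    proc <- readRDS(cache)
  } else {
    if (is.null(cohort)) {
      spec <- do.call(cohort_spec,
                      c(cfg$cohort, list(seed = derive_seed(cfg$seed, "cohort"))))
      cohort <- simulate_cohort(spec, progress = progress)
    }
    proc <- process_cohort(cohort, cfg, progress = progress)
    if (!is.null(cache)) saveRDS(proc, cache)
  }
  plan <- make_splits(unique(proc$features[c("patient_id", "class_label")]),
                      outer_repeats = cfg$outer_repeats,
                      n_test_c1 = cfg$n_test_c1, n_test_c0 = cfg$n_test_c0,
                      seed = derive_seed(cfg$seed, "splits"))
  report <- vt_evaluate(proc$features, variants = cfg$variant, plan = plan,
                        search_iterations = cfg$search_iterations,
                        seed = derive_seed(cfg$seed, "eval"))
  if (!is.null(out_dir)) {
    utils::write.csv(report$table, file.path(out_dir, "auroc_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(proc$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(cfg, file.path(out_dir, "config_resolved.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(report = report, manifest = proc$manifest, quality = proc$quality,
       features = proc$features, config = cfg)
}
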