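test_that("cohort sampling honours counts, labels and determinism", {
  spec <- cohort_spec(n_c0 = 2, n_c1 = 1, seed = 7)
  prof <- sample_cohort(spec)
  expect_equal(nrow(prof), 3L)
  expect_equal(prof$class_label, c("C0", "C0", "C1"))
  expect_identical(prof, sample_cohort(spec))

  spec2 <- cohort_spec(n_c0 = 2, n_c1 = 1, seed = 8)
  expect_false(identical(prof$mean_hr, sample_cohort(spec2)$mean_hr))

  expect_error(cohort_spec(params = list(mean_hr = list(sd = -1))),
               "invalid distribution")
  expect_error(cohort_spec(n_c0 = -1), "counts")
})

test_that("null cohort (effect_size_scale = 0) equalises the classes", {
  spec <- cohort_spec(n_c0 = 500, n_c1 = 500, effect_size_scale = 0,
                      seed = 123)
  prof <- sample_cohort(spec)
  ks <- suppressWarnings(
    stats::ks.test(prof$pvc_prob[prof$class_label == "C0"],
                   prof$pvc_prob[prof$class_label == "C1"]))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(
    stats::ks.test(prof$frag_coeff[prof$class_label == "C0"],
                   prof$frag_coeff[prof$class_label == "C1"]))
  expect_gt(ks2$p.value, 0.01)
})

test_that("RR generator degenerate and PVC-free cases", {
  p <- base_profile(mean_hr = 60, rr_sd = 0, lf_amp = 0, hf_amp = 0)
  gt <- generate_rr_series(p, 0.1, seed = 1)
  expect_true(all(gt$beat_labels == "N"))
  expect_true(all(abs(gt$rr_ms - 1000) < 1e-9))
  expect_equal(gt$realized_pvc_fraction, 0)
  expect_error(generate_rr_series(p, -1), "positive")
})

test_that("PVC beats shorten their interval and get a compensatory pause", {
  p <- base_profile(mean_hr = 60, rr_sd = 0, lf_amp = 0, hf_amp = 0,
                    pvc_prob = 0.05, pvc_coupling = 0.6)
  gt <- generate_rr_series(p, 0.5, seed = 3)
  v <- which(gt$beat_labels == "V")
  expect_gt(length(v), 5)
  expect_true(all(abs(gt$rr_ms[v] - 600) < 1e-6))
  expect_true(all(abs(gt$rr_ms[v] + gt$rr_ms[v + 1L] - 2000) < 1e-6))
})

test_that("realized PVC fraction falls in the central binomial interval", {
  p <- base_profile(pvc_prob = 0.05)
  gt <- generate_rr_series(p, 2, seed = 11)
  n <- length(gt$rr_ms)
  lo <- qbinom(0.005, n, 0.05) / n
  hi <- qbinom(0.995, n, 0.05) / n
  expect_gte(gt$realized_pvc_fraction, lo)
  expect_lte(gt$realized_pvc_fraction, hi)
})

test_that("PVC prevalence is recovered at large beat counts", {
  p <- base_profile(pvc_prob = 0.05)
  gt <- generate_rr_series(p, 13, seed = 5)
  expect_gte(length(gt$rr_ms), 50000)
  expect_lt(abs(gt$realized_pvc_fraction - 0.05), 0.005)
})

test_that("RR duration conservation holds within one mean RR", {
  for (s in 1:5) {
    p <- base_profile(mean_hr = 60 + 5 * s)
    gt <- generate_rr_series(p, 0.5, seed = s)
    expect_lt(abs(sum(gt$rr_ms) - 0.5 * 3600 * 1000), 60000 / p$mean_hr)
  }
})

test_that("identical spec and seed give a bit-identical cohort", {
  spec <- cohort_spec(n_c0 = 2, n_c1 = 1, duration_hr = 0.05, fs = 128,
                      seed = 99)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$recordings[[1]]$signal, c2$recordings[[1]]$signal)
})

test_that("ECG synthesis geometry and annotations", {
  p <- base_profile(noise_level = 0, mean_hr = 60, rr_sd = 0, lf_amp = 0,
                    hf_amp = 0)
  gt <- generate_rr_series(p, 0.5, seed = 1)
  ecg <- synthesize_ecg(gt, p, 250, seed = 1)
  expect_equal(nrow(ecg$signal), 450000L)
  expect_equal(ncol(ecg$signal), 3L)
  # R is the largest bump: signal argmax within +/-50 ms of each annotation
  x <- ecg$signal[, 1]
  for (s in ecg$annotations$sample[10:14]) {
    reg <- (s - 12):(s + 12) + 1L
    expect_lt(abs(which.max(x[reg]) - 13L), 250 * 0.05)
  }
  # rendered ventricular QRS spans > 120 ms between 3-sigma bounds
  expect_gt(vtscreen:::rendered_qrs_span(2), 120)
  expect_error(synthesize_ecg(gt, p, 50), "fs too low")
})

test_that("VT run injection inserts fast ventricular runs", {
  p <- base_profile(mean_hr = 60, rr_sd = 10)
  rec <- simulate_recording(p, 0.5, 128, seed = 2, n_vt_runs = 0)
  expect_length(rec$gt$vt_runs, 0)

  res <- inject_vt_runs(rec, rec$gt, n_runs = 1, run_length_beats = 3,
                        run_rate_bpm = 150, seed = 4)
  expect_length(res$gt$vt_runs, 1)
  v_rr <- res$gt$rr_ms[res$gt$beat_labels == "V"]
  expect_true(all(abs(v_rr - 400) < 1e-6))
  run <- res$gt$vt_runs[[1]]
  expect_lt((run[2] - run[1]) / 128, 3 * 0.4 + 1)

  expect_error(inject_vt_runs(rec, rec$gt, 1, run_length_beats = 2),
               ">= 3 beats")
  expect_error(inject_vt_runs(rec, rec$gt, 1, run_rate_bpm = 90),
               "100")
})

test_that("windows overlapping injected VT match brute-force interval overlap", {
  p <- base_profile(mean_hr = 70, class_label = "C1")
  rec <- simulate_recording(p, 2, 128, seed = 31, n_vt_runs = 2)
  w <- split_windows(rec, 30)
  brute <- vapply(seq_len(nrow(w)), function(i) {
    any(vapply(rec$gt$vt_runs, function(run)
      run[1] < w$end_sample[i] && run[2] > w$start_sample[i], logical(1)))
  }, logical(1))
  expect_equal(w$contains_vt, brute)
  expect_gt(sum(brute), 0)
})
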