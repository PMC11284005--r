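test_that("both detectors are accurate on a clean 5-min ECG at 60 bpm", {
  p <- base_profile(mean_hr = 60, noise_level = 0, pvc_prob = 0)
  gt <- generate_rr_series(p, 1 / 12, seed = 4)
  ecg <- synthesize_ecg(gt, p, 128, seed = 5)
  x <- ecg$signal[, 1]
  tru <- ecg$annotations$sample
  expect_equal(length(tru), 300, tolerance = 2 / 300)

  for (det in list(detect_qrs_primary, detect_qrs_secondary)) {
    d <- det(x, 128)
    expect_equal(length(d), length(tru), tolerance = 2 / 300)
    expect_gte(bsqi(d, tru, 50, 128), 0.99)
    expect_true(all(diff(d) > 0))
    expect_true(all(diff(d) >= 0.25 * 128))
  }
})

test_that("detectors return empty on degenerate input and rescale cleanly", {
  z <- rep(0, 128 * 30)
  expect_length(detect_qrs_primary(z, 128), 0)
  expect_length(detect_qrs_secondary(z, 128), 0)
  expect_error(detect_qrs_primary(rep(0, 10), 128), "2 s")

  fx <- clean_beat_fixture()
  d1 <- detect_qrs_primary(fx$x, fx$fs)
  d2 <- detect_qrs_primary(fx$x / 2, fx$fs)
  expect_gte(bsqi(d1, d2, 20, fx$fs), 0.999)
})

test_that("detectors disagree on heavy noise (low bsqi)", {
  set.seed(9)
  xn <- rnorm(128 * 660, 0, 1)
  q <- bsqi(detect_qrs_primary(xn, 128), detect_qrs_secondary(xn, 128),
            150, 128)
  expect_lt(q, 0.8)
})

test_that("delineation recovers generator QRS geometry", {
  # clean normal beats at 250 Hz: QRS duration within [60, 110] ms
  p <- base_profile(noise_level = 0, mean_hr = 60, rr_sd = 0, lf_amp = 0,
                    hf_amp = 0)
  gt <- generate_rr_series(p, 1 / 30, seed = 1)
  ecg <- synthesize_ecg(gt, p, 250, seed = 1)
  rec <- suppressWarnings(apply_filters(as_recording(ecg$signal, 250),
                                        filter_spec()))
  x <- rec$signal[, 1]
  d <- delineate(x, 250, detect_qrs_primary(x, 250))
  dur <- d$qrs_dur_ms[!is.na(d$qrs_dur_ms)]
  expect_gt(length(dur), 50)
  expect_true(all(dur >= 60 & dur <= 110))
  expect_gt(mean(!is.na(d$p_peak)), 0.95)
  expect_true(all(d$qrs_on < d$r_sample & d$r_sample < d$qrs_off,
                  na.rm = TRUE))

  # ventricular beats: wide QRS, no P
  p2 <- base_profile(noise_level = 0, mean_hr = 60, rr_sd = 0, lf_amp = 0,
                     hf_amp = 0, pvc_prob = 0.08, pvc_width_factor = 2)
  gt2 <- generate_rr_series(p2, 1 / 12, seed = 2)
  ecg2 <- synthesize_ecg(gt2, p2, 250, seed = 1)
  rec2 <- suppressWarnings(apply_filters(as_recording(ecg2$signal, 250),
                                         filter_spec()))
  x2 <- rec2$signal[, 1]
  d2 <- delineate(x2, 250, detect_qrs_primary(x2, 250))
  vi <- which(ecg2$annotations$label == "V")
  m <- match_ann(d2$r_sample, ecg2$annotations$sample[vi], tol = 20)
  m <- m[!is.na(m)]
  expect_gt(length(m), 10)
  expect_true(all(d2$qrs_dur_ms[m] > 120))
  expect_true(all(is.na(d2$p_peak[m])))
})

test_that("edge beats get no fiducials", {
  fx <- clean_beat_fixture()
  d <- delineate(fx$x[1:(30 * fx$fs)], fx$fs, c(2L, 300L))
  expect_true(is.na(d$qrs_on[1]))
  expect_false(is.na(d$qrs_on[2]))
})

test_that("beat classification separates V from N on a labelled fixture", {
  fx <- clean_beat_fixture()
  m <- match_ann(fx$beats$r_sample, fx$ann$sample)
  ok <- !is.na(m)
  truth <- fx$ann$label[ok]
  pred <- fx$beats$label[m[ok]]
  tv <- truth == "V"
  expect_gte(sum(tv & pred == "V") / sum(tv), 0.90)        # sensitivity
  expect_gte(sum(!tv & pred != "V") / sum(!tv), 0.95)      # specificity
  expect_true(all(pred %in% c("N", "S", "V", "F", "none")))
  expect_gt(mean(tv & pred == "V") , 0)
})

test_that("an all-normal fixture yields almost no false V labels", {
  p <- base_profile(pvc_prob = 0)
  gt <- generate_rr_series(p, 1 / 6, seed = 13)
  ecg <- synthesize_ecg(gt, p, 128, seed = 14)
  rec <- suppressWarnings(apply_filters(as_recording(ecg$signal, 128),
                                        filter_spec()))
  x <- rec$signal[, 1]
  beats <- classify_beats(delineate(x, 128, detect_qrs_primary(x, 128)),
                          x, 128)
  expect_lte(mean(beats$label == "V"), 0.01)
})

test_that("beats without fiducials are labelled none, one label per beat", {
  fx <- clean_beat_fixture()
  b <- fx$beats
  expect_true(all(b$label[is.na(b$qrs_on)] == "none"))
  expect_equal(sum(b$label %in% c("N", "S", "V", "F", "none")), nrow(b))
})
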