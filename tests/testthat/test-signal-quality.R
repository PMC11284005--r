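test_that("bsqi handles the boundary and worked cases", {
  expect_equal(bsqi(c(10, 20, 30), c(10, 20, 30), 150, 1000), 1)
  expect_equal(bsqi(integer(0), integer(0), 150, 1000), 1)
  expect_equal(bsqi(c(100, 600, 1100), integer(0), 150, 1000), 0)
  expect_equal(bsqi(integer(0), c(100), 150, 1000), 0)
  # worked example: TP = 2, FN = 1, FP = 0 -> F1 = 0.8
  expect_equal(bsqi(c(100, 600, 1100), c(102, 1105), 150, 1000), 0.8)
  expect_error(bsqi(c(5, 1), c(1, 5), 150, 1000), "sorted")
  # Jaccard variant: 2 / (2 + 1)
  expect_equal(bsqi(c(100, 600, 1100), c(102, 1105), 150, 1000,
                    variant = "jaccard"), 2 / 3)
})

test_that("bsqi equals brute-force maximum matching and is symmetric", {
  set.seed(77)
  for (k in 1:300) {
    na <- sample(0:30, 1); nb <- sample(0:30, 1)
    a <- sort(sample.int(3000, na))
    b <- sort(sample.int(3000, nb))
    tol_ms <- sample(c(50, 100, 150), 1)
    got <- bsqi(a, b, tol_ms, 1000)
    expect_equal(got, oracle_bsqi(a, b, tol_ms), info = paste("case", k))
    expect_equal(got, bsqi(b, a, tol_ms, 1000))
  }
})

test_that("windows are scored per lead and degrade with noise", {
  p <- base_profile(noise_level = 0, n_bad_segments = 0L)
  gt <- generate_rr_series(p, 0.5, seed = 21)
  ecg <- synthesize_ecg(gt, p, 128, seed = 22)
  rec <- suppressWarnings(apply_filters(as_recording(ecg$signal, 128),
                                        filter_spec()))
  w <- score_windows(split_windows(rec, 30), rec)
  expect_gt(w$bsqi[1], 0.95)
  expect_true(w$quality_ok[1])
  expect_true(w$lead_used[1] %in% 1:3)

  # monotone degradation with added white noise (median over seeds).
  # Beyond full degradation the score saturates at the chance-agreement
  # floor of refractory-limited matching (~0.6), so the monotone range is
  # the one where the beats are progressively lost.
  med_bsqi <- vapply(c(0, 0.1, 0.2), function(nl) {
    stats::median(vapply(1:5, function(s) {
      set.seed(s)
      noisy <- rec
      noisy$signal <- rec$signal + matrix(rnorm(length(rec$signal), 0, nl),
                                          nrow(rec$signal))
      score_windows(split_windows(noisy, 30), noisy)$bsqi[1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_bsqi) <= 0))

  # short windows score zero
  short <- split_windows(rec, 30)
  short$end_sample[1] <- short$start_sample[1] + 5 * 128
  expect_equal(score_windows(short[1, ], rec)$bsqi, 0)
})

test_that("exclusion rules reproduce hand-computed accounting", {
  # constructed fixture: 3 recordings, hand-set bsqi/VT flags
  mkw <- function(rid, pid, bsqi, vt) {
    data.frame(recording_id = rid, patient_id = pid,
               window_index = seq_along(bsqi) - 1L,
               start_sample = 0, end_sample = 1, duration_min = 30,
               lead_used = 1L, bsqi = bsqi, quality_ok = bsqi > 0.8,
               contains_vt = vt, stringsAsFactors = FALSE)
  }
  w <- rbind(
    # A: 5 good + 3 bad -> excluded by the six-window rule
    mkw("A", "p1", c(rep(0.9, 5), rep(0.5, 3)), rep(FALSE, 8)),
    # B (C1): 7 good of which 1 VT-window, 1 bad
    mkw("B", "p2", c(rep(0.95, 7), 0.2), c(TRUE, rep(FALSE, 7))),
    # C (C0): 6 good incl. one exactly at threshold (excluded), 1 VT overlap
    #         which does NOT drop windows in a C0 recording
    mkw("C", "p3", c(rep(0.85, 6), 0.8), c(rep(FALSE, 6), TRUE)))
  labels <- data.frame(recording_id = c("A", "B", "C"),
                       class_label = c("C0", "C1", "C0"))
  res <- apply_exclusions(w, labels)
  rep <- res$report
  expect_equal(rep$recording_excluded, c(TRUE, FALSE, FALSE))
  expect_equal(rep$n_windows_excluded_quality, c(3, 1, 1))
  expect_equal(rep$n_windows_excluded_vt, c(0, 1, 0))
  expect_equal(sort(unique(res$retained$recording_id)), c("B", "C"))
  expect_equal(nrow(res$retained), 6 + 6)   # B: 7-1 VT; C: 6 (0.8 excluded)
  m <- res$manifest
  expect_equal(m$windows_total,
               m$windows_retained + m$windows_excluded_quality +
                 m$windows_excluded_vt + m$windows_in_excluded_recordings)
  expect_equal(m$windows_in_excluded_recordings, 8)
  expect_equal(m$recordings_excluded, 1)
})

test_that("C1 VT windows are dropped, all-good recordings untouched", {
  w <- data.frame(recording_id = "D", patient_id = "p",
                  window_index = 0:3, start_sample = 0, end_sample = 1,
                  duration_min = 30, lead_used = 1L, bsqi = rep(0.9, 4),
                  quality_ok = TRUE,
                  contains_vt = c(FALSE, FALSE, TRUE, FALSE))
  labels <- data.frame(recording_id = "D", class_label = "C1")
  res <- apply_exclusions(w, labels, min_good_windows = 1)
  expect_equal(res$retained$window_index, c(0L, 1L, 3L))

  w$contains_vt <- FALSE
  res2 <- apply_exclusions(w, labels, min_good_windows = 1)
  expect_equal(nrow(res2$retained), 4L)
  expect_equal(res2$manifest$windows_excluded_quality, 0)
})
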