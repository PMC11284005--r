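test_that("compute_rr builds intervals with the range filter", {
  ann <- data.frame(r_sample = c(0, 1000, 2000, 3000), label = rep("N", 4))
  rr <- compute_rr(ann, 1000)
  expect_equal(rr$intervals_ms, c(1000, 1000, 1000))
  expect_true(all(rr$valid))

  ann2 <- data.frame(r_sample = c(0, 1000, 6000, 7000))
  rr2 <- compute_rr(ann2, 1000)
  expect_equal(rr2$valid, c(TRUE, FALSE, TRUE))

  expect_length(compute_rr(data.frame(r_sample = 1), 1000)$intervals_ms, 0)
})

test_that("time-domain HRV closed forms", {
  rr <- rr_series(rep(800, 20))
  h <- hrv_time(rr)
  expect_equal(unname(h["AVNN"]), 800)
  expect_equal(unname(h["SDNN"]), 0)
  expect_equal(unname(h["RMSSD"]), 0)
  expect_equal(unname(h["pNN50"]), 0)

  rr2 <- rr_series(rep(c(800, 850), 10))
  h2 <- hrv_time(rr2)
  expect_equal(unname(h2["RMSSD"]), 50)
  expect_equal(unname(h2["pNN50"]), 0)   # strict inequality
  expect_equal(unname(h2["pNN20"]), 1)

  set.seed(3)
  rr3 <- rr_series(rnorm(50, 900, 40))
  h3 <- hrv_time(rr3)
  expect_equal(unname(h3["SEM"]), unname(h3["SDNN"]) / sqrt(50))

  expect_true(all(is.na(hrv_time(rr_series(rep(800, 5))))))
})

test_that("fragmentation closed forms: ramp and perfect alternation", {
  ramp <- rr_series(seq(800, 980, by = 20))  # 10 intervals, increasing
  h <- hrv_fragmentation(ramp)
  expect_equal(unname(h["PIP"]), 0)
  expect_equal(unname(h["IALS"]), 1 / 9)
  expect_equal(unname(h["PAS"]), 0)
  expect_equal(unname(h["PSS"]), 0)

  alt <- rr_series(rep(c(800, 850), 5))      # 10 intervals alternating
  h2 <- hrv_fragmentation(alt)
  expect_equal(unname(h2["PIP"]), 8 / 10)    # (n-2)/n exactly
  expect_equal(unname(h2["PAS"]), 1)
  expect_equal(unname(h2["PSS"]), 1)
  expect_equal(unname(h2["IALS"]), 1)

  for (n in c(12, 20, 40)) {
    altn <- rr_series(rep(c(700, 760), n / 2))
    expect_equal(unname(hrv_fragmentation(altn)["PIP"]), (n - 2) / n)
  }
})

test_that("PIP decreases as the increment autocorrelation rises", {
  mean_pip <- vapply(c(-0.8, 0, 0.8), function(fc) {
    mean(vapply(1:20, function(s) {
      p <- base_profile(frag_coeff = fc, lf_amp = 0, hf_amp = 0)
      gt <- generate_rr_series(p, 0.25, seed = s)
      unname(hrv_fragmentation(rr_series(gt$rr_ms))["PIP"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_pip) < 0))
})

test_that("frequency-domain features localise sinusoidal RR modulation", {
  tms <- cumsum(rep(1, 400))
  lf <- rr_series(1000 + 50 * sin(2 * pi * 0.1 * tms))
  h <- hrv_frequency(lf)
  expect_gt(unname(h["LF_PWR"] / (h["LF_PWR"] + h["HF_PWR"])), 0.9)
  expect_gt(unname(h["LF_HF"]), 9)

  hf <- rr_series(1000 + 50 * sin(2 * pi * 0.25 * tms))
  h2 <- hrv_frequency(hf)
  expect_gt(unname(h2["HF_NORM"]), 90)

  expect_true(all(h[c("TOT_PWR", "VLF_PWR", "LF_PWR", "HF_PWR")] >= 0))
  # too short for spectral analysis -> missing
  expect_true(all(is.na(hrv_frequency(rr_series(rep(800, 20))))))
})

test_that("algebraic identities hold on random series", {
  set.seed(11)
  for (k in 1:50) {
    x <- rnorm(350, 1000, 60)
    rr <- rr_series(x)
    h <- c(hrv_time(rr), hrv_nonlinear(rr), hrv_frequency(rr))
    expect_lt(abs(h["SD1"] - h["RMSSD"] / sqrt(2)) / h["SD1"], 1e-9)
    expect_lt(abs(h["LF_NORM"] + h["HF_NORM"] - 100) / 100, 1e-9)
    expect_true(h["SD2"] >= 0)
  }
})

test_that("nonlinear features behave on reference processes", {
  a1 <- vapply(1:20, function(s) {
    set.seed(s)
    unname(hrv_nonlinear(rr_series(rnorm(500, 1000, 30)))["DFA_alpha1"])
  }, numeric(1))
  expect_lt(abs(mean(a1) - 0.5), 0.1)

  # constant series: SampEn degenerate -> missing
  h <- hrv_nonlinear(rr_series(rep(800, 150)))
  expect_true(is.na(h["SampEn"]))

  # SampEn agrees with a direct R reference implementation on a small case
  # (Richman-Moorman convention: both template lengths counted over the
  # same n - m start positions, self-matches excluded)
  set.seed(5)
  x <- rnorm(120, 1000, 30)
  r <- 0.2 * sd(x)
  n <- length(x); m <- 2L
  ref_count <- function(L) {
    cnt <- 0L
    for (i in 1:(n - m - 1)) for (j in (i + 1):(n - m)) {
      if (max(abs(x[i:(i + L - 1)] - x[j:(j + L - 1)])) <= r) cnt <- cnt + 1L
    }
    cnt
  }
  expect_equal(vtscreen:::sampen_cpp(x, m, r),
               -log(ref_count(m + 1L) / ref_count(m)))
})

test_that("morphology ratios partition the window's beats", {
  fx <- clean_beat_fixture()
  mo <- mor_features(fx$beats, fx$x, fx$fs)
  r <- mo[c("Nratio", "Sratio", "Vratio", "Fratio", "NoneRatio")]
  expect_equal(unname(sum(r)), 1)
  expect_equal(unname(mo["Vratio"]),
               mean(fx$beats$label == "V"))
  expect_gt(unname(mo["medianQRSint"]), 40)
  expect_gte(unname(mo["iqrQRSint"]), 0)
  expect_true(all(!is.na(mo[paste0(c("mean", "median", "min", "max", "iqr"),
                                   "Rwave")])))

  # too few classifiable beats: waveform summaries missing, ratios kept
  few <- fx$beats[1:4, ]
  mo2 <- mor_features(few, fx$x, fx$fs)
  expect_true(is.na(mo2["meanRwave"]))
  expect_false(is.na(mo2["Vratio"]))
})

test_that("window feature vector has the full published dimensionality", {
  fn <- feature_names()
  expect_length(fn$hrv, 23)
  expect_length(fn$mor, 115)
  expect_length(fn$pi, 4)
  expect_false(any(duplicated(c(fn$hrv, fn$mor, fn$pi))))

  fx <- clean_beat_fixture()
  fv <- window_features(fx$x, fx$fs, fx$det)
  expect_length(fv, 138)
  expect_true(all(c(fn$hrv, fn$mor) %in% names(fv)))
})

test_that("feature assembly broadcasts PI, orders rows, rejects duplicates", {
  fn <- feature_names()
  mkrow <- function(rid, wi) {
    v <- as.data.frame(t(stats::setNames(rnorm(138), c(fn$hrv, fn$mor))),
                       check.names = FALSE)
    cbind(data.frame(patient_id = sub("_R.*", "", rid), recording_id = rid,
                     window_index = wi, gt_pvc_fraction = 0), v)
  }
  meta <- data.frame(recording_id = c("p1_R01", "p2_R01"),
                     class_label = c("C0", "C1"), age = c(60, 70),
                     sex = c("M", "F"), bmi = c(25, 30),
                     smoking = c(TRUE, FALSE))
  ft <- assemble_features(list(mkrow("p2_R01", 0), mkrow("p1_R01", 0),
                               mkrow("p1_R01", 1)), meta)
  expect_equal(nrow(ft), 3)
  expect_equal(ft$patient_id, c("p1", "p1", "p2"))
  expect_equal(ft$sex, c(1L, 1L, 0L))
  expect_equal(ft$smoking, c(1L, 1L, 0L))
  expect_length(variant_columns(ft, "PI"), 4)
  expect_length(variant_columns(ft, "HRV"), 23)
  expect_length(variant_columns(ft, "MOR"), 115)
  expect_length(variant_columns(ft, "PI+HRV+MOR"), 142)

  expect_error(assemble_features(list(mkrow("p1_R01", 0), mkrow("p1_R01", 0)),
                                 meta), "duplicate")
})

test_that("no feature depends on the class label (leakage guard)", {
  fn <- feature_names()
  mkrow <- function(rid) {
    set.seed(1)  # identical feature content regardless of label
    v <- as.data.frame(t(stats::setNames(rnorm(138), c(fn$hrv, fn$mor))),
                       check.names = FALSE)
    cbind(data.frame(patient_id = rid, recording_id = paste0(rid, "_R01"),
                     window_index = 0, gt_pvc_fraction = 0), v)
  }
  meta1 <- data.frame(recording_id = "p1_R01", class_label = "C0", age = 60,
                      sex = "M", bmi = 25, smoking = FALSE)
  meta2 <- meta1; meta2$class_label <- "C1"
  f1 <- assemble_features(list(mkrow("p1")), meta1)
  f2 <- assemble_features(list(mkrow("p1")), meta2)
  cols <- c(fn$hrv, fn$mor, fn$pi)
  expect_identical(f1[cols], f2[cols])
})
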