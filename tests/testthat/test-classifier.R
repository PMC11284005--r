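test_that("outer splits are patient-disjoint, sized and deterministic", {
  pts <- data.frame(patient_id = sprintf("P%04d", 1:1619),
                    class_label = rep(c("C1", "C0"), c(49, 1570)))
  plan <- make_splits(pts, outer_repeats = 10, seed = 3)
  expect_length(plan$repeats, 10)
  expect_equal(plan$n_test_c1, 10)
  expect_equal(plan$n_test_c0, 130)
  lab <- stats::setNames(pts$class_label, pts$patient_id)
  for (rp in plan$repeats) {
    expect_length(intersect(rp$test_patients, rp$train_patients), 0)
    expect_equal(sum(lab[rp$test_patients] == "C1"), 10)
    expect_equal(sum(lab[rp$test_patients] == "C0"), 130)
    expect_equal(length(rp$test_patients) + length(rp$train_patients), 1619)
  }
  expect_identical(plan, make_splits(pts, outer_repeats = 10, seed = 3))

  # small cohorts scale to ceiling(0.2 * class size)
  small <- data.frame(patient_id = sprintf("p%03d", 1:50),
                      class_label = rep(c("C1", "C0"), c(10, 40)))
  plan2 <- make_splits(small, outer_repeats = 2, seed = 1)
  expect_equal(plan2$n_test_c1, ceiling(0.2 * 10))
  expect_equal(plan2$n_test_c0, ceiling(0.2 * 40))
  expect_error(make_splits(small[1:2, ], outer_repeats = 1), "too few")
})

test_that("inner folds are patient-disjoint and cover everyone", {
  pts <- data.frame(patient_id = sprintf("q%02d", 1:37),
                    class_label = rep(c("C1", "C0"), c(9, 28)))
  folds <- vtscreen:::inner_folds(pts, 4L, seed = 5)
  expect_length(folds, 4)
  all_ids <- unlist(folds)
  expect_setequal(all_ids, pts$patient_id)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("mRMR ranks the informative feature first and skips its copy", {
  set.seed(21)
  X <- data.frame(inf = c(rnorm(150, 0), rnorm(150, 2)))
  X$copy <- X$inf
  for (k in 1:8) X[[paste0("noise", k)]] <- rnorm(300)
  y <- rep(c(0, 1), each = 150)
  sel <- mrmr_select(X, y, energy = 0.9)
  expect_equal(sel[1], "inf")
  expect_false("copy" %in% sel[1:2])

  all_order <- mrmr_select(X, y, energy = 1.0)
  expect_setequal(all_order, names(X))
  expect_equal(mrmr_select(X["inf"], y, 0.4), "inf")
  expect_error(mrmr_select(X, y, energy = 0), "energy")
  expect_error(mrmr_select(X, y, energy = 1.5), "energy")
})

test_that("patient aggregation is the median, order-invariant", {
  expect_equal(vtscreen:::patient_median(c(0.2, 0.9, 0.4),
                                         rep("a", 3))[["a"]], 0.4)
  expect_equal(vtscreen:::patient_median(c(0.2, 0.9, 0.4, 0.6),
                                         rep("a", 4))[["a"]], 0.5)
  set.seed(1)
  pr <- runif(9); id <- rep(c("a", "b", "c"), 3)
  o <- sample(9)
  expect_equal(vtscreen:::patient_median(pr, id),
               vtscreen:::patient_median(pr[o], id[o]))
})

test_that("training learns a separable synthetic table and is deterministic", {
  ft <- make_feature_table(n_c0 = 24, n_c1 = 10, windows = 3, seed = 2)
  te_ids <- c(sprintf("P%03d", 20:24), sprintf("P%03d", 30:34))  # both classes
  tr <- ft[!ft$patient_id %in% te_ids, ]
  te <- ft[ft$patient_id %in% te_ids, ]
  m1 <- vt_train(tr, variant = "HRV+MOR", search_iterations = 5, seed = 7)
  expect_s3_class(m1, "vt_model")
  expect_true(all(m1$selected_features %in% variant_columns(tr, "HRV+MOR")))
  expect_gt(m1$inner_auroc, 0.8)

  ps <- score_patients(m1, te)
  expect_true(all(ps$score >= 0 & ps$score <= 1))
  expect_gte(auroc(ps$score, ps$class_label == "C1"), 0.9)

  m2 <- vt_train(tr, variant = "HRV+MOR", search_iterations = 5, seed = 7)
  expect_identical(m1$hyperparams, m2$hyperparams)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_equal(predict(m1, te), predict(m2, te))
})

test_that("imputation is fitted on training data only and fills NAs", {
  ft <- make_feature_table(n_c0 = 10, n_c1 = 6, windows = 2, seed = 4)
  ft$SampEn[1:5] <- NA
  m <- vt_train(ft, variant = "HRV", search_iterations = 3, seed = 1)
  expect_false(anyNA(predict(m, ft)))
  expect_equal(unname(m$imputation_medians[["SampEn"]]),
               stats::median(ft$SampEn, na.rm = TRUE))
})

test_that("single-class inner folds score 0.5 with a warning", {
  ft <- make_feature_table(n_c0 = 12, n_c1 = 0, windows = 2, seed = 5)
  ft$class_label <- "C0"
  fd <- list(list(Xtr = ft[1:12, c("Vratio", "PIP")],
                  ytr = rep(0L, 12),
                  Xva = ft[13:20, c("Vratio", "PIP")],
                  pid_va = ft$patient_id[13:20],
                  plab_va = stats::setNames(
                    rep("C0", 4), unique(ft$patient_id[13:20])),
                  rank = vtscreen:::mrmr_rank(ft[1:12, c("Vratio", "PIP")],
                                              rep(0L, 12))))
  cfg <- vtscreen:::space_transform(matrix(0.5, 1, 8),
                                    vtscreen:::default_hyper_space())
  expect_warning(sc <- vtscreen:::score_config(cfg, fd), "single class")
  expect_equal(sc, 0.5)
})
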