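#' Build the outer train/test split plan
#'
#' Ten (by default) independent patient-level splits: per repeat,
#' `n_test_c1` C1 and `n_test_c0` C0 patients form the test set and all
#' remaining patients the training set.  All recordings and windows of a
#' patient stay on one side (no information leakage).  When a class is too
#' small for its default test count, the count scales to
#' `ceiling(0.2 * class size)`.
#'
#' @param patients data frame `patient_id`, `class_label`.
#' @param outer_repeats number of outer repeats.
#' @param n_test_c1,n_test_c0 test-set patient counts per class.
#' @param seed integer seed.
#' @return A `vt_split_plan`: list of repeats, each with `test_patients`
#'   and `train_patients`.
#' @export
make_splits <- function(patients, outer_repeats = 10, n_test_c1 = 10,
                        n_test_c0 = 130, seed = 1L) {
  patients <- unique(patients[c("patient_id", "class_label")])
  ids1 <- patients$patient_id[patients$class_label == "C1"]
  ids0 <- patients$patient_id[patients$class_label == "C0"]
  scale_count <- function(n_default, n_class) {
    if (n_default <= floor(n_class / 2)) n_default
    else ceiling(0.2 * n_class)
  }
  k1 <- scale_count(n_test_c1, length(ids1))
  k0 <- scale_count(n_test_c0, length(ids0))
  if (k1 < 1 || k0 < 1 || k1 >= length(ids1) || k0 >= length(ids0))
    vt_abort("too few patients per class for a train/test split")
  reps <- with_seed(derive_seed(seed, "splits"), {
    lapply(seq_len(outer_repeats), function(r) {
      test <- c(sample(ids1, k1), sample(ids0, k0))
      list(repeat_id = r, test_patients = test,
           train_patients = setdiff(patients$patient_id, test))
    })
  })
  structure(list(repeats = reps, n_test_c1 = k1, n_test_c0 = k0,
                 seed = seed), class = "vt_split_plan")
}

# Patient-disjoint inner folds, classes spread round-robin across folds.
inner_folds <- function(patients, k = 4L, seed = 1L) {
  with_seed(seed, {
    folds <- vector("list", k)
    for (cl in unique(patients$class_label)) {
      ids <- sample(patients$patient_id[patients$class_label == cl])
      f <- rep(seq_len(k), length.out = length(ids))
      for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], ids[f == j])
    }
    folds
  })
}
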