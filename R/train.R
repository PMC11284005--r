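# Hyperparameter space for the gradient-boosted window classifier.  Each
# entry: lower, upper, and whether the dimension is searched on the log
# scale / rounded to an integer.
default_hyper_space <- function() {
  list(
    nrounds          = list(lo = 50, hi = 300, log = FALSE, int = TRUE),
    max_depth        = list(lo = 2, hi = 8, log = FALSE, int = TRUE),
    eta              = list(lo = 0.01, hi = 0.3, log = TRUE, int = FALSE),
    subsample        = list(lo = 0.5, hi = 1, log = FALSE, int = FALSE),
    colsample_bytree = list(lo = 0.5, hi = 1, log = FALSE, int = FALSE),
    min_child_weight = list(lo = 1, hi = 20, log = TRUE, int = FALSE),
    scale_pos_weight = list(lo = 1, hi = 30, log = TRUE, int = FALSE),
    mrmr_energy      = list(lo = 0.3, hi = 1, log = FALSE, int = FALSE)
  )
}

# Map a [0,1]^d matrix into the hyperparameter space.
space_transform <- function(U, space) {
  out <- as.data.frame(U)
  names(out) <- names(space)
  for (nm in names(space)) {
    s <- space[[nm]]
    x <- if (s$log) exp(log(s$lo) + out[[nm]] * (log(s$hi) - log(s$lo)))
         else s$lo + out[[nm]] * (s$hi - s$lo)
    if (s$int) x <- round(x)
    out[[nm]] <- x
  }
  out
}

fit_booster <- function(X, y, cfg) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = cfg$max_depth, eta = cfg$eta,
                  subsample = cfg$subsample,
                  colsample_bytree = cfg$colsample_bytree,
                  min_child_weight = cfg$min_child_weight,
                  scale_pos_weight = cfg$scale_pos_weight,
                  nthread = 1,
                  seed = 1),  # fixed: xgboost otherwise draws from the R RNG
    data = dtrain, nrounds = cfg$nrounds, verbose = 0)
}

predict_booster <- function(bst, X)
  stats::predict(bst, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1))

impute_fit <- function(X) vapply(X, function(c) stats::median(c, na.rm = TRUE),
                                 numeric(1))

impute_apply <- function(X, med) {
  for (nm in names(X)) {
    x <- X[[nm]]
    x[is.na(x)] <- if (is.na(med[[nm]])) 0 else med[[nm]]
    X[[nm]] <- x
  }
  X
}

patient_median <- function(prob, patient_id) {
  sp <- split(prob, patient_id)
  vapply(sp, stats::median, numeric(1))
}

# Score one hyperparameter configuration by inner patient-disjoint CV.
score_config <- function(cfg, fold_data) {
  aucs <- vapply(fold_data, function(fd) {
    feats <- mrmr_prefix(fd$rank, cfg$mrmr_energy)
    bst <- fit_booster(fd$Xtr[feats], fd$ytr, cfg)
    prob <- predict_booster(bst, fd$Xva[feats])
    ps <- patient_median(prob, fd$pid_va)
    plab <- fd$plab_va[names(ps)]
    if (length(unique(plab)) < 2L) {
      vt_warn("inner fold with a single class; scored 0.5")
      return(0.5)
    }
    auroc(ps, plab == "C1")
  }, numeric(1))
  mean(aucs)
}

#' Train the window-level VT classifier with nested tuning
#'
#' Runs a sequential model-based (Bayesian) hyperparameter search --- Latin
#' hypercube initialisation followed by a random-forest surrogate with an
#' upper-confidence-bound acquisition --- over tree-ensemble parameters and
#' the mRMR energy threshold.  Each configuration is scored by 4-fold
#' patient-disjoint inner cross-validation on the patient-level AUROC
#' (median window probability per patient); the best configuration is then
#' refit on all training windows.
#'
#' @param features a `vt_features` training table.
#' @param variant feature-set variant (see [variant_columns()]).
#' @param search_iterations total configurations evaluated.
#' @param folds inner folds.
#' @param seed integer seed; the whole search is deterministic given it.
#' @param space hyperparameter space (see `default_hyper_space`).
#' @return A `vt_model`: booster, selected features, imputation medians,
#'   chosen hyperparameters, inner AUROC trace.
#' @export
vt_train <- function(features, variant = "HRV+MOR", search_iterations = 50,
                     folds = 4L, seed = 1L, space = default_hyper_space()) {
  cols <- variant_columns(features, variant)
  y <- as.integer(features$class_label == "C1")
  patients <- unique(features[c("patient_id", "class_label")])
  fold_ids <- inner_folds(patients, folds, derive_seed(seed, "folds"))

  # per-fold fixed artefacts: imputation, mRMR ranking (config-independent)
  fold_data <- lapply(fold_ids, function(va_pat) {
    tr <- !(features$patient_id %in% va_pat)
    Xtr <- features[tr, cols]; Xva <- features[!tr, cols]
    med <- impute_fit(Xtr)
    Xtr <- impute_apply(Xtr, med); Xva <- impute_apply(Xva, med)
    list(Xtr = Xtr, ytr = y[tr], Xva = Xva,
         pid_va = features$patient_id[!tr],
         plab_va = stats::setNames(patients$class_label,
                                   patients$patient_id)[
                     unique(features$patient_id[!tr])],
         rank = mrmr_rank(Xtr, y[tr]))
  })

  d <- length(space)
  n_init <- max(4L, min(search_iterations, ceiling(search_iterations / 3)))
  U <- with_seed(derive_seed(seed, "lhs"),
                 lhs::randomLHS(n_init, d))
  configs <- space_transform(U, space)
  scores <- numeric(0)
  for (i in seq_len(nrow(configs)))
    scores[i] <- score_config(configs[i, ], fold_data)
  Umat <- U

  it <- nrow(configs)
  while (it < search_iterations) {
    it <- it + 1L
    cand_u <- with_seed(derive_seed(seed, paste0("cand", it)),
                        matrix(stats::runif(300 * d), ncol = d))
    sur <- ranger::ranger(
      y = scores, x = as.data.frame(Umat), num.trees = 200,
      seed = derive_seed(seed, "surrogate"), num.threads = 1)
    pr <- stats::predict(sur, as.data.frame(cand_u), predict.all = TRUE,
                         num.threads = 1)$predictions
    acq <- rowMeans(pr) + apply(pr, 1L, stats::sd)
    u_next <- cand_u[which.max(acq), , drop = FALSE]
    cfg <- space_transform(u_next, space)
    configs <- rbind(configs, cfg)
    Umat <- rbind(Umat, u_next)
    scores[it] <- score_config(configs[it, ], fold_data)
  }

  best <- which.max(scores)
  best_cfg <- configs[best, ]
  med <- impute_fit(features[cols])
  Xall <- impute_apply(features[cols], med)
  rk <- mrmr_rank(Xall, y)
  feats <- mrmr_prefix(rk, best_cfg$mrmr_energy)
  bst <- fit_booster(Xall[feats], y, best_cfg)
  imp <- tryCatch(xgboost::xgb.importance(model = bst),
                  error = function(e) NULL)
  structure(list(booster = bst, selected_features = feats,
                 imputation_medians = med, hyperparams = best_cfg,
                 variant = variant, seed = seed,
                 inner_auroc = scores[best], search_trace = scores,
                 importance = imp),
            class = "vt_model")
}

#' @export
print.vt_model <- function(x, ...) {
  cat("VT window classifier (", x$variant, "): ",
      length(x$selected_features), " features, inner AUROC ",
      sprintf("%.3f", x$inner_auroc), "\n", sep = "")
  cat("hyperparameters:",
      paste(names(x$hyperparams),
            signif(unlist(x$hyperparams), 3), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict window probabilities from a trained model
#'
#' @param object a `vt_model`.
#' @param newdata a `vt_features` table.
#' @param ... unused.
#' @return Numeric vector of window-level VT probabilities.
#' @export
predict.vt_model <- function(object, newdata, ...) {
  X <- impute_apply(newdata[names(object$imputation_medians)],
                    object$imputation_medians)
  predict_booster(object$booster, X[object$selected_features])
}

#' Aggregate window probabilities to patient scores
#'
#' The patient score is the median probability over all of the patient's
#' retained windows (across all their recordings); invariant to window
#' order.  Patients with zero retained windows are dropped with a warning.
#'
#' @param model a `vt_model`.
#' @param features a `vt_features` table of test windows.
#' @return Data frame `patient_id`, `score`, `class_label`.
#' @export
score_patients <- function(model, features) {
  if (!nrow(features)) vt_abort("no windows to score")
  prob <- predict(model, features)
  ps <- patient_median(prob, features$patient_id)
  lab <- stats::setNames(features$class_label, features$patient_id)
  data.frame(patient_id = names(ps), score = unname(ps),
             class_label = unname(lab[names(ps)]), stringsAsFactors = FALSE)
}
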