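#' Area under the ROC curve
#'
#' Rank-based (Mann--Whitney) AUROC with midrank tie handling:
#' `U / (n1 * n0)`, the probability that a random positive outranks a random
#' negative (ties count one half).
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) positive-class indicator.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) vt_abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mann--Whitney screening of features between classes
#'
#' Two-sided Mann--Whitney U test per feature on per-recording values (the
#' median over the recording's retained windows), exact when both groups
#' have at most 8 observations and no ties, otherwise the tie-corrected
#' normal approximation.  No multiple-testing correction by default,
#' matching a flat P < 0.05 criterion; Benjamini--Hochberg is available.
#'
#' @param features a `vt_features` table (window level).
#' @param feature_cols columns to screen (default: all feature columns).
#' @param alpha significance cut-off.
#' @param aggregate `"median"` or `"mean"` across a recording's windows.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame sorted by p-value: feature, class medians, U,
#'   p-value, significance flag.
#' @export
mann_whitney_screen <- function(features, feature_cols = NULL, alpha = 0.05,
                                aggregate = c("median", "mean"),
                                adjust = c("none", "BH")) {
  aggregate <- match.arg(aggregate)
  adjust <- match.arg(adjust)
  if (is.null(feature_cols)) {
    fn <- feature_names()
    feature_cols <- intersect(c(fn$pi, fn$hrv, fn$mor), names(features))
  }
  aggfun <- if (aggregate == "median") stats::median else mean
  rec <- lapply(split(features, features$recording_id), function(w) {
    vals <- vapply(feature_cols,
                   function(cc) aggfun(w[[cc]][!is.na(w[[cc]])]), numeric(1))
    c(list(class_label = w$class_label[1L]), as.list(vals))
  })
  rec <- do.call(rbind, lapply(rec, as.data.frame))
  is1 <- rec$class_label == "C1"
  if (!any(is1) || all(is1)) vt_abort("both classes must be present")

  rows <- lapply(feature_cols, function(cc) {
    x0 <- rec[[cc]][!is1]; x1 <- rec[[cc]][is1]
    x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
    if (length(x0) < 2L || length(x1) < 2L ||
        (stats::sd(c(x0, x1)) == 0)) {
      u <- length(x0) * length(x1) / 2; p <- 1
    } else {
      exact <- length(x0) <= 8L && length(x1) <= 8L &&
        !any(duplicated(c(x0, x1)))
      wt <- suppressWarnings(
        stats::wilcox.test(x1, x0, exact = exact, correct = !exact))
      u <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(feature = cc, c0_median = stats::median(x0),
               c1_median = stats::median(x1), U = u, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}

# ROC curve (FPR/TPR) and its vertical interpolation on a common FPR grid.
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o]); fp <- cumsum(!labels[o])
  data.frame(fpr = c(0, fp / sum(!labels)), tpr = c(0, tp / sum(labels)))
}

interp_roc <- function(curve, grid) {
  stats::approx(curve$fpr, curve$tpr, xout = grid, ties = max,
                yleft = 0, yright = 1)$y
}

#' Evaluate model variants under the outer resampling
#'
#' For each outer repeat: train on the training patients' windows
#' ([vt_train()], with its inner 4-fold patient-disjoint tuning), score the
#' held-out patients ([score_patients()]) and record the patient-level
#' AUROC.
#'
#' @param features full `vt_features` table.
#' @param variants character vector of feature-set variants.
#' @param plan a `vt_split_plan` from [make_splits()].
#' @param search_iterations configurations per tuning search.
#' @param seed integer seed.
#' @return A `vt_eval` object (see [build_report()]).
#' @export
vt_evaluate <- function(features, variants = "HRV+MOR", plan,
                        search_iterations = 50, seed = 1L) {
  results <- list()
  for (v in variants) {
    per_rep <- lapply(plan$repeats, function(rp) {
      tr <- features[features$patient_id %in% rp$train_patients, ]
      te <- features[features$patient_id %in% rp$test_patients, ]
      stopifnot(length(intersect(tr$patient_id, te$patient_id)) == 0L)
      model <- vt_train(tr, variant = v,
                        search_iterations = search_iterations,
                        seed = derive_seed(seed, paste0(v, rp$repeat_id)))
      ps <- score_patients(model, te)
      list(auroc = auroc(ps$score, ps$class_label == "C1"),
           roc = roc_curve(ps$score, ps$class_label == "C1"),
           importance = model$importance,
           n_features = length(model$selected_features))
    })
    results[[v]] <- per_rep
  }
  build_report(results)
}

#' Summarise per-repeat results into an evaluation report
#'
#' Mean and sample SD of the patient-level AUROC per variant over the outer
#' repeats, pooled ROC curves (median and interquartile envelope by vertical
#' averaging on a 101-point FPR grid) and averaged feature importances.
#'
#' @param results per-variant list of per-repeat results (AUROC + ROC).
#' @return A `vt_eval` object.
#' @export
build_report <- function(results) {
  grid <- seq(0, 1, length.out = 101L)
  variants <- names(results)
  table_rows <- list(); rocs <- list(); importances <- list()
  per_repeat <- list()
  for (v in variants) {
    aucs <- vapply(results[[v]], `[[`, numeric(1), "auroc")
    if (length(aucs) == 1L) vt_warn("single outer repeat; SD reported as 0")
    tprs <- vapply(results[[v]], function(r) interp_roc(r$roc, grid),
                   numeric(length(grid)))
    tprs <- matrix(tprs, nrow = length(grid))
    rocs[[v]] <- data.frame(
      fpr = grid,
      tpr_median = apply(tprs, 1L, stats::median),
      tpr_q1 = apply(tprs, 1L, stats::quantile, 0.25),
      tpr_q3 = apply(tprs, 1L, stats::quantile, 0.75))
    imp <- lapply(results[[v]], `[[`, "importance")
    imp <- imp[!vapply(imp, function(d) is.null(d) || nrow(d) == 0,
                       logical(1))]
    if (length(imp)) {
      gain <- do.call(rbind, lapply(imp, function(d)
        data.frame(feature = d$Feature, gain = d$Gain)))
      ag <- stats::aggregate(gain$gain, list(feature = gain$feature), mean)
      importances[[v]] <- ag[order(-ag$x), ]
      names(importances[[v]])[2L] <- "mean_gain"
    }
    table_rows[[v]] <- data.frame(
      variant = v, mean_auroc = mean(aucs),
      sd_auroc = if (length(aucs) > 1L) stats::sd(aucs) else 0,
      n_repeats = length(aucs), stringsAsFactors = FALSE)
    per_repeat[[v]] <- aucs
  }
  structure(list(table = do.call(rbind, table_rows), roc = rocs,
                 importance = importances, per_repeat = per_repeat),
            class = "vt_eval")
}

#' @export
print.vt_eval <- function(x, ...) {
  cat("Patient-level test AUROC (mean ± SD over outer repeats):\n")
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %-12s %.3f ± %.3f  (%d repeats)\n",
                x$table$variant[i], x$table$mean_auroc[i],
                x$table$sd_auroc[i], x$table$n_repeats[i]))
  invisible(x)
}

#' @export
summary.vt_eval <- function(object, ...) {
  print(object)
  for (v in names(object$importance)) {
    top <- utils::head(object$importance[[v]], 5L)
    cat("top features (", v, "): ",
        paste(top$feature, collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}

#' Plot pooled ROC curves with interquartile envelopes
#'
#' @param x a `vt_eval`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vt_eval <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
                 ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  cols <- grDevices::hcl.colors(max(length(x$roc), 2L), "Dark 2")
  for (i in seq_along(x$roc)) {
    rc <- x$roc[[i]]
    graphics::polygon(c(rc$fpr, rev(rc$fpr)), c(rc$tpr_q1, rev(rc$tpr_q3)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(rc$fpr, rc$tpr_median, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(x$roc), col = cols,
                   lwd = 2, bty = "n")
  invisible(x)
}
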