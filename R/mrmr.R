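# Mutual information between two discrete codes (natural log).  Codes must
# be small positive integers; joint counts via tabulate for speed.
mi_disc <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  ka <- max(a); kb <- max(b)
  n <- length(a)
  if (n == 0) return(0)
  joint <- tabulate(a + ka * (b - 1L), nbins = ka * kb) / n
  pa <- tabulate(a, nbins = ka) / n
  pb <- tabulate(b, nbins = kb) / n
  pp <- outer(pa, pb)
  idx <- joint > 0
  sum(joint[idx] * log(joint[idx] / pp[idx]))
}

# Quantile-discretise a numeric matrix into `bins` codes (per column).
discretise <- function(X, bins = 10L) {
  apply(X, 2L, function(col) {
    br <- unique(stats::quantile(col, probs = seq(0, 1, length.out = bins + 1L),
                                 na.rm = TRUE, type = 7))
    if (length(br) < 2L) return(rep(1L, length(col)))
    findInterval(col, br, rightmost.closed = TRUE, all.inside = TRUE)
  })
}

# Full greedy mRMR ranking: relevance = MI(feature, label), redundancy =
# mean MI with already-selected features.  Returns the order plus each
# feature's relevance, so any energy prefix can be cut without re-ranking.
mrmr_rank <- function(X, y, bins = 10L) {
  Xd <- discretise(as.matrix(X), bins)
  y <- as.integer(factor(y))
  p <- ncol(Xd)
  rel <- vapply(seq_len(p), function(j) mi_disc(Xd[, j], y), numeric(1))
  names(rel) <- colnames(X)
  sel <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)
  while (length(remaining)) {
    if (!length(sel)) {
      pick <- remaining[which.max(rel[remaining])]
    } else {
      score <- rel[remaining] - red_sum[remaining] / length(sel)
      pick <- remaining[which.max(score)]
    }
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) mi_disc(Xd[, j], Xd[, pick]), numeric(1))
  }
  list(order = colnames(X)[sel], relevance = rel)
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy mRMR ranking over quantile-discretised features (mutual
#' information relevance minus mean mutual information with the selected
#' set), cut at the smallest prefix whose cumulative relevance reaches
#' `energy` times the total relevance.
#'
#' @param X numeric feature data frame/matrix (no missing values).
#' @param y class labels.
#' @param energy fraction of total relevance to retain, in (0, 1].
#' @param bins discretisation bins.
#' @return Ordered character vector of selected feature names.
#' @export
mrmr_select <- function(X, y, energy = 1.0, bins = 10L) {
  if (energy <= 0 || energy > 1) vt_abort("energy must be in (0, 1]")
  if (ncol(X) == 1L) return(colnames(X))
  rk <- mrmr_rank(X, y, bins)
  mrmr_prefix(rk, energy)
}

mrmr_prefix <- function(rk, energy) {
  cumrel <- cumsum(rk$relevance[rk$order])
  total <- cumrel[length(cumrel)]
  if (total <= 0) return(rk$order)
  k <- which(cumrel >= energy * total)[1L]
  rk$order[seq_len(max(k, 1L))]
}
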