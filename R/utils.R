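#' @useDynLib vtscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Clamp a numeric vector to [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Derive a per-stage seed from a global seed and a stage tag, so every stage
# is independently reproducible.  Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}

# Evaluate expr with the RNG state restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Interquartile range with midpoint (type 7) interpolation, Q3 - Q1.
iqr7 <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))

vt_abort <- function(...) stop(..., call. = FALSE)

vt_warn <- function(...) warning(..., call. = FALSE)
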