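## Candidate normalization strategies for heterogeneous cross-experiment
## z-value data, plus the distribution diagnostics used to compare them.

#' Rank-based inverse-normal (Gaussian) transform
#'
#' Maps the value with rank i (1-based, average ranks for ties) to the
#' standard-normal quantile at (i - offset) / n. Forces an essentially
#' standard-normal distribution, compressing heavy tails while preserving rank
#' order; used per experiment before aggregating z-values across experiments.
#'
#' @param values Numeric vector, length >= 2, finite.
#' @param offset Rank offset in (0, 1); default 0.5.
#' @return Numeric vector of transformed values, same order as the input.
#' @export
gaussian_transform <- function(values, offset = 0.5) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("need at least 2 numeric values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0 || offset >= 1)
    stop("offset must lie in (0, 1)")
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / length(values))
}

#' Signed logarithmic transform
#'
#' The odd function sign(x) * log(1 + |x|); compresses large magnitudes while
#' keeping the sign of each z-value (a plain log would be undefined for the
#' negative half).
#'
#' @param values Numeric vector, finite.
#' @return Transformed vector.
#' @export
log_transform <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric")
  if (any(!is.finite(values))) stop("values must be finite")
  sign(values) * log1p(abs(values))
}

#' Quantile normalization of a genes-by-samples matrix
#'
#' Every column's sorted values are replaced by the reference distribution
#' (the row-wise mean of all columns' sorted values), preserving within-column
#' rank order. Ties within a column receive the mean of the reference values
#' their rank span covers.
#'
#' @param mat Numeric matrix, >= 2 rows and >= 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix")
  if (ncol(mat) < 2L)
    stop("quantile normalization needs >= 2 columns")
  if (nrow(mat) < 2L) stop("quantile normalization needs >= 2 rows")
  if (any(!is.finite(mat))) stop("values must be finite")
  ref <- rowMeans(apply(mat, 2, sort))
  cref <- c(0, cumsum(ref))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    rmin <- rank(mat[, j], ties.method = "min")
    rmax <- rank(mat[, j], ties.method = "max")
    out[, j] <- (cref[rmax + 1L] - cref[rmin]) / (rmax - rmin + 1L)
  }
  out
}

#' Distribution diagnostics for a vector of values
#'
#' Reports, for each requested closed interval, the fraction of values inside
#' it, together with the negative:positive percentage split (values equal to
#' zero count as positive) and the extremes. Used to compare normalization
#' strategies.
#'
#' @param values Nonempty numeric vector.
#' @param intervals List of length-2 numeric vectors \code{c(lo, hi)} with
#'   \code{lo <= hi}; may be empty.
#' @return Object of class \code{"distribution_report"}: a list with
#'   \code{n}, \code{fraction_in} (named by interval), \code{neg_pos_ratio}
#'   (percentages summing to 100), and \code{extremes}.
#' @export
distribution_report <- function(values, intervals = list()) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("values must be a nonempty numeric vector")
  if (any(!is.finite(values))) stop("values must be finite")
  frac <- vapply(intervals, function(iv) {
    if (length(iv) != 2L || !is.numeric(iv)) stop("intervals must be numeric pairs")
    if (iv[1] > iv[2]) stop("interval lower bound exceeds upper bound")
    mean(values >= iv[1] & values <= iv[2])
  }, numeric(1))
  names(frac) <- vapply(intervals, function(iv)
    sprintf("[%g,%g]", iv[1], iv[2]), character(1))
  neg <- 100 * mean(values < 0)
  structure(
    list(n = length(values), fraction_in = frac,
         neg_pos_ratio = c(negative = neg, positive = 100 - neg),
         extremes = range(values)),
    class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  cat(sprintf("Distribution report (n = %d)\n", x$n))
  cat(sprintf("  range: [%.4g, %.4g]\n", x$extremes[1], x$extremes[2]))
  cat(sprintf("  negative:positive = %.1f:%.1f\n",
              x$neg_pos_ratio[1], x$neg_pos_ratio[2]))
  for (nm in names(x$fraction_in))
    cat(sprintf("  fraction in %s: %.3f\n", nm, x$fraction_in[[nm]]))
  invisible(x)
}
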