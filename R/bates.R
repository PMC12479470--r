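## Bates rank test: the sorting-rescaling rank cascade that maps per-gene
## z-scores onto an equally spaced grid in [-1, 1], the Bates / Irwin-Hall
## null distribution for the mean of the overlapping genes' ranks, and the
## test itself.

#' Sorting-rescaling rank cascade
#'
#' Maps per-gene z-scores onto an equally spaced grid spanning exactly
#' [-1, 1]: (i) each z gets an infinitesimal push away from the interval
#' midpoint, r = z +/- 1e-50; (ii) r is folded, r' = -1 - r for r <= 0 and
#' 1 - r for r > 0; (iii) r' values are sorted ascending (ties broken by gene
#' identifier) and assigned unique ranks 1..n; (iv) ranks are rescaled
#' affinely to r''' = -1 + 2 (rank - 1) / (n - 1). The fold in step (ii)
#' places genes with extreme |z| mid-scale and genes near zero at the
#' endpoints; the cascade is applied exactly as defined, and the null for a
#' mean of random draws from the resulting grid is (asymptotically) the Bates
#' distribution on [-1, 1].
#'
#' @param z_m Named numeric vector of z-scores (>= 2 genes, finite).
#' @return Named numeric vector of r''' values: all distinct, mean zero,
#'   spanning exactly [-1, 1].
#' @export
bates_rank_cascade <- function(z_m) {
  if (!is.numeric(z_m) || length(z_m) < 2L)
    stop("need >= 2 genes")
  if (is.null(names(z_m)) || anyDuplicated(names(z_m)))
    stop("z_m must be uniquely named by gene")
  if (any(!is.finite(z_m))) stop("z_m must be finite")
  r <- ifelse(z_m >= 0, z_m + 1e-50, z_m - 1e-50)
  rp <- ifelse(r <= 0, -1 - r, 1 - r)
  n <- length(z_m)
  o <- order(rp, names(z_m))
  r2 <- integer(n)
  r2[o] <- seq_len(n)
  setNames(-1 + 2 * (r2 - 1) / (n - 1), names(z_m))
}

# CDF of the Irwin-Hall distribution (sum of n iid uniforms on [0,1]) at s,
# by the alternating closed form. The sum is only evaluated on the lower half
# s <= n/2, where it has few terms and tolerable cancellation; the upper half
# uses the symmetry F(s) = 1 - F(n - s). Accurate in double precision for
# n <= ~50.
irwin_hall_cdf <- function(s, n) {
  vapply(s, function(si) {
    if (si <= 0) return(0)
    if (si >= n) return(1)
    if (si > n / 2) return(1 - irwin_hall_cdf(n - si, n))
    k <- 0:floor(si)
    terms <- exp(lchoose(n, k) + n * log(si - k) - lfactorial(n))
    min(max(sum(terms * (-1)^k), 0), 1)
  }, numeric(1))
}

#' Bates distribution function
#'
#' CDF of the arithmetic mean of n independent uniform variables on the
#' interval spanned by \code{a} and \code{b} (default [-1, 1]). Uses the
#' Irwin-Hall closed form after an affine map to [0, 1] for n <= 50 and the
#' normal approximation (mean = interval midpoint, variance = range^2 / (12 n))
#' beyond, where the closed form's alternating sum loses precision; the two
#' branches agree to ~1e-3 at the switch.
#'
#' @param x Quantile(s).
#' @param n Number of uniforms (>= 1).
#' @param a,b Interval endpoints; defaults 1 and -1.
#' @return Probability in [0, 1], vectorized over \code{x}.
#' @export
bates_cdf <- function(x, n, a = 1, b = -1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  lo <- min(a, b); hi <- max(a, b)
  if (lo >= hi) stop("interval endpoints must differ")
  if (any(!is.finite(x))) stop("x must be finite")
  if (n <= 50L) {
    irwin_hall_cdf(n * (x - lo) / (hi - lo), n)
  } else {
    pnorm(x, mean = (lo + hi) / 2, sd = sqrt((hi - lo)^2 / 12 / n))
  }
}

#' Bates rank test of a signature against a DEG set
#'
#' Applies \code{\link{bates_rank_cascade}} to the continuous PRGS z-scores,
#' averages the r''' values of the genes shared with \code{degs} to the mean
#' rank R(G), and evaluates it against the Bates null on [-1, 1] with n equal
#' to the overlap size: p = batesCDF(R, n) for R at or below the midpoint and
#' 1 - batesCDF(-R, n) above it (the reflection about the midpoint; the two
#' branches coincide for the symmetric null).
#'
#' @param prgs_continuous Named numeric vector: the continuous PRGS
#'   (gene -> z-score).
#' @param degs Character vector of DEG identifiers; must intersect the
#'   signature.
#' @return List with \code{method = "bates"}, \code{statistic} (the mean rank
#'   R(G)), \code{p_value}, \code{n_set}, \code{n_overlap}, \code{details}
#'   (the overlapping genes' r''' values).
#' @export
bates_test <- function(prgs_continuous, degs) {
  if (!is.numeric(prgs_continuous) || is.null(names(prgs_continuous)))
    stop("prgs_continuous must be a named numeric vector")
  overlap <- intersect(names(prgs_continuous), unique(as.character(degs)))
  if (length(overlap) == 0L)
    stop("no overlap between PRGS and DEG set")
  r3 <- bates_rank_cascade(prgs_continuous)
  R <- mean(r3[overlap])
  n <- length(overlap)
  p <- if (R <= 0) bates_cdf(R, n) else 1 - bates_cdf(-R, n)
  list(method = "bates", statistic = R, p_value = p,
       n_set = length(prgs_continuous), n_overlap = n,
       details = list(r3 = r3[overlap]))
}
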