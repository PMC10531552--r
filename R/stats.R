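# Cohort statistics: product-moment correlation (with the point-biserial
# special case), ordinary least squares, and the Wilcoxon signed-rank test
# with exact small-sample p-values by sign enumeration.

#' Pearson product-moment correlation with a t-test p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3), both non-constant.
#' @return List with `r`, `p` (two-sided, from the t transform with n - 2
#'   degrees of freedom; 0 when |r| = 1) and `n`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("correlation undefined for constant input")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a binary and a continuous variable, computed
#' by coding the binary variable 0/1 — they are mathematically identical,
#' and the identity is what the tests pin.
#'
#' @param binary vector with exactly two observed levels (logical, 0/1
#'   numeric, or 2-level factor/character; levels are coded in sort order).
#' @param continuous numeric vector of the same length.
#' @return As [pearson_cor].
#' @export
point_biserial <- function(binary, continuous) {
  lev <- sort(unique(as.vector(binary)))
  if (length(lev) != 2L)
    stop("`binary` must contain exactly two distinct levels")
  pearson_cor(as.double(match(binary, lev) - 1L), continuous)
}

#' Ordinary least-squares simple linear regression
#'
#' @param x,y numeric vectors, n >= 3, `x` non-constant.
#' @return List with `slope`, `intercept`, `r_squared` (equal to the squared
#'   Pearson correlation) and `n`.
#' @export
linear_regression <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 points")
  dx <- x - mean(x)
  sxx <- sum(dx^2)
  if (sxx == 0) stop("regression undefined for constant x")
  slope <- sum(dx * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy == 0) 1 else (slope^2 * sxx) / syy
  list(slope = slope, intercept = intercept, r_squared = r2, n = n)
}

# distribution of 2*W+ over all sign assignments for given |d| ranks
# (ranks doubled so midranks become integers); returns probability vector
# indexed 0..sum(2*ranks)
.signed_rank_dist <- function(ranks2) {
  total <- sum(ranks2)
  pr <- numeric(total + 1L)
  pr[1L] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), pr[seq_len(total + 1L - r)])
    pr <- (pr + shifted) / 2
  }
  pr
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped (classical convention, not Pratt); absolute
#' differences are ranked with midranks for ties; the reported statistic is
#' W = min(W+, W-). For effective n <= `exact_limit` the two-sided p-value
#' is exact: P(min(W+, W-) <= W_obs) under the null that signs are
#' independent fair coin flips, computed from the full sign-assignment
#' distribution. Beyond that, a normal approximation with tie correction and
#' a 0.5 continuity correction is used.
#'
#' @param pre,post equal-length paired numeric vectors.
#' @param exact_limit largest effective n for exact enumeration (default 15).
#' @return List with `w` (min of the signed-rank sums), `n_effective`
#'   (non-zero differences), `p` (two-sided), `method` (`"exact"`,
#'   `"normal"` or `"degenerate"`).
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_limit = 15L) {
  if (length(pre) != length(post)) stop("paired vectors must match in length")
  if (!length(pre)) stop("need at least one pair")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(w = 0, n_effective = 0L, p = 1, method = "degenerate"))
  }
  rk <- rank(abs(d)) # midranks for ties
  w_plus <- sum(rk[d > 0])
  w_minus <- sum(rk) - w_plus
  w <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * rk))
    pr <- .signed_rank_dist(ranks2)
    total <- sum(ranks2)
    w2 <- as.integer(round(2 * w))
    lo <- sum(pr[seq_len(w2 + 1L)])                  # P(2W+ <= 2w)
    hi <- sum(pr[seq.int(total - w2 + 1L, total + 1L)]) # P(2W+ >= total-2w)
    p <- min(1, if (total - w2 <= w2) 1 else lo + hi)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(w = w, n_effective = n, p = p, method = method)
}
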