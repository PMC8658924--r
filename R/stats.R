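#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic step-up adjustment: sort p-values, multiply by `n/rank`, take the
#' cumulative minimum from the largest rank downwards, cap at 1, and return in
#' the input order. Ties share the adjusted value; the output dominates the
#' input elementwise and is monotone in it.
#'
#' @param p numeric vector of p-values, each in (0, 1], finite, length >= 1.
#' @return Adjusted p-values in the order of `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must be finite and in (0, 1]", call. = FALSE)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[order(o)]
}

#' Ordinary least-squares slope test
#'
#' Simple linear regression `y = a + b*t` with the two-sided Student-t test of
#' `b = 0` on `n - 2` degrees of freedom, evaluated in closed form
#' (`b = Sty/Stt`, `se = sqrt(RSS/(n-2)/Stt)`). A numerically zero residual
#' sum of squares (a perfect line) yields the smallest positive normalized
#' double as p-value rather than 0, so downstream FDR adjustment stays finite.
#'
#' @param y numeric response, length >= 3.
#' @param t numeric covariate (time, hours), same length, not constant.
#' @return Named list: `intercept`, `slope`, `p_value`.
#' @export
ols_slope_test <- function(y, t) {
  n <- length(y)
  if (n < 3L || length(t) != n)
    stop("need >= 3 paired observations", call. = FALSE)
  tc <- t - mean(t)
  Stt <- sum(tc^2)
  if (Stt == 0) stop("time covariate is constant", call. = FALSE)
  b <- sum(tc * y) / Stt
  a <- mean(y) - b * mean(t)
  rss <- sum((y - a - b * t)^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 1e-20 * n * max(mean(y^2), 1e-300)) {
    # constant response: no evidence about the slope at all
    b <- 0; p <- 1
  } else if (rss <= 1e-12 * tss) {
    # perfect nonconstant fit: zero residual, keep p positive
    p <- .Machine$double.xmin
  } else {
    se <- sqrt(rss / (n - 2) / Stt)
    p <- 2 * stats::pt(abs(b / se), df = n - 2, lower.tail = FALSE)
  }
  list(intercept = a, slope = b, p_value = p)
}

#' Upper-tail chi-squared probability
#'
#' `P[X > x]` for `X ~ chi-squared(df)`; continuous and strictly decreasing in
#' `x`, equal to 1 at `x = 0` and to `exp(-x/2)` when `df = 2`.
#'
#' @param x nonnegative statistic (vectorized).
#' @param df positive integer degrees of freedom.
#' @return Upper-tail probabilities in (0, 1].
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("chi-squared statistic must be finite and nonnegative", call. = FALSE)
  if (length(df) != 1L || df < 1 || df != round(df))
    stop("df must be a positive integer", call. = FALSE)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

# Vectorized per-row OLS slope test for a probes x samples matrix: the same
# closed form as ols_slope_test, evaluated with matrix algebra. Returns one
# row per probe.
row_ols_slope_test <- function(X, t) {
  n <- ncol(X)
  if (n < 3L) stop("need >= 3 samples", call. = FALSE)
  tc <- t - mean(t)
  Stt <- sum(tc^2)
  if (Stt == 0) stop("time covariate is constant", call. = FALSE)
  b <- as.vector(X %*% tc) / Stt
  ybar <- rowMeans(X)
  a <- ybar - b * mean(t)
  rss <- rowSums((X - ybar - outer(b, tc))^2)
  tss <- rowSums((X - ybar)^2)
  se <- sqrt(rss / (n - 2) / Stt)
  tstat <- b / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  constant <- tss <= 1e-20 * n * pmax(rowMeans(X^2), 1e-300)
  perfect <- !constant & rss <= 1e-12 * tss
  b[constant] <- 0; tstat[constant] <- 0; p[constant] <- 1
  p[perfect] <- .Machine$double.xmin
  tstat[perfect] <- sign(b[perfect]) * Inf
  data.frame(intercept = a, slope = b, t_statistic = tstat, p_value = p)
}
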