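#' Per-probe linear-regression feature extraction (baseline)
#'
#' The conventional comparison method: for every probe independently, ordinary
#' least squares of expression on incubation time (`x[i, j] = a_i + b_i*t_j`),
#' a two-sided Student-t test of the slope, Benjamini-Hochberg adjustment
#' across probes, and selection at adjusted p strictly below `alpha_probe`.
#' Expression values are regressed as stored; `standardize_first = TRUE`
#' applies the column standardization of [standardize()] beforehand (the
#' alternative reading of the method), and the choice is recorded in the
#' result's `standardize_first` attribute so reports stay auditable.
#'
#' @param m an [expression_matrix()] holding a single arm (>= 3 samples,
#'   >= 2 distinct times).
#' @param alpha_probe selection threshold on the adjusted p-value
#'   (default 0.01).
#' @param standardize_first standardize columns before regressing
#'   (default `FALSE`).
#' @return data.frame, one row per probe in input order: `probe_id`,
#'   `intercept`, `slope`, `statistic` (squared t), `p_value`, `adjusted_p`,
#'   `selected`.
#' @export
run_linreg_fe <- function(m, alpha_probe = 0.01, standardize_first = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 3L) stop("need >= 3 samples", call. = FALSE)
  if (length(unique(m$time_h)) < 2L)
    stop("all time values identical; cannot regress on time", call. = FALSE)
  X <- if (standardize_first) standardize(m)$values else m$values
  fit <- row_ols_slope_test(X, m$time_h)
  adj <- bh_adjust(fit$p_value)
  out <- data.frame(probe_id = probe_ids(m),
                    intercept = fit$intercept, slope = fit$slope,
                    statistic = fit$t_statistic^2,
                    p_value = fit$p_value, adjusted_p = adj,
                    selected = adj < alpha_probe, row.names = NULL)
  attr(out, "standardize_first") <- standardize_first
  attr(out, "alpha_probe") <- alpha_probe
  out
}
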