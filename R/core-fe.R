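#' Standardize an expression matrix column-wise
#'
#' Each sample column is centered across probes and rescaled so that its sum
#' of squares equals the number of probes: after standardization
#' `sum_i x[i, j] = 0` and `sum_i x[i, j]^2 = n_probes` for every sample `j`.
#' This is the conventional preprocessing for the SVD-as-PCA reading in which
#' probes are observations and samples are variables.
#'
#' @param m an [expression_matrix()].
#' @return A `StandardizedMatrix`: like the input, with standardized `values`
#'   and an `n_probes` field.
#' @export
standardize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  n <- nrow(v)
  centered <- sweep(v, 2L, colMeans(v))
  ss <- colSums(centered^2)
  if (any(ss == 0))
    stop("zero-variance sample column(s): ",
         paste(colnames(v)[ss == 0], collapse = ", "), call. = FALSE)
  out <- sweep(centered, 2L, sqrt(ss / n), "/")
  structure(list(values = out, condition = m$condition, time_h = m$time_h,
                 n_probes = n),
            class = c("StandardizedMatrix", "ExpressionMatrix"))
}

#' Singular value decomposition of a standardized matrix
#'
#' Full thin SVD `X = U D V'` with components ordered by descending singular
#' value. The left singular vectors (columns of `U`, over probes) are the
#' principal-component scores of the probes; the right singular vectors
#' (columns of `V`, over samples) are the sample loadings. Signs are fixed
#' deterministically: each probe-score column is oriented so that its
#' largest-magnitude entry is positive. All downstream statistics are
#' invariant to this choice (squares and two-sided tests only).
#'
#' @param sm a `StandardizedMatrix` from [standardize()] (any
#'   `ExpressionMatrix` with finite values is accepted).
#' @return A `DecompositionResult`: list with `singular_values`,
#'   `probe_scores` (probes x components), `sample_loadings`
#'   (samples x components), plus the sample metadata carried through.
#' @export
decompose <- function(sm) {
  stopifnot(inherits(sm, "ExpressionMatrix"))
  v <- sm$values
  if (any(!is.finite(v))) stop("matrix contains non-finite values", call. = FALSE)
  s <- svd(v)
  for (l in seq_along(s$d)) {
    i <- which.max(abs(s$u[, l]))
    if (s$u[i, l] < 0) {
      s$u[, l] <- -s$u[, l]
      s$v[, l] <- -s$v[, l]
    }
  }
  k <- length(s$d)
  comp <- paste0("PC", seq_len(k))
  dimnames(s$u) <- list(rownames(v), comp)
  dimnames(s$v) <- list(colnames(v), comp)
  structure(list(singular_values = s$d, probe_scores = s$u,
                 sample_loadings = s$v,
                 condition = sm$condition, time_h = sm$time_h),
            class = "DecompositionResult")
}

#' Regress sample loadings on time to find time-associated components
#'
#' For each component, the sample-loading vector is regressed on incubation
#' time by ordinary least squares (`v[l, j] = a_l + b_l * t_j`) and the slope
#' is tested two-sided. P-values are Benjamini-Hochberg adjusted across all
#' components; a component is selected when its adjusted p-value is strictly
#' below `alpha_component`.
#'
#' @param d a [decompose()] result.
#' @param time_h per-sample times in hours; defaults to the metadata carried
#'   in `d`. At least 3 samples and 2 distinct times are required.
#' @param alpha_component selection threshold on the adjusted p-value
#'   (default 0.05).
#' @param time_scale `"hours"` regresses on raw hours; `"log2_hours"` on
#'   `log2(t)` (times must then be positive).
#' @return data.frame: `component`, `intercept`, `slope`, `p_value`,
#'   `adjusted_p`, `selected`, one row per component in decreasing
#'   singular-value order (component index is 1-based).
#' @export
associate_components_with_time <- function(d, time_h = d$time_h,
                                           alpha_component = 0.05,
                                           time_scale = c("hours", "log2_hours")) {
  stopifnot(inherits(d, "DecompositionResult"))
  time_scale <- match.arg(time_scale)
  if (length(time_h) < 3L) stop("need >= 3 samples", call. = FALSE)
  t_reg <- switch(time_scale, hours = time_h, log2_hours = {
    if (any(time_h <= 0)) stop("log2 time scale needs positive times", call. = FALSE)
    log2(time_h)
  })
  if (length(unique(t_reg)) < 2L)
    stop("all time values identical; cannot regress on time", call. = FALSE)
  fits <- lapply(seq_len(ncol(d$sample_loadings)), function(l)
    ols_slope_test(d$sample_loadings[, l], t_reg))
  p <- vapply(fits, `[[`, numeric(1), "p_value")
  adj <- bh_adjust(p)
  data.frame(
    component = seq_along(fits),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    p_value = p,
    adjusted_p = adj,
    selected = adj < alpha_component,
    row.names = NULL
  )
}

#' Score probes on the selected components with a chi-squared statistic
#'
#' Under the null, the probe scores `u[l, i]` of a component are taken to be
#' Gaussian with mean zero; the standardized squared score
#' `(u[l, i]/sigma_l)^2` is then chi-squared with 1 degree of freedom, and the
#' sum over the selected components is chi-squared with `df = `number of
#' selected components. `sigma_l` is, by default, the root mean square of the
#' component's probe scores about zero (`sigma_mode = "rms"`); the
#' mean-subtracted standard deviation (`"sd"`) differs negligibly because the
#' probe scores of a column-centered matrix have mean approximately zero.
#' Probe p-values are the chi-squared upper tail, Benjamini-Hochberg adjusted
#' across probes, with selection at adjusted p strictly below `alpha_probe`.
#'
#' @param d a [decompose()] result.
#' @param selected integer vector of 1-based component indices to score on;
#'   must be nonempty.
#' @param alpha_probe selection threshold on the adjusted p-value
#'   (default 0.01).
#' @param sigma_mode `"rms"` (root mean square about zero, default) or `"sd"`
#'   (sample standard deviation).
#' @return data.frame: `probe_id`, `statistic`, `p_value`, `adjusted_p`,
#'   `selected`, one row per probe in input order, with attributes `sigma`
#'   (named per-component scale) and `df`.
#' @export
score_probes <- function(d, selected, alpha_probe = 0.01,
                         sigma_mode = c("rms", "sd")) {
  stopifnot(inherits(d, "DecompositionResult"))
  sigma_mode <- match.arg(sigma_mode)
  if (!length(selected))
    stop("no time-associated component: probe scoring needs at least one ",
         "selected component (an empty selection at pipeline level is the ",
         "expected outcome for a control-like arm)", call. = FALSE)
  selected <- as.integer(selected)
  if (any(selected < 1L | selected > ncol(d$probe_scores)))
    stop("component index out of range", call. = FALSE)
  u <- d$probe_scores[, selected, drop = FALSE]
  sigma <- switch(sigma_mode,
                  rms = sqrt(colMeans(u^2)),
                  sd = apply(u, 2L, stats::sd))
  if (any(sigma <= 0)) stop("component score scale sigma must be positive", call. = FALSE)
  stat <- rowSums(sweep(u, 2L, sigma, "/")^2)
  p <- chi2_upper_tail(stat, df = length(selected))
  adj <- bh_adjust(p)
  out <- data.frame(probe_id = rownames(d$probe_scores),
                    statistic = stat, p_value = p, adjusted_p = adj,
                    selected = adj < alpha_probe, row.names = NULL)
  attr(out, "sigma") <- stats::setNames(sigma, paste0("PC", selected))
  attr(out, "df") <- length(selected)
  out
}

#' PCA-based unsupervised feature extraction for a time course
#'
#' The full pipeline for one experimental arm: standardize the probes x
#' samples matrix, decompose it, regress every sample-loading component on
#' time, and, if any component is time-associated at `alpha_component`, score
#' all probes on those components and select at `alpha_probe`. When no
#' component is time-associated (the expected outcome for a control arm whose
#' expression does not develop in time) the result carries an empty selection
#' and status `"no_time_associated_component"` rather than an error.
#'
#' @param m an [expression_matrix()] holding a single arm.
#' @param alpha_component component-level threshold on BH-adjusted p
#'   (default 0.05).
#' @param alpha_probe probe-level threshold on BH-adjusted p (default 0.01).
#' @param single_component if `TRUE`, restrict scoring to the single most
#'   significant passing component even when several pass.
#' @param sigma_mode,time_scale passed to [score_probes()] and
#'   [associate_components_with_time()].
#' @return A `pca_fe_result` list: `standardized`, `decomposition`,
#'   `associations`, `scores` (zero-row table when nothing is selected),
#'   `selected_components`, `status` (`"ok"` or
#'   `"no_time_associated_component"`), and the thresholds used.
#' @export
run_pca_fe <- function(m, alpha_component = 0.05, alpha_probe = 0.01,
                       single_component = FALSE,
                       sigma_mode = c("rms", "sd"),
                       time_scale = c("hours", "log2_hours")) {
  sigma_mode <- match.arg(sigma_mode)
  time_scale <- match.arg(time_scale)
  sm <- standardize(m)
  d <- decompose(sm)
  assoc <- associate_components_with_time(d, alpha_component = alpha_component,
                                          time_scale = time_scale)
  sel <- assoc$component[assoc$selected]
  if (single_component && length(sel) > 1L)
    sel <- sel[which.min(assoc$adjusted_p[sel])]
  if (length(sel)) {
    scores <- score_probes(d, sel, alpha_probe = alpha_probe,
                           sigma_mode = sigma_mode)
    status <- "ok"
  } else {
    scores <- data.frame(probe_id = character(), statistic = numeric(),
                         p_value = numeric(), adjusted_p = numeric(),
                         selected = logical())
    status <- "no_time_associated_component"
  }
  structure(list(standardized = sm, decomposition = d, associations = assoc,
                 scores = scores, selected_components = sel, status = status,
                 alpha_component = alpha_component, alpha_probe = alpha_probe,
                 sigma_mode = sigma_mode, time_scale = time_scale),
            class = "pca_fe_result")
}

#' @export
print.pca_fe_result <- function(x, ...) {
  cat("PCA-based unsupervised feature extraction\n")
  cat(sprintf("  components tested: %d; time-associated (BH < %g): %s\n",
              nrow(x$associations), x$alpha_component,
              if (length(x$selected_components))
                paste(x$selected_components, collapse = ", ") else "none"))
  if (x$status == "ok") {
    cat(sprintf("  probes selected (BH < %g): %d of %d\n", x$alpha_probe,
                sum(x$scores$selected), nrow(x$scores)))
  } else {
    cat("  status: no time-associated component; empty probe selection\n")
  }
  invisible(x)
}
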