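#' Expression matrix with per-sample condition and time metadata
#'
#' The central container of the package: a numeric probes x samples matrix
#' together with, for every sample column, an experimental condition
#' (`"treated"` or `"control"`) and an incubation time in hours. Probe and
#' sample identifiers are carried as the matrix dimnames and must be unique.
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row and
#'   column names are used as probe and sample identifiers; if absent they may
#'   be supplied through `probe_ids` / `sample_ids`.
#' @param condition character vector, one entry per sample, each `"treated"`
#'   or `"control"`.
#' @param time_h numeric vector, one entry per sample, nonnegative finite
#'   hours.
#' @param probe_ids,sample_ids optional identifier vectors overriding the
#'   dimnames of `values`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `condition`, `time_h`.
#' @examples
#' m <- expression_matrix(matrix(rnorm(12), 3, 4,
#'                               dimnames = list(paste0("p", 1:3), paste0("s", 1:4))),
#'                        condition = c("treated", "control", "treated", "control"),
#'                        time_h = c(1, 1, 48, 48))
#' split_by_condition(m)$treated
#' @export
expression_matrix <- function(values, condition, time_h,
                              probe_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.null(probe_ids)) rownames(values) <- probe_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("probe and sample identifiers are required (dimnames or explicit ids)",
         call. = FALSE)
  condition <- as.character(condition)
  time_h <- as.numeric(time_h)
  obj <- structure(list(values = values, condition = condition, time_h = time_h),
                   class = "ExpressionMatrix")
  validate_expression_matrix(obj)
}

validate_expression_matrix <- function(x) {
  v <- x$values
  if (anyDuplicated(rownames(v))) stop("probe ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(v))) stop("sample ids must be unique", call. = FALSE)
  n <- ncol(v)
  if (length(x$condition) != n || length(x$time_h) != n)
    stop("condition and time_h must have one entry per sample", call. = FALSE)
  bad <- setdiff(unique(x$condition), c("treated", "control"))
  if (length(bad))
    stop("condition labels must be 'treated' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(x$time_h)) || any(x$time_h < 0))
    stop("time_h must be finite and nonnegative for every sample", call. = FALSE)
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tb <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  cat("  time points (h):", paste(sort(unique(x$time_h)), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Split an expression matrix by experimental condition
#'
#' Partitions the sample columns into the treated and the control arm. Probe
#' order is preserved and identical in both arms; sample order within each arm
#' follows the input. Each arm is analysed separately downstream: the
#' decomposition is never run on a mixed-condition matrix.
#'
#' @param m an [expression_matrix()].
#' @param conditions which arms to return; requesting an arm with zero samples
#'   is an error.
#' @return Named list of `ExpressionMatrix` objects, one per requested
#'   condition.
#' @export
split_by_condition <- function(m, conditions = c("treated", "control")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  conditions <- match.arg(conditions, several.ok = TRUE)
  out <- lapply(conditions, function(cond) {
    keep <- which(m$condition == cond)
    if (!length(keep))
      stop("no samples with condition '", cond, "'", call. = FALSE)
    expression_matrix(m$values[, keep, drop = FALSE],
                      condition = m$condition[keep],
                      time_h = m$time_h[keep])
  })
  names(out) <- conditions
  out
}

#' Replicate layout of the collagen-glycosaminoglycan time course
#'
#' The sample design of the GEO series GSE6432 (IMR90 fibroblasts, treated =
#' contact with collagen-glycosaminoglycan mesh): replicate counts per time
#' point for each arm. These counts are the default design of the synthetic
#' generator.
#'
#' @return data.frame with columns `condition`, `time_h`, `n_replicates`.
#' @export
gse6432_design <- function() {
  data.frame(
    condition = rep(c("treated", "control"), each = 7L),
    time_h = rep(c(1, 2, 4, 8, 12, 24, 48), 2L),
    n_replicates = c(3L, 2L, 3L, 4L, 3L, 2L, 2L,
                     1L, 2L, 3L, 2L, 3L, 1L, 1L)
  )
}
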