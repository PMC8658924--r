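#' Specification of a synthetic two-arm time-course dataset
#'
#' The generator's world: a probes x samples matrix per arm with the replicate
#' layout of the collagen-glycosaminoglycan time course ([gse6432_design()]),
#' per-probe Gaussian baseline offsets shared between arms, i.i.d. Gaussian
#' measurement noise, and — in the treated arm only — a minority of planted
#' probes whose expression follows a linear trend in raw hours with slope
#' `+/- slope_scale` (random sign). The default `slope_scale` is
#' `3 * noise_sd / 48`: the planted trend spans three noise standard
#' deviations over the 48-hour course.
#'
#' @param n_probes number of probes (desk-scale default 2000; the platform's
#'   full 22283 remains available for fidelity runs).
#' @param replicate_counts named list with elements `treated` and `control`,
#'   each a named numeric vector mapping time in hours to a positive replicate
#'   count. Default: the GSE6432 layout.
#' @param signal_fraction fraction of probes planted with a trend, in (0, 1);
#'   `round(signal_fraction * n_probes)` must be >= 1. Use `null_model = TRUE`
#'   for a no-signal world — a zero fraction is rejected so that type-I
#'   experiments are explicit.
#' @param slope_scale magnitude of planted slopes, expression units per hour;
#'   default `3 * noise_sd / 48`.
#' @param noise_sd standard deviation of the measurement noise (default 1).
#' @param baseline_sd standard deviation of the per-probe baseline offsets
#'   (default 1).
#' @param seed integer RNG seed; generation is fully reproducible from it.
#' @param null_model if `TRUE`, plant nothing (global null) while keeping the
#'   rest of the spec intact.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_probes = 2000L,
                           replicate_counts = NULL,
                           signal_fraction = 0.02,
                           slope_scale = NULL,
                           noise_sd = 1,
                           baseline_sd = 1,
                           seed = 1L,
                           null_model = FALSE) {
  if (is.null(replicate_counts)) {
    des <- gse6432_design()
    replicate_counts <- lapply(split(des, des$condition), function(d)
      stats::setNames(d$n_replicates, d$time_h))[c("treated", "control")]
  }
  if (is.null(slope_scale)) slope_scale <- 3 * noise_sd / 48
  spec <- structure(list(n_probes = as.integer(n_probes),
                         replicate_counts = replicate_counts,
                         signal_fraction = signal_fraction,
                         slope_scale = slope_scale, noise_sd = noise_sd,
                         baseline_sd = baseline_sd, seed = as.integer(seed),
                         null_model = isTRUE(null_model)),
                    class = "synthetic_spec")
  problems <- character()
  if (!isTRUE(spec$n_probes >= 2L)) problems <- c(problems, "n_probes must be >= 2")
  for (arm in c("treated", "control")) {
    rc <- spec$replicate_counts[[arm]]
    if (is.null(rc) || !length(rc) || any(rc < 1) || any(rc != round(rc)))
      problems <- c(problems, paste0(arm, " replicate counts must be positive integers"))
    else if (any(as.numeric(names(rc)) <= 0) || anyNA(as.numeric(names(rc))))
      problems <- c(problems, paste0(arm, " time points must be positive hours"))
  }
  if (!isTRUE(spec$signal_fraction > 0 && spec$signal_fraction < 1))
    problems <- c(problems, "signal_fraction must be in (0, 1)")
  else if (round(spec$signal_fraction * spec$n_probes) < 1)
    problems <- c(problems, "signal_fraction * n_probes rounds to zero planted probes")
  if (!isTRUE(spec$slope_scale > 0)) problems <- c(problems, "slope_scale must be > 0")
  if (!isTRUE(spec$noise_sd > 0)) problems <- c(problems, "noise_sd must be > 0")
  if (!isTRUE(spec$baseline_sd >= 0)) problems <- c(problems, "baseline_sd must be >= 0")
  if (is.na(spec$seed)) problems <- c(problems, "seed must be an integer")
  if (length(problems))
    stop("invalid synthetic spec: ", paste(problems, collapse = "; "),
         call. = FALSE)
  spec
}

#' Generate a synthetic two-arm time-course dataset
#'
#' Draws, reproducibly from `spec$seed`:
#' `x[i, j] = baseline_i + b_i * t_j * [treated & i planted] + noise`, with
#' `baseline_i ~ N(0, baseline_sd^2)` shared between arms,
#' `noise ~ N(0, noise_sd^2)` i.i.d., and planted slopes `b_i = +/-
#' slope_scale` with random sign. The control arm is never planted.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `treated` and `control` [expression_matrix()] objects
#'   (identical probe ids) and `truth`: list with `planted_probe_ids`,
#'   `true_slope` (named, planted probes only), `probe_ids` (the full
#'   universe), `spec`, `seed`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_probes
  probes <- sprintf("probe_%05d", seq_len(n))
  baseline <- stats::rnorm(n, 0, spec$baseline_sd)
  if (spec$null_model) {
    planted <- integer()
    slopes <- numeric()
  } else {
    planted <- sort(sample.int(n, round(spec$signal_fraction * n)))
    slopes <- sample(c(-1, 1), length(planted), replace = TRUE) * spec$slope_scale
  }
  make_arm <- function(arm, prefix) {
    rc <- spec$replicate_counts[[arm]]
    times <- rep(as.numeric(names(rc)), rc)
    ns <- length(times)
    x <- matrix(stats::rnorm(n * ns, 0, spec$noise_sd), n, ns) + baseline
    if (arm == "treated" && length(planted))
      x[planted, ] <- x[planted, ] + outer(slopes, times)
    dimnames(x) <- list(probes, sprintf("%s%02d", prefix, seq_len(ns)))
    expression_matrix(x, condition = rep(arm, ns), time_h = times)
  }
  treated <- make_arm("treated", "T")
  control <- make_arm("control", "C")
  truth <- list(planted_probe_ids = probes[planted],
                true_slope = stats::setNames(slopes, probes[planted]),
                probe_ids = probes, spec = spec, seed = spec$seed)
  list(treated = treated, control = control, truth = truth)
}

#' Recovery metrics of a probe selection against planted truth
#'
#' @param selected_probe_ids character vector of selected probe ids; must be
#'   a subset of the generated dataset's probe universe.
#' @param truth the `truth` element of [generate_synthetic()].
#' @return Named list `recall`, `precision`, `f1`, each in `[0, 1]`.
#'   Precision is `NA` (undefined) for an empty selection against a nonempty
#'   planted set; both metrics are 1 when selection and planted set are both
#'   empty. `f1` is the harmonic mean when defined.
#' @export
evaluate_recovery <- function(selected_probe_ids, truth) {
  selected_probe_ids <- unique(as.character(selected_probe_ids))
  stray <- setdiff(selected_probe_ids, truth$probe_ids)
  if (length(stray))
    stop("selected probe ids not in the dataset: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  planted <- truth$planted_probe_ids
  hits <- length(intersect(selected_probe_ids, planted))
  if (!length(planted) && !length(selected_probe_ids))
    return(list(recall = 1, precision = 1, f1 = 1))
  recall <- if (length(planted)) hits / length(planted) else 1
  precision <- if (length(selected_probe_ids)) hits / length(selected_probe_ids)
               else NA_real_
  f1 <- if (!is.na(precision) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else
    if (!is.na(precision)) 0 else NA_real_
  list(recall = recall, precision = precision, f1 = f1)
}
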