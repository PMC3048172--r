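# One-at-a-time parameter ranking and two-parameter grid analyses.
#
# All sweeps run in well-mixed mode (exact for the homogeneous tumors they
# study, and fast); grid points are independent of each other. The swept
# outputs are the free-growth rate constant k and the percent volume
# reduction after the default preoperative schedule.

sweepable_parameters <- c("Tc", "T_G0", "T_N", "T_A", "R_A", "R_ADiff",
                          "R_NDiff", "P_G0toG1", "N_LIMP", "P_sym",
                          "P_sleep", "CKR_total")

#' Default biologically plausible sweep ranges
#'
#' Per-parameter (low, high) ranges used by [rank_parameters()]. For the
#' parameters that genuinely vary across the packaged virtual-tumor
#' scenarios the range is the scenario span widened by 20 percent
#' (\code{Tc}, \code{T_G0}, \code{P_sym}, \code{P_sleep},
#' \code{CKR_total}); the remaining parameters use moderate
#' (roughly factor-two) perturbations around their reference values, since
#' the isolated extreme values that individual fitted scenarios assign to
#' e.g. the differentiated-cell death rates describe one particular tumor
#' rather than a typical plausible range. All ranges are overridable.
#'
#' @return Named list of two-element numeric ranges.
#' @export
default_sweep_ranges <- function() {
  list(Tc = c(20, 58), T_G0 = c(34, 102), T_N = c(10, 40), T_A = c(3, 12),
       R_A = c(0.0005, 0.002), R_ADiff = c(0.0015, 0.006),
       R_NDiff = c(0.0005, 0.002), P_G0toG1 = c(0.005, 0.02),
       N_LIMP = c(1, 5), P_sym = c(0.42, 0.79), P_sleep = c(0.27, 0.41),
       CKR_total = c(0.48, 0.72))
}

# build a parameter set with one named value replaced; CKR_total is swept by
# scaling both drug CKRs proportionally, durations/N_LIMP are rounded by the
# constructor
perturbed_parameters <- function(base, parameter, value) {
  raw <- base[c("Tc", "T_G0", "T_N", "T_A", "R_A", "R_ADiff", "R_NDiff",
                "P_G0toG1", "N_LIMP", "P_sym", "P_sleep",
                "CKR_VCR", "CKR_ACT")]
  if (parameter == "CKR_total") {
    f <- value / (base$CKR_VCR + base$CKR_ACT)
    raw$CKR_VCR <- min(1, base$CKR_VCR * f)
    raw$CKR_ACT <- min(1, base$CKR_ACT * f)
  } else raw[[parameter]] <- value
  build_parameters(raw)
}

sweep_output <- function(params, selector, schedule, free_hours) {
  if (selector == "growth_rate") {
    res <- run_simulation(1, params,
                          treatment_schedule(horizon_h = free_hours))
    fit_growth_rate(res)$k
  } else {
    sch <- default_siop_schedule(ckr_vcr = params$CKR_VCR,
                                 ckr_act = params$CKR_ACT)
    if (!is.null(schedule)) {
      sch <- schedule
      sch$administrations <- lapply(sch$administrations, function(d) {
        if (d$ckr_vcr > 0) d$ckr_vcr <- params$CKR_VCR
        if (d$ckr_act > 0) d$ckr_act <- params$CKR_ACT
        d
      })
    }
    res <- run_simulation(1, params, sch)
    s <- res$series
    volume_reduction(s$total[1], s$total[nrow(s)])
  }
}

#' One-at-a-time parameter sweep
#'
#' Runs one full well-mixed simulation per grid point, all other parameters
#' held at their base values, and records the selected output: the fitted
#' free-growth rate constant or the percent volume reduction after the
#' treatment schedule. \code{CKR_total} is swept by scaling both drug CKRs
#' proportionally. A failed grid point is recorded as \code{NA}, not an
#' error.
#'
#' @param base base [tumor_parameters()].
#' @param parameter one of \code{Tc, T_G0, T_N, T_A, R_A, R_ADiff, R_NDiff,
#'   P_G0toG1, N_LIMP, P_sym, P_sleep, CKR_total}.
#' @param range two-element (low, high) range; defaults to
#'   [default_sweep_ranges()].
#' @param n number of grid points (at least 3).
#' @param selector \code{"volume_reduction"} or \code{"growth_rate"}.
#' @param schedule optional [treatment_schedule()] for the
#'   volume-reduction selector (per-event CKRs are rescaled when
#'   \code{CKR_total} is swept); default is the packaged SIOP schedule.
#' @param free_hours free-growth horizon for the growth-rate selector.
#' @return Data frame with columns \code{parameter, value, output}.
#' @export
oat_sweep <- function(base, parameter, range = NULL, n = 5,
                      selector = c("volume_reduction", "growth_rate"),
                      schedule = NULL, free_hours = 500) {
  selector <- match.arg(selector)
  if (!parameter %in% sweepable_parameters)
    stop("unknown sweep parameter: ", parameter)
  if (is.null(range)) range <- default_sweep_ranges()[[parameter]]
  if (n < 3) stop("a sweep needs at least 3 grid points")
  values <- seq(range[1], range[2], length.out = n)
  if (parameter == "N_LIMP") values <- unique(round(values))
  out <- vapply(values, function(v) {
    tryCatch(sweep_output(perturbed_parameters(base, parameter, v),
                          selector, schedule, free_hours),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(parameter = parameter, value = values, output = out)
}

#' Sorting criterion of a sweep curve
#'
#' A nonnegative, scale-free measure of how strongly the output responds
#' over the swept range: the output range (max minus min over the curve)
#' normalized by the absolute output at the base parameter values (taken as
#' the mean of the curve when no base output is supplied). Zero exactly when
#' the output is constant, and invariant to reversing the sweep direction.
#' The criterion is pluggable: any function of the curve can be ranked.
#'
#' @param curve data frame from [oat_sweep()] (columns \code{value},
#'   \code{output}).
#' @param base_output output at the base parameter values; defaults to the
#'   mean absolute output of the curve.
#' @return Nonnegative scalar SC value.
#' @export
sorting_criterion <- function(curve, base_output = NULL) {
  out <- curve$output[!is.na(curve$output)]
  if (length(out) < 3) stop("sorting criterion needs at least 3 valid points")
  rng <- max(out) - min(out)
  if (rng == 0) return(0)
  denom <- if (is.null(base_output)) mean(abs(out)) else abs(base_output)
  if (denom == 0) return(Inf)
  rng / denom
}

#' Rank all tumor-dynamics parameters by their effect on an output
#'
#' One-at-a-time sweeps of all twelve tumor-dynamics parameters over
#' biologically plausible ranges, each summarized by the sorting criterion
#' and sorted in nonincreasing order. With the volume-reduction selector
#' this ranks the cellular mechanisms by their impact on
#' chemotherapy-induced tumor shrinkage.
#'
#' @param base base [tumor_parameters()].
#' @param ranges named list of (low, high) ranges;
#'   [default_sweep_ranges()] by default.
#' @param n grid points per parameter.
#' @param selector,schedule,free_hours passed to [oat_sweep()].
#' @param criterion function \code{(curve, base_output) -> scalar};
#'   [sorting_criterion()] by default.
#' @return Data frame (\code{parameter}, \code{sc}) sorted by decreasing
#'   criterion; ties keep the input parameter order.
#' @export
rank_parameters <- function(base, ranges = default_sweep_ranges(), n = 5,
                            selector = c("volume_reduction", "growth_rate"),
                            schedule = NULL, free_hours = 500,
                            criterion = sorting_criterion) {
  selector <- match.arg(selector)
  base_out <- sweep_output(base, selector, schedule, free_hours)
  sc <- vapply(names(ranges), function(pn) {
    curve <- oat_sweep(base, pn, ranges[[pn]], n = n, selector = selector,
                       schedule = schedule, free_hours = free_hours)
    criterion(curve, base_out)
  }, numeric(1))
  res <- data.frame(parameter = names(ranges), sc = unname(sc))
  res[order(-res$sc), , drop = FALSE]
}

#' Two-parameter grid of growth rate and volume reduction
#'
#' Evaluates every combination of two swept parameters and returns both the
#' free-growth rate constant and the post-therapy volume reduction, with a
#' validity mask: grid points whose free growth is not monotonic (non-
#' positive growth rate) are masked in the growth grid, and points showing
#' no volume reduction after therapy are masked in the reduction grid.
#'
#' @param base base [tumor_parameters()].
#' @param param_x,param_y swept parameter names.
#' @param range_x,range_y (low, high) ranges; defaults from
#'   [default_sweep_ranges()].
#' @param n_x,n_y grid sizes (at least 5).
#' @param schedule,free_hours passed to the per-point runs.
#' @return List with \code{x}, \code{y} (grid values), matrices \code{k}
#'   and \code{reduction} (rows index x), and logical masks
#'   \code{k_valid}, \code{reduction_valid}.
#' @export
dyad_grid <- function(base, param_x, param_y,
                      range_x = NULL, range_y = NULL, n_x = 5, n_y = 5,
                      schedule = NULL, free_hours = 500) {
  if (n_x < 5 || n_y < 5) stop("dyad grids need at least 5 points per axis")
  if (is.null(range_x)) range_x <- default_sweep_ranges()[[param_x]]
  if (is.null(range_y)) range_y <- default_sweep_ranges()[[param_y]]
  xs <- seq(range_x[1], range_x[2], length.out = n_x)
  ys <- seq(range_y[1], range_y[2], length.out = n_y)
  k <- red <- matrix(NA_real_, n_x, n_y)
  for (i in seq_len(n_x)) for (j in seq_len(n_y)) {
    p <- tryCatch(
      perturbed_parameters(perturbed_parameters(base, param_x, xs[i]),
                           param_y, ys[j]),
      error = function(e) NULL)
    if (is.null(p)) next
    k[i, j] <- tryCatch(sweep_output(p, "growth_rate", NULL, free_hours),
                        error = function(e) NA_real_)
    red[i, j] <- tryCatch(sweep_output(p, "volume_reduction", schedule, 0),
                          error = function(e) NA_real_)
  }
  list(x = xs, y = ys, k = k, reduction = red,
       k_valid = !is.na(k) & k > 0,
       reduction_valid = !is.na(red) & red > 0)
}
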