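# Derived report quantities: volume reduction, fitted growth rate, and
# composition at a given hour of a simulation.

#' Percent volume reduction
#'
#' \code{100 * (1 - v_final / v_baseline)}. Tumor growth yields a negative
#' reduction.
#'
#' @param v_baseline baseline volume (cm^3 or any consistent unit), > 0.
#' @param v_final final volume, same unit.
#' @return Reduction in percent.
#' @export
volume_reduction <- function(v_baseline, v_final) {
  if (any(v_baseline <= 0)) stop("baseline volume must be positive")
  100 * (1 - v_final / v_baseline)
}

#' Fit the exponential growth-rate constant from a simulated trajectory
#'
#' Least-squares slope of \code{ln(total cells)} versus time over a window
#' of the recorded series, suitable for a treatment-free interval after an
#' initial burn-in.
#'
#' @param result a \code{tumor_simulation} from [run_simulation()].
#' @param window two-element vector of hours \code{c(from, to)}; default
#'   skips a 48 h burn-in and uses the rest of the series.
#' @return List with \code{k} (per hour) and \code{Td_days}
#'   (\code{ln2/k} in days).
#' @export
fit_growth_rate <- function(result, window = NULL) {
  s <- result$series
  if (is.null(window)) window <- c(48, max(s$hour))
  s <- s[s$hour >= window[1] & s$hour <= window[2], ]
  if (nrow(s) < 3) stop("fit window contains fewer than 3 recorded hours")
  if (any(s$total <= 0)) stop("non-positive totals in fit window")
  k <- unname(stats::coef(stats::lm(log(s$total) ~ s$hour))[2])
  list(k = k, Td_days = log(2) / k / 24)
}

#' Composition of a simulated tumor at a given hour
#'
#' Percentages of the total population in the reported classes at the
#' recorded hour, in both exhaustive decompositions (proliferating /
#' dormant / differentiated / dead, and stem / LIMP / differentiated /
#' dead).
#'
#' @param result a \code{tumor_simulation}.
#' @param hour recorded hour within the horizon.
#' @return A \code{composition_summary} (see [state_composition()]).
#' @export
composition_at <- function(result, hour) {
  s <- result$series
  row <- s[s$hour == hour, ]
  if (nrow(row) != 1) stop("hour ", hour, " is not within the horizon")
  if (row$total <= 0) stop("empty tumor at hour ", hour)
  out <- 100 * c(proliferating = row$proliferating, dormant = row$dormant,
                 stem = row$stem, limp = row$limp, diff = row$diff,
                 dead = row$dead) / row$total
  class(out) <- "composition_summary"
  out
}
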