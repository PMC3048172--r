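#' Tumor dynamics parameters
#'
#' Constructs and validates the set of twelve cytokinetic parameters that
#' drive the tumor model, together with the derived combined cell kill ratio
#' and the split of the cell cycle into phase durations. Defaults are the
#' reference values used for the "typical" nephroblastoma virtual tumor.
#'
#' @param Tc Cell cycle duration, hours.
#' @param T_G0 Dormant (G0) phase duration, hours: the time a cell may remain
#'   dormant before dying through necrosis.
#' @param T_N Time for necrosis to complete and its lysis products to be
#'   cleared from the tumor, hours.
#' @param T_A Time for apoptosis to complete and its products to be cleared,
#'   hours.
#' @param R_A Spontaneous apoptosis rate of living stem and LIMP cells,
#'   fraction per hour.
#' @param R_ADiff Apoptosis rate of terminally differentiated cells, per hour.
#' @param R_NDiff Necrosis rate of terminally differentiated cells, per hour.
#' @param P_G0toG1 Fraction of cells leaving the G0 compartment that re-enter
#'   the cycle at G1 (the remainder die through necrosis).
#' @param N_LIMP Maximum number of mitoses a LIMP (limited mitotic potential)
#'   cell performs before terminal differentiation; nonnegative integer.
#' @param P_sym Fraction of stem cell divisions that are symmetric (two stem
#'   daughters); the remainder are asymmetric (one stem, one LIMP daughter).
#' @param P_sleep Fraction of newborn (post-mitotic) stem/LIMP cells that
#'   enter G0 rather than G1.
#' @param CKR_VCR Vincristine cell kill ratio per administration, in [0,1].
#' @param CKR_ACT Actinomycin-D cell kill ratio per administration, in [0,1].
#' @param phase_split Fractions of \code{Tc} assigned to G1/S/G2/M; must sum
#'   to 1. Phase durations are rounded to whole hours (largest-remainder
#'   rounding) so that they sum to \code{Tc} exactly. The split does not
#'   affect the free growth rate; it only positions the actinomycin-D death
#'   point (end of S) within the cycle.
#'
#' @return An object of class \code{tumor_parameters}: a list of the validated
#'   parameters plus \code{CKR_total = min(1, CKR_VCR + CKR_ACT)} (additive
#'   drug effect, capped), the integer phase durations, and the internal state
#'   layout used by the engine.
#' @seealso [build_parameters()] for construction from a flat named mapping,
#'   [load_scenario()] for the packaged virtual-tumor parameter sets.
#' @export
#' @examples
#' p <- tumor_parameters()
#' p$CKR_total      # 0.5
#' p$phase_hours    # G1 S G2 M, summing to Tc
tumor_parameters <- function(Tc = 23, T_G0 = 96, T_N = 20, T_A = 6,
                             R_A = 0.001, R_ADiff = 0.003, R_NDiff = 0.001,
                             P_G0toG1 = 0.01, N_LIMP = 3,
                             P_sym = 0.45, P_sleep = 0.28,
                             CKR_VCR = 0.3, CKR_ACT = 0.2,
                             phase_split = c(G1 = 0.40, S = 0.39,
                                             G2 = 0.13, M = 0.08)) {
  p <- list(Tc = Tc, T_G0 = T_G0, T_N = T_N, T_A = T_A,
            R_A = R_A, R_ADiff = R_ADiff, R_NDiff = R_NDiff,
            P_G0toG1 = P_G0toG1, N_LIMP = N_LIMP,
            P_sym = P_sym, P_sleep = P_sleep,
            CKR_VCR = CKR_VCR, CKR_ACT = CKR_ACT)
  validate_parameters(p, phase_split)
  # durations are whole hours: the engine advances age bins in 1 h steps
  p$Tc <- as.integer(round(Tc))
  p$T_G0 <- as.integer(round(T_G0))
  p$T_N <- as.integer(round(T_N))
  p$T_A <- as.integer(round(T_A))
  p$N_LIMP <- as.integer(round(N_LIMP))
  p$CKR_total <- min(1, CKR_VCR + CKR_ACT)
  p$phase_split <- phase_split
  p$phase_hours <- phase_durations(p$Tc, phase_split)
  p$layout <- state_layout(p)
  class(p) <- "tumor_parameters"
  p
}

#' Build tumor parameters from a flat named mapping
#'
#' Accepts a named list or vector keyed by the parameter symbols
#' (\code{Tc, T_G0, T_N, T_A, R_A, R_ADiff, R_NDiff, P_G0toG1, N_LIMP, P_sym,
#' P_sleep, CKR_VCR, CKR_ACT}) as read from a flat configuration file.
#' Missing parameters take their reference value. Unknown keys are an error.
#'
#' @param raw_values named list or numeric vector of parameter values.
#' @return A \code{tumor_parameters} object.
#' @export
build_parameters <- function(raw_values = list()) {
  raw_values <- as.list(raw_values)
  known <- names(formals(tumor_parameters))
  bad <- setdiff(names(raw_values), known)
  if (length(bad) > 0)
    stop("unknown tumor parameter(s): ", paste(bad, collapse = ", "))
  do.call(tumor_parameters, raw_values)
}

validate_parameters <- function(p, phase_split) {
  chk <- function(name, ok) if (!isTRUE(ok))
    stop("invalid value for parameter '", name, "'", call. = FALSE)
  for (nm in c("Tc", "T_G0", "T_N", "T_A"))
    chk(nm, is.numeric(p[[nm]]) && length(p[[nm]]) == 1 && p[[nm]] > 0)
  for (nm in c("R_A", "R_ADiff", "R_NDiff"))
    chk(nm, is.numeric(p[[nm]]) && length(p[[nm]]) == 1 &&
          p[[nm]] >= 0 && p[[nm]] <= 1)
  for (nm in c("P_G0toG1", "P_sym", "P_sleep", "CKR_VCR", "CKR_ACT"))
    chk(nm, is.numeric(p[[nm]]) && length(p[[nm]]) == 1 &&
          p[[nm]] >= 0 && p[[nm]] <= 1)
  chk("N_LIMP", is.numeric(p$N_LIMP) && length(p$N_LIMP) == 1 &&
        p$N_LIMP >= 0 && abs(p$N_LIMP - round(p$N_LIMP)) < 1e-9)
  chk("R_ADiff + R_NDiff", p$R_ADiff + p$R_NDiff <= 1)
  if (abs(sum(phase_split) - 1) > 1e-12)
    stop("phase_split must sum to 1", call. = FALSE)
  if (any(phase_split < 0)) stop("phase_split must be nonnegative", call. = FALSE)
  if (round(p$Tc) < 4)
    stop("Tc must be at least 4 h (one hour per cycle phase)", call. = FALSE)
  invisible(TRUE)
}

#' Integer phase durations from the cycle duration and a fractional split
#'
#' Largest-remainder rounding of \code{split * Tc} to whole hours, summing to
#' \code{Tc} exactly; every phase is given at least one hour.
#'
#' @param Tc integer cell cycle duration, hours.
#' @param split fractions for G1/S/G2/M summing to 1.
#' @return Named integer vector \code{c(G1, S, G2, M)}.
#' @export
phase_durations <- function(Tc, split = c(G1 = 0.40, S = 0.39,
                                          G2 = 0.13, M = 0.08)) {
  raw <- split * Tc
  fl <- pmax(1L, as.integer(floor(raw)))
  rem <- as.integer(Tc - sum(fl))
  if (rem < 0) stop("Tc too short for four cycle phases")
  if (rem > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1L
  }
  stats::setNames(fl, names(split))
}

#' @export
print.tumor_parameters <- function(x, ...) {
  cat("Tumor dynamics parameters\n")
  cat(sprintf("  Tc=%d h (G1/S/G2/M = %s), T_G0=%d h, T_N=%d h, T_A=%d h\n",
              x$Tc, paste(x$phase_hours, collapse = "/"),
              x$T_G0, x$T_N, x$T_A))
  cat(sprintf("  R_A=%g, R_ADiff=%g, R_NDiff=%g  (per hour)\n",
              x$R_A, x$R_ADiff, x$R_NDiff))
  cat(sprintf("  P_G0toG1=%g, N_LIMP=%d, P_sym=%g, P_sleep=%g\n",
              x$P_G0toG1, x$N_LIMP, x$P_sym, x$P_sleep))
  cat(sprintf("  CKR_VCR=%g, CKR_ACT=%g -> CKR_total=%g\n",
              x$CKR_VCR, x$CKR_ACT, x$CKR_total))
  invisible(x)
}
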