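# Chemotherapy pharmacodynamics: CKR-based marking of lethally hit cells and
# their traversal of the rudimentary cycle to apoptotic death.
#
# Vincristine binds to cells in all cycling phases and causes apoptosis at
# the end of M (a mitotic-spindle poison); actinomycin-D binds to cells in
# all phases including G0 and causes apoptosis at the end of S. Only
# actinomycin-D acts on dormant cells. The additive combined effect is
# CKR_total = min(1, CKR_VCR + CKR_ACT).

#' A single drug administration event
#'
#' @param time_h hours from simulation start (nonnegative).
#' @param ckr_vcr vincristine cell kill ratio for this event, in [0,1].
#' @param ckr_act actinomycin-D cell kill ratio for this event, in [0,1].
#' @return Object of class \code{drug_administration}.
#' @export
drug_administration <- function(time_h, ckr_vcr = 0, ckr_act = 0) {
  stopifnot(time_h >= 0, ckr_vcr >= 0, ckr_vcr <= 1,
            ckr_act >= 0, ckr_act <= 1)
  structure(list(time_h = time_h, ckr_vcr = ckr_vcr, ckr_act = ckr_act),
            class = "drug_administration")
}

#' An ordered treatment schedule
#'
#' @param administrations list of [drug_administration()] events with
#'   strictly increasing times.
#' @param horizon_h simulation horizon in hours; all events must fall within.
#' @return Object of class \code{treatment_schedule}.
#' @export
treatment_schedule <- function(administrations = list(), horizon_h = 672) {
  times <- vapply(administrations, `[[`, numeric(1), "time_h")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("administration times must be strictly increasing")
  if (length(times) > 0 && max(times) > horizon_h)
    stop("schedule horizon (", horizon_h, " h) precedes the last dose")
  structure(list(administrations = administrations, horizon_h = horizon_h),
            class = "treatment_schedule")
}

#' The preoperative SIOP/GPOH vincristine + actinomycin-D schedule
#'
#' Four weekly administrations at days 3, 10, 17 and 24, with a 28-day
#' horizon (day 0 and day 28 being the two imaging instants). Vincristine is
#' given at every administration; actinomycin-D at administrations 1 and 3
#' (days 3 and 17), matching the fortnightly actinomycin-D dosing of the
#' preoperative AV regimen. Set \code{act_events = 1:4} for combined dosing
#' at every instant.
#'
#' @param ckr_vcr vincristine cell kill ratio per administration.
#' @param ckr_act actinomycin-D cell kill ratio per administration.
#' @param act_events indices (1..4) of the administrations that carry
#'   actinomycin-D.
#' @param days administration days.
#' @param horizon_days simulation horizon in days.
#' @return A [treatment_schedule()].
#' @export
#' @examples
#' sch <- default_siop_schedule()
#' vapply(sch$administrations, `[[`, numeric(1), "time_h") / 24  # 3 10 17 24
default_siop_schedule <- function(ckr_vcr = 0.3, ckr_act = 0.2,
                                  act_events = c(1L, 3L),
                                  days = c(3, 10, 17, 24),
                                  horizon_days = 28) {
  evs <- lapply(seq_along(days), function(i)
    drug_administration(days[i] * 24, ckr_vcr,
                        if (i %in% act_events) ckr_act else 0))
  treatment_schedule(evs, horizon_h = horizon_days * 24)
}

#' Mark lethally hit cells at the instant of drug administration
#'
#' From every cycling (G1/S/G2/M) stem and LIMP compartment a fraction
#' \code{min(1, ckr_vcr + ckr_act)} is moved into the hit compartments,
#' attributed to vincristine and actinomycin-D in proportion to their
#' individual kill ratios and preserving cycle position; from every dormant
#' (G0) compartment a fraction \code{ckr_act} is moved to the
#' actinomycin-D-hit holding slot (dormant cells are untouched by
#' vincristine). Differentiated and dead cells are unaffected. Marking moves
#' cells between compartments and conserves the total count exactly; the
#' marked cells die later, at their mechanism-specific death point, during
#' ordinary stepping.
#'
#' @param state cell state vector.
#' @param dose a [drug_administration()] (its \code{time_h} is not used here).
#' @param params a [tumor_parameters()] object.
#' @return The state after marking.
#' @export
apply_administration <- function(state, dose, params) {
  L <- params$layout
  v <- dose$ckr_vcr; a <- dose$ckr_act
  tot <- min(1, v + a)
  if (tot <= 0) return(state)
  fv <- if (v + a > 0) v / (v + a) else 0

  m <- tot * state[L$sc]
  state[L$hv_s] <- state[L$hv_s] + fv * m
  state[L$ha_s] <- state[L$ha_s] + (1 - fv) * m
  state[L$sc] <- state[L$sc] - m
  if (params$N_LIMP > 0) {
    m <- tot * state[L$lc_all]
    per_pos <- rowSums(matrix(m, nrow = params$Tc))  # pool LIMP m-indices
    state[L$hv_l] <- state[L$hv_l] + fv * per_pos
    state[L$ha_l] <- state[L$ha_l] + (1 - fv) * per_pos
    state[L$lc_all] <- state[L$lc_all] - m
  }
  if (a > 0) {
    mg <- a * state[L$sg]
    state[L$haG0_s] <- state[L$haG0_s] + sum(mg)
    state[L$sg] <- state[L$sg] - mg
    if (params$N_LIMP > 0) {
      mg <- a * state[L$lg_all]
      state[L$haG0_l] <- state[L$haG0_l] + sum(mg)
      state[L$lg_all] <- state[L$lg_all] - mg
    }
  }
  state
}

#' Age hit cells through their rudimentary cycle
#'
#' Advances only the hit-cell compartments by one hour: vincristine-hit
#' cells convert to the apoptotic compartment at the end of M, actinomycin-D
#' hit cells at the end of S (those marked past S, in G2 or M, at the end of
#' M without dividing), and actinomycin-D-hit dormant cells leave their G0
#' holding slot into G1 of the rudimentary cycle. All other compartments are
#' left untouched (apart from the apoptotic inflow); the full engine step
#' [step_state()] performs the same hit-cell advancement as its rule (f).
#'
#' @param state cell state vector.
#' @param params a [tumor_parameters()] object.
#' @return The state with hit conveyors advanced and deaths delivered to the
#'   apoptotic age-0 bin.
#' @export
step_hit_cells <- function(state, params) {
  L <- params$layout
  out <- state
  hit_ix <- c(L$hv_s, L$hv_l, L$ha_s, L$ha_l, L$haG0)
  out[hit_ix] <- 0
  sh <- function(v, skip = integer(0)) {
    keep <- setdiff(seq_len(length(v) - 1L), skip)
    out[v[keep + 1L]] <<- state[v[keep]]
  }
  sh(L$hv_s); sh(L$hv_l)
  sh(L$ha_s, skip = L$posS); sh(L$ha_l, skip = L$posS)
  out[L$ha1[1L]] <- out[L$ha1[1L]] + state[L$haG0_s]
  out[L$ha1[2L]] <- out[L$ha1[2L]] + state[L$haG0_l]
  dead <- sum(state[c(L$hv_exit, L$ha_exit)])
  out[L$ap1] <- out[L$ap1] + dead
  out
}
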