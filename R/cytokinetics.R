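# Cytokinetic engine: one-hour advancement of the age-structured population.

# Core kernel. S is an ncomp x n matrix (one tumor or geometrical cell per
# column). All rules are applied simultaneously from the pre-step state, in
# the documented order:
#   (a) spontaneous apoptosis at R_A on living stem/LIMP (including G0) and
#       at R_ADiff/R_NDiff on differentiated cells;
#   (b) aging of every bin by one hour;
#   (c) end-of-M mitosis (stem: symmetric with mass P_sym giving 2 stem, else
#       1 stem + 1 LIMP at m = N_LIMP; LIMP at m: 2 daughters at m-1, or 2
#       differentiated when m-1 = 0); each stem/LIMP daughter enters G0 with
#       mass P_sleep, else G1;
#   (d) G0 exit at age T_G0: fraction P_G0toG1 to G1 age 0, rest necrotic;
#   (e) apoptotic bins past T_A and necrotic bins past T_N leave the tumor;
#   (f) hit-cell conveyors advance and convert to apoptotic at their
#       mechanism-specific death point (end of S for actinomycin-D, end of M
#       for vincristine; ACT-hit cells marked in G2/M die at end of M,
#       ACT-hit dormant cells leave G0 on the next step).
step_engine <- function(S, p) {
  L <- p$layout
  NL <- p$N_LIMP
  out <- matrix(0, nrow = L$n, ncol = ncol(S))

  # (a) spontaneous deaths, applied to pre-step occupancies
  sv <- S
  sv[L$living, ] <- (1 - p$R_A) * S[L$living, , drop = FALSE]
  ap_in <- p$R_A * colSums(S[L$living, , drop = FALSE])
  ap_in <- ap_in + p$R_ADiff * S[L$diff, ]
  ne_in <- p$R_NDiff * S[L$diff, ]
  d_apo <- ap_in   # deaths by apoptosis this step (spontaneous, so far)
  d_nec <- ne_in

  # (b) conveyor aging (all plain shifts at once)
  out[L$shift_to, ] <- sv[L$shift_from, , drop = FALSE]

  # (c) mitosis at end of M
  Es <- sv[L$sc_exit, ]
  stemD <- Es * (1 + p$P_sym)
  out[L$diff, ] <- (1 - p$R_ADiff - p$R_NDiff) * S[L$diff, ]
  limpD <- matrix(0, nrow = max(NL, 1L), ncol = ncol(S))
  if (NL > 0) {
    Em <- sv[L$lc_exit, , drop = FALSE]
    limpD[NL, ] <- Es * (1 - p$P_sym)
    if (NL > 1)
      limpD[seq_len(NL - 1L), ] <- limpD[seq_len(NL - 1L), , drop = FALSE] +
        2 * Em[-1L, , drop = FALSE]
    out[L$diff, ] <- out[L$diff, ] + 2 * Em[1L, ]
    births <- Es + colSums(Em)
  } else {
    # a LIMP cell with zero permitted mitoses is born terminally differentiated
    out[L$diff, ] <- out[L$diff, ] + Es * (1 - p$P_sym)
    births <- Es
  }

  # (d) G0 exits
  Gs <- sv[L$sg_exit, ]
  out[L$sc1, ] <- out[L$sc1, ] + stemD * (1 - p$P_sleep) + Gs * p$P_G0toG1
  out[L$sg1, ] <- out[L$sg1, ] + stemD * p$P_sleep
  g0_nec <- Gs
  if (NL > 0) {
    Gm <- sv[L$lg_exit, , drop = FALSE]
    for (m in seq_len(NL)) {
      out[L$lc1[m], ] <- out[L$lc1[m], ] +
        limpD[m, ] * (1 - p$P_sleep) + Gm[m, ] * p$P_G0toG1
      out[L$lg1[m], ] <- out[L$lg1[m], ] + limpD[m, ] * p$P_sleep
    }
    g0_nec <- g0_nec + colSums(Gm)
  }
  ne_in <- ne_in + g0_nec * (1 - p$P_G0toG1)
  d_nec <- d_nec + g0_nec * (1 - p$P_G0toG1)

  # (f) hit-cell death points and the ACT-hit dormant holding slot
  hit_dead <- colSums(S[c(L$hv_exit, L$ha_exit), , drop = FALSE])
  ap_in <- ap_in + hit_dead
  d_apo <- d_apo + hit_dead
  out[L$ha1[1L], ] <- out[L$ha1[1L], ] + S[L$haG0_s, ]
  out[L$ha1[2L], ] <- out[L$ha1[2L], ] + S[L$haG0_l, ]

  # (e) clearance of completed apoptosis/necrosis; new dead enter age bin 1
  cleared <- S[L$ap_exit, ] + S[L$ne_exit, ]
  out[L$ap1, ] <- ap_in
  out[L$ne1, ] <- ne_in

  list(S = out, births = births, deaths_apoptosis = d_apo,
       deaths_necrosis = d_nec, clearances = cleared)
}

#' Advance a cell state by one hour
#'
#' Applies one fixed time step of the cytokinetic model. Without drugs the
#' dynamics are linear in the state; lethally hit cells (placed by
#' [apply_administration()]) are aged toward their death points as part of
#' the same step.
#'
#' @param state cell state vector (see [new_cell_state()]).
#' @param params a [tumor_parameters()] object.
#' @param dt time step in hours; the engine is defined for \code{dt = 1}.
#' @return The advanced state. Attribute \code{"ledger"} holds a named list
#'   \code{births} (net new cells from mitosis), \code{deaths_apoptosis},
#'   \code{deaths_necrosis} (cells moved to the dead compartments this step)
#'   and \code{clearances} (cells whose lysis completed and which left the
#'   tumor), satisfying \code{total(t+1) = total(t) + births - clearances}.
#' @export
step_state <- function(state, params, dt = 1) {
  if (dt != 1) stop("the engine uses a fixed 1 h time step")
  r <- step_engine(matrix(state, ncol = 1L), params)
  s <- r$S[, 1L]
  if (any(s < -1e-9 * max(abs(state), 1)))
    stop("internal consistency error: negative compartment after update")
  attr(s, "ledger") <- list(births = r$births,
                            deaths_apoptosis = r$deaths_apoptosis,
                            deaths_necrosis = r$deaths_necrosis,
                            clearances = r$clearances)
  s
}

#' One-hour transition matrix of the drug-free dynamics
#'
#' Explicit dense matrix formulation of the cytokinetic rules: one
#' application to a state vector equals [step_state()] on that state (the
#' drug-free dynamics are linear, and hit-cell conveyors are themselves
#' linear). Built independently of the stepping kernel, it serves as a
#' cross-check and exposes the growth rate as its dominant eigenvalue.
#'
#' @param params a [tumor_parameters()] object.
#' @return Square nonnegative matrix of dimension \code{params$layout$n}.
#' @export
transition_matrix <- function(params) {
  p <- params; L <- p$layout
  Tc <- p$Tc; TG0 <- p$T_G0; NL <- p$N_LIMP
  A <- matrix(0, L$n, L$n)
  srv <- 1 - p$R_A

  conveyor <- function(ix) for (t in seq_len(length(ix) - 1L))
    A[ix[t + 1L], ix[t]] <<- srv
  spont <- function(ix) A[L$ap1, ix] <<- A[L$ap1, ix] + p$R_A

  # stem cycle
  conveyor(L$sc); spont(L$sc)
  ex <- L$sc_exit
  stemD <- srv * (1 + p$P_sym)
  A[L$sc1, ex] <- A[L$sc1, ex] + stemD * (1 - p$P_sleep)
  A[L$sg1, ex] <- A[L$sg1, ex] + stemD * p$P_sleep
  limp_born <- srv * (1 - p$P_sym)
  if (NL > 0) {
    A[L$lc1[NL], ex] <- A[L$lc1[NL], ex] + limp_born * (1 - p$P_sleep)
    A[L$lg1[NL], ex] <- A[L$lg1[NL], ex] + limp_born * p$P_sleep
  } else A[L$diff, ex] <- A[L$diff, ex] + limp_born

  # stem G0
  conveyor(L$sg); spont(L$sg)
  A[L$sc1, L$sg_exit] <- A[L$sc1, L$sg_exit] + srv * p$P_G0toG1
  A[L$ne1, L$sg_exit] <- A[L$ne1, L$sg_exit] + srv * (1 - p$P_G0toG1)

  # LIMP cycles and G0s
  for (m in seq_len(NL)) {
    conveyor(L$lc[, m]); spont(L$lc[, m])
    ex <- L$lc_exit[m]
    if (m > 1) {
      A[L$lc1[m - 1L], ex] <- A[L$lc1[m - 1L], ex] + 2 * srv * (1 - p$P_sleep)
      A[L$lg1[m - 1L], ex] <- A[L$lg1[m - 1L], ex] + 2 * srv * p$P_sleep
    } else A[L$diff, ex] <- A[L$diff, ex] + 2 * srv
    conveyor(L$lg[, m]); spont(L$lg[, m])
    A[L$lc1[m], L$lg_exit[m]] <- A[L$lc1[m], L$lg_exit[m]] + srv * p$P_G0toG1
    A[L$ne1, L$lg_exit[m]] <- A[L$ne1, L$lg_exit[m]] + srv * (1 - p$P_G0toG1)
  }

  # differentiated cells
  A[L$diff, L$diff] <- 1 - p$R_ADiff - p$R_NDiff
  A[L$ap1, L$diff] <- p$R_ADiff
  A[L$ne1, L$diff] <- p$R_NDiff

  # dead-cell clearance queues (the final bin leaves the tumor)
  for (ix in list(L$ap, L$ne))
    for (t in seq_len(length(ix) - 1L)) A[ix[t + 1L], ix[t]] <- 1

  # hit-cell conveyors
  for (v in list(L$hv_s, L$hv_l)) {
    for (t in seq_len(Tc - 1L)) A[v[t + 1L], v[t]] <- 1
    A[L$ap1, v[Tc]] <- A[L$ap1, v[Tc]] + 1
  }
  for (v in list(L$ha_s, L$ha_l)) {
    for (t in setdiff(seq_len(Tc - 1L), L$posS)) A[v[t + 1L], v[t]] <- 1
    A[L$ap1, v[L$posS]] <- A[L$ap1, v[L$posS]] + 1
    A[L$ap1, v[Tc]] <- A[L$ap1, v[Tc]] + 1
  }
  A[L$ha1[1L], L$haG0_s] <- 1
  A[L$ha1[2L], L$haG0_l] <- 1
  A
}

#' Stationary (equilibrium) composition of free exponential growth
#'
#' Computes the dominant eigenvector of the one-hour drug-free transition
#' structure by damped power iteration: the composition a freely growing
#' tumor settles into, in which every compartment is multiplied by the same
#' factor each hour. Initializing a virtual tumor from this composition
#' avoids artificial transient growth behaviors.
#'
#' @param params a [tumor_parameters()] object.
#' @param tol convergence tolerance on the normalized state change.
#' @param max_iter iteration bound; exceeded iteration is an error.
#' @return List with \code{composition} (a [state_composition()] summary),
#'   \code{state} (eigenvector normalized to total 1), \code{lambda} (the
#'   per-hour multiplication factor) and \code{k = log(lambda)} (per hour).
#' @export
equilibrium_composition <- function(params, tol = 1e-12, max_iter = 50000) {
  # memoized on the drug-free dynamics (kill ratios play no role here)
  key <- paste(c(params$Tc, params$T_G0, params$T_N, params$T_A,
                 params$R_A, params$R_ADiff, params$R_NDiff,
                 params$P_G0toG1, params$N_LIMP, params$P_sym,
                 params$P_sleep, params$phase_hours, tol), collapse = "|")
  hit <- .equilibrium_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- equilibrium_iterate(params, tol, max_iter)
  .equilibrium_cache[[key]] <- res
  res
}

.equilibrium_cache <- new.env(parent = emptyenv())

# Dominant per-hour multiplication factor of the self-renewing stem block,
# from its renewal (Euler-Lotka) equation: a stem cell completing the cycle
# (Tc steps, surviving spontaneous apoptosis) leaves (1+P_sym) stem
# daughters, each re-entering G1 directly or after a G0 sojourn of T_G0
# steps with re-entry probability P_G0toG1. The LIMP and dead-cell chains
# are pass-through (nilpotent) and contribute no eigenvalue; the
# differentiated pool decays at its own rate. So the dominant eigenvalue of
# the full transition structure is the larger of the stem-renewal root and
# 1 - R_ADiff - R_NDiff.
stem_renewal_root <- function(p) {
  g <- function(lam)
    (1 + p$P_sym) * ((1 - p$R_A) / lam)^p$Tc *
      ((1 - p$P_sleep) +
         p$P_sleep * p$P_G0toG1 * ((1 - p$R_A) / lam)^p$T_G0) - 1
  if (!is.finite(g(4)) || g(4) >= 0)
    stop("stem renewal equation has no root below 4")
  lo <- 1e-3
  if (g(lo) <= 0) return(0)  # lineage not self-sustaining at any rate
  stats::uniroot(g, c(lo, 4), tol = 1e-15)$root
}

equilibrium_iterate <- function(params, tol, max_iter) {
  lambda0 <- max(stem_renewal_root(params),
                 1 - params$R_ADiff - params$R_NDiff)
  if (lambda0 <= 0)
    stop("population has no persistent mode (dominant eigenvalue 0)")
  # eigenvector by inverse iteration at the (analytically known) dominant
  # eigenvalue, slightly shifted off the singularity
  A <- transition_matrix(params)
  I <- diag(nrow(A))
  mu <- lambda0 * (1 + 1e-10) + 1e-13
  v <- rep(1 / nrow(A), nrow(A))
  for (i in seq_len(max(2L, min(max_iter, 50L)))) {
    w <- solve(A - mu * I, v)
    w <- w * sign(sum(w))
    w[w < 0] <- 0           # numerically tiny negatives off the Perron cone
    v <- w / sum(w)
    av <- as.numeric(A %*% v)
    lambda <- sum(av)
    if (max(abs(av - lambda * v)) < tol) {
      cs <- state_composition(v, params)
      return(list(composition = cs, state = v, lambda = lambda,
                  k = log(lambda)))
    }
  }
  stop("equilibrium composition did not converge (residual above ", tol, ")")
}

#' Intrinsic free-growth rate constant and volume doubling time
#'
#' The growth rate constant \code{k} is the natural log of the dominant
#' per-hour multiplication factor of the drug-free transition structure;
#' the doubling time is \code{ln(2)/k}, reported in days.
#'
#' @param params a [tumor_parameters()] object.
#' @return List with \code{k} (per hour), \code{Td_days} (\code{ln2/k} in
#'   days; \code{Inf} or negative when not growing) and \code{shrinking}
#'   (\code{TRUE} when the dominant factor is at or below 1; returned as a
#'   flag, not an error).
#' @export
intrinsic_growth_rate <- function(params) {
  eq <- equilibrium_composition(params)
  k <- eq$k
  list(k = k, Td_days = log(2) / k / 24, shrinking = k <= 0)
}
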