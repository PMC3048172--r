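# State layout and tallies.
#
# The age-structured population is stored as one numeric vector. Cycling cells
# occupy a "conveyor" of Tc hourly positions (G1 first, then S, G2, M; a cell
# at the last position divides on the next step). G0, apoptotic and necrotic
# compartments are conveyors of T_G0, T_A and T_N positions. Lethally hit
# cells ride separate conveyors per drug and lineage; actinomycin-D-hit cells
# exit (die) at the end of S, vincristine-hit at the end of M.

state_layout <- function(p) {
  Tc <- p$Tc; TG0 <- p$T_G0; TA <- p$T_A; TN <- p$T_N; NL <- p$N_LIMP
  off <- 0L
  take <- function(n) { i <- off + seq_len(n); off <<- off + as.integer(n); i }
  L <- list()
  L$sc <- take(Tc)                 # stem cycling, positions 1..Tc
  L$sg <- take(TG0)                # stem G0, ages 1..T_G0
  L$lc <- if (NL > 0) matrix(take(NL * Tc), nrow = Tc) else
    matrix(integer(0), nrow = Tc)  # column m: LIMP with m mitoses left
  L$lg <- if (NL > 0) matrix(take(NL * TG0), nrow = TG0) else
    matrix(integer(0), nrow = TG0)
  L$diff <- take(1L)
  L$ap <- take(TA)
  L$ne <- take(TN)
  L$hv_s <- take(Tc); L$hv_l <- take(Tc)   # vincristine-hit conveyors
  L$ha_s <- take(Tc); L$ha_l <- take(Tc)   # actinomycin-D-hit conveyors
  L$haG0_s <- take(1L); L$haG0_l <- take(1L)  # ACT-hit dormant holding slot
  L$n <- off
  L$posS <- as.integer(p$phase_hours[["G1"]] + p$phase_hours[["S"]])

  # one gathered shift map for every plain "age by one hour" move
  sh <- function(v) list(from = v[-length(v)], to = v[-1L])
  pieces <- list(sh(L$sc), sh(L$sg), sh(L$ap), sh(L$ne),
                 sh(L$hv_s), sh(L$hv_l))
  for (m in seq_len(NL)) pieces <- c(pieces, list(sh(L$lc[, m]), sh(L$lg[, m])))
  for (v in list(L$ha_s, L$ha_l)) {
    keep <- setdiff(seq_len(Tc - 1L), L$posS)  # end-of-S position exits instead
    pieces <- c(pieces, list(list(from = v[keep], to = v[keep + 1L])))
  }
  L$shift_from <- unlist(lapply(pieces, `[[`, "from"))
  L$shift_to <- unlist(lapply(pieces, `[[`, "to"))

  L$lc_all <- as.integer(L$lc); L$lg_all <- as.integer(L$lg)
  L$living <- c(L$sc, L$sg, L$lc_all, L$lg_all)
  L$sc_exit <- L$sc[Tc]; L$sg_exit <- L$sg[TG0]
  L$lc_exit <- if (NL > 0) L$lc[Tc, ] else integer(0)
  L$lg_exit <- if (NL > 0) L$lg[TG0, ] else integer(0)
  L$sc1 <- L$sc[1L]; L$sg1 <- L$sg[1L]
  L$lc1 <- if (NL > 0) L$lc[1L, ] else integer(0)
  L$lg1 <- if (NL > 0) L$lg[1L, ] else integer(0)
  L$ap1 <- L$ap[1L]; L$ne1 <- L$ne[1L]
  L$ap_exit <- L$ap[TA]; L$ne_exit <- L$ne[TN]
  L$hv_exit <- c(L$hv_s[Tc], L$hv_l[Tc])
  L$ha_exit <- c(L$ha_s[L$posS], L$ha_l[L$posS], L$ha_s[Tc], L$ha_l[Tc])
  L$ha1 <- c(L$ha_s[1L], L$ha_l[1L])
  L$haG0 <- c(L$haG0_s, L$haG0_l)

  # tally index sets (hit cells are counted in their current phase class)
  L$ix_prolif <- c(L$sc, L$lc_all, L$hv_s, L$hv_l, L$ha_s, L$ha_l)
  L$ix_dormant <- c(L$sg, L$lg_all, L$haG0_s, L$haG0_l)
  L$ix_stem <- c(L$sc, L$sg, L$hv_s, L$ha_s, L$haG0_s)
  L$ix_limp <- c(L$lc_all, L$lg_all, L$hv_l, L$ha_l, L$haG0_l)
  L$ix_apo <- L$ap; L$ix_nec <- L$ne
  L
}

#' Empty cell state vector
#'
#' @param params a [tumor_parameters()] object.
#' @return Numeric vector of length equal to the number of age-resolved
#'   compartments implied by \code{params}, all zero.
#' @export
new_cell_state <- function(params) {
  numeric(params$layout$n)
}

#' Total number of cells in a state
#'
#' @param state a cell state vector (or a matrix with one state per column).
#' @return Total cell count (per column for matrix input).
#' @export
state_total <- function(state) {
  if (is.matrix(state)) colSums(state) else sum(state)
}

# absolute subpopulation tallies; state may be a vector or a ncomp x n matrix
state_tallies <- function(state, params) {
  L <- params$layout
  S <- if (is.matrix(state)) state else matrix(state, ncol = 1L)
  g <- function(ix) colSums(S[ix, , drop = FALSE])
  out <- rbind(total = colSums(S),
               stem = g(L$ix_stem), limp = g(L$ix_limp),
               diff = S[L$diff, ], dormant = g(L$ix_dormant),
               proliferating = g(L$ix_prolif),
               apoptotic = g(L$ix_apo), necrotic = g(L$ix_nec))
  out <- rbind(out, dead = out["apoptotic", ] + out["necrotic", ])
  if (is.matrix(state)) out else out[, 1L]
}

#' Composition summary of a cell state
#'
#' Percentages of the total population in each reported class. Two exhaustive
#' decompositions are available: proliferating + dormant + differentiated +
#' dead, and stem + LIMP + differentiated + dead; both sum to 100. Hit cells
#' still traversing their rudimentary cycle are counted in the phase class
#' they currently occupy (they take up tumor volume until cleared).
#'
#' @param state cell state vector.
#' @param params a [tumor_parameters()] object.
#' @return Object of class \code{composition_summary}: named numeric vector
#'   with elements \code{proliferating}, \code{dormant}, \code{stem},
#'   \code{limp}, \code{diff}, \code{dead} (percent of total).
#' @export
state_composition <- function(state, params) {
  tl <- state_tallies(state, params)
  if (tl[["total"]] <= 0) stop("empty tumor: composition undefined")
  out <- 100 * tl[c("proliferating", "dormant", "stem", "limp",
                    "diff", "dead")] / tl[["total"]]
  class(out) <- "composition_summary"
  out
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Tumor composition (% of total population):\n")
  v <- unclass(x)
  cat(sprintf("  proliferating (GF) %5.1f | dormant %5.1f | dead %5.1f\n",
              v[["proliferating"]], v[["dormant"]], v[["dead"]]))
  cat(sprintf("  stem %5.1f | LIMP %5.1f | differentiated %5.1f\n",
              v[["stem"]], v[["limp"]], v[["diff"]]))
  invisible(x)
}

#' Seeded stochastic rounding of a cell state
#'
#' Optional integerization for small populations: each compartment value is
#' rounded down or up at random with probability equal to its fractional
#' part, preserving the expected count. The default engine is deterministic
#' mean-field bookkeeping (populations of 1e6 and more per geometrical cell),
#' where fractional expectation dynamics are appropriate.
#'
#' @param state cell state vector or matrix.
#' @return State with integer-valued entries.
#' @export
stochastic_round <- function(state) {
  fl <- floor(state)
  fr <- state - fl
  add <- stats::runif(length(state)) < fr
  out <- fl + as.numeric(add)
  if (is.matrix(state)) dim(out) <- dim(state)
  out
}
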