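# 3D lattice of geometrical cells (GCs) and the simulation drivers.
#
# Each GC is an elementary cube (default 1 mm^3) holding a full age-resolved
# cell state. A complete time step is two scans: the first updates every GC
# by the cytokinetic rules, the second rebalances GC occupancies between a
# minimum and maximum bound around the typical initial content (nbc),
# creating boundary GCs when the tumor expands and dissolving underpopulated
# GCs when it shrinks. The well-mixed mode aggregates the whole tumor into a
# single state, which is exact for homogeneous tumors because the dynamics
# are density-independent and linear.

neighbor_offsets <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0,
                             0, 0, 1, 0, 0, -1), ncol = 3, byrow = TRUE)

#' Initialize a tumor mesh
#'
#' Builds a quasi-spherical tumor of \code{ceiling(volume / gc_volume)}
#' geometrical cells (or the given occupancy mask), each populated with
#' \code{nbc = cell_density * gc_volume} biological cells distributed
#' according to the equilibrium composition of \code{params} — so that free
#' growth starts without artificial transients.
#'
#' @param initial_volume_cm3 tumor volume in cm^3 (ignored when \code{mask}
#'   is given).
#' @param params a [tumor_parameters()] object.
#' @param mask optional 3D logical array of occupied sites; must be
#'   nonempty and 6-connected.
#' @param cell_density biological cells per cm^3.
#' @param gc_volume volume of one geometrical cell, cm^3.
#' @param max_frac,min_frac rebalancing bounds as multiples of \code{nbc}.
#' @return Object of class \code{tumor_mesh}.
#' @export
initialize_mesh <- function(initial_volume_cm3 = NULL, params,
                            mask = NULL, cell_density = 1e9,
                            gc_volume = 1e-3,
                            max_frac = 1.5, min_frac = 0.5) {
  nbc <- cell_density * gc_volume
  if (is.null(mask)) {
    if (is.null(initial_volume_cm3) || initial_volume_cm3 <= 0)
      stop("initial volume must be positive")
    n_gc <- ceiling(initial_volume_cm3 / gc_volume)
    side <- 2L * ceiling((3 * n_gc / (4 * pi))^(1 / 3)) + 5L
    ctr <- (side + 1) / 2
    g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
    d2 <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2
    ord <- order(d2, g$x, g$y, g$z)
    coords <- as.matrix(g[ord[seq_len(n_gc)], , drop = FALSE])
  } else {
    if (!is.array(mask) || length(dim(mask)) != 3)
      stop("mask must be a 3D logical array")
    if (!any(mask)) stop("mask is empty")
    coords <- which(mask, arr.ind = TRUE)
    colnames(coords) <- c("x", "y", "z")
    if (!mask_connected(mask)) stop("mask is not 6-connected")
  }
  rownames(coords) <- NULL
  mesh <- structure(list(coords = coords, params = params,
                         nbc = nbc, cell_density = cell_density,
                         gc_volume = gc_volume,
                         max_frac = max_frac, min_frac = min_frac,
                         region = rep(1L, nrow(coords)),
                         region_params = list(params)),
                    class = "tumor_mesh")
  eq <- equilibrium_composition(params)
  mesh$states <- matrix(eq$state * nbc, nrow = params$layout$n,
                        ncol = nrow(coords))
  mesh <- rebuild_grid(mesh)
  mesh
}

mask_connected <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1) return(TRUE)
  dm <- dim(mask)
  seen <- array(FALSE, dm)
  start <- arrayInd(idx[1], dm)
  seen[start] <- TRUE
  frontier <- matrix(start, ncol = 3)
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (k in seq_len(6)) {
      nb <- sweep(frontier, 2, neighbor_offsets[k, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
        nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) next
      hit <- mask[nb] & !seen[nb]
      if (any(hit)) {
        seen[nb[hit, , drop = FALSE]] <- TRUE
        nxt <- rbind(nxt, nb[hit, , drop = FALSE])
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 3) else nxt
  }
  sum(seen) == length(idx)
}

# occupancy grid (0 = empty) sized to the coordinates plus a growth margin
rebuild_grid <- function(mesh, margin = 3L) {
  co <- mesh$coords
  shift <- margin + 1L - apply(co, 2, min)
  co <- sweep(co, 2, shift, `+`)
  dm <- apply(co, 2, max) + margin
  grid <- array(0L, dm)
  grid[co] <- seq_len(nrow(co))
  mesh$coords <- co
  mesh$grid <- grid
  mesh
}

#' Assign a parameter override to a region of the mesh
#'
#' Attaches distinct tumor-dynamics parameters to a subset of geometrical
#' cells (e.g. a metabolically distinct subregion); those GCs are advanced
#' with the override during [scan_update()]. Overrides must share the same
#' compartment layout (same durations and \code{N_LIMP}) as the base
#' parameters.
#'
#' @param mesh a \code{tumor_mesh}.
#' @param gc_index integer indices of the GCs in the region.
#' @param params override [tumor_parameters()].
#' @return The mesh with the region attached.
#' @export
set_mesh_region <- function(mesh, gc_index, params) {
  if (params$layout$n != mesh$params$layout$n)
    stop("region override must preserve the compartment layout")
  rid <- length(mesh$region_params) + 1L
  mesh$region_params[[rid]] <- params
  mesh$region[gc_index] <- rid
  mesh
}

#' First mesh scan: cytokinetic update of every geometrical cell
#'
#' Applies any due drug administrations (marking) and one engine step to
#' every GC independently, honoring per-region parameter overrides.
#'
#' @param mesh a \code{tumor_mesh}.
#' @param active_doses list of [drug_administration()] events due at this
#'   step (usually zero or one).
#' @return The updated mesh.
#' @export
scan_update <- function(mesh, active_doses = list()) {
  if (nrow(mesh$coords) == 0) return(mesh)
  for (rid in unique(mesh$region)) {
    cols <- which(mesh$region == rid)
    p <- mesh$region_params[[rid]]
    S <- mesh$states[, cols, drop = FALSE]
    for (dose in active_doses)
      S <- apply(S, 2, apply_administration, dose = dose, params = p)
    mesh$states[, cols] <- step_engine(S, p)$S
  }
  mesh
}

#' Second mesh scan: occupancy rebalancing (expansion/shrinkage)
#'
#' Any GC exceeding \code{max_frac * nbc} sheds half its content outward:
#' the shed half is inserted at the first site of the shortest path toward
#' the nearest empty site, displacing the contents along that path by one
#' GC and creating a new boundary GC. Any GC below \code{min_frac * nbc} is
#' emptied into its most populated 6-neighbor and deleted. Total cell count
#' in every compartment is conserved exactly; the pass is repeated until no
#' bound is violated.
#'
#' @param mesh a \code{tumor_mesh}.
#' @return The rebalanced mesh.
#' @export
rebalance <- function(mesh) {
  if (nrow(mesh$coords) == 0) return(mesh)
  for (pass in seq_len(100)) {
    tot <- colSums(mesh$states)
    hi <- which(tot > mesh$max_frac * mesh$nbc)
    changed <- FALSE
    for (g in hi) {
      mesh <- shed_outward(mesh, g)
      changed <- TRUE
    }
    tot <- colSums(mesh$states)
    lo <- which(tot < mesh$min_frac * mesh$nbc)
    if (length(lo) > 0 && nrow(mesh$coords) > 1) {
      mesh <- dissolve_gcs(mesh, lo)
      changed <- TRUE
    }
    if (!changed) break
  }
  mesh
}

# grow the occupancy grid when the tumor reaches its border
ensure_margin <- function(mesh) {
  dm <- dim(mesh$grid)
  co <- mesh$coords
  if (min(co) <= 1L || any(apply(co, 2, max) >= dm))
    mesh <- rebuild_grid(mesh)
  mesh
}

shed_outward <- function(mesh, g) {
  mesh <- ensure_margin(mesh)
  dm <- dim(mesh$grid)
  from <- mesh$coords[g, ]
  empt <- which(mesh$grid == 0L)
  ec <- arrayInd(empt, dm)
  d2 <- (ec[, 1] - from[1])^2 + (ec[, 2] - from[2])^2 + (ec[, 3] - from[3])^2
  ord <- order(d2, ec[, 1], ec[, 2], ec[, 3])
  target <- ec[ord[1], ]
  # greedy 6-neighbor walk toward the target, fixed axis tie-break order
  path <- list()
  cur <- from
  repeat {
    cand <- sweep(neighbor_offsets, 2, cur, `+`)
    cd2 <- (cand[, 1] - target[1])^2 + (cand[, 2] - target[2])^2 +
      (cand[, 3] - target[3])^2
    cur <- cand[which.min(cd2), ]
    path[[length(path) + 1L]] <- cur
    if (mesh$grid[cur[1], cur[2], cur[3]] == 0L) break
  }
  # insert the shed half at the first path site, displacing contents outward
  half <- mesh$states[, g] / 2
  mesh$states[, g] <- half
  carry <- half; carry_region <- mesh$region[g]
  for (site in path) {
    id <- mesh$grid[site[1], site[2], site[3]]
    if (id == 0L) {
      mesh$states <- cbind(mesh$states, carry, deparse.level = 0)
      mesh$coords <- rbind(mesh$coords, site)
      mesh$region <- c(mesh$region, carry_region)
      mesh$grid[site[1], site[2], site[3]] <- ncol(mesh$states)
      break
    }
    nxt <- mesh$states[, id]; nxt_region <- mesh$region[id]
    mesh$states[, id] <- carry; mesh$region[id] <- carry_region
    carry <- nxt; carry_region <- nxt_region
  }
  mesh
}

dissolve_gcs <- function(mesh, lo) {
  # process in decreasing index so earlier indices stay valid after deletion
  for (g in sort(lo, decreasing = TRUE)) {
    if (nrow(mesh$coords) <= 1) break
    cur <- mesh$coords[g, ]
    nb <- sweep(neighbor_offsets, 2, cur, `+`)
    ids <- apply(nb, 1, function(s) mesh$grid[s[1], s[2], s[3]])
    ids <- ids[ids != 0L & ids != g]
    if (length(ids) > 0) {
      tgt <- ids[which.max(colSums(mesh$states[, ids, drop = FALSE]))]
    } else {
      # isolated GC: merge into the nearest occupied GC to conserve cells
      other <- setdiff(seq_len(nrow(mesh$coords)), g)
      oc <- mesh$coords[other, , drop = FALSE]
      d2 <- (oc[, 1] - cur[1])^2 + (oc[, 2] - cur[2])^2 + (oc[, 3] - cur[3])^2
      tgt <- other[order(d2, oc[, 1], oc[, 2], oc[, 3])[1]]
    }
    mesh$states[, tgt] <- mesh$states[, tgt] + mesh$states[, g]
    mesh$grid[cur[1], cur[2], cur[3]] <- 0L
    mesh$states <- mesh$states[, -g, drop = FALSE]
    mesh$coords <- mesh$coords[-g, , drop = FALSE]
    mesh$region <- mesh$region[-g]
    shiftd <- mesh$grid > g
    mesh$grid[shiftd] <- mesh$grid[shiftd] - 1L
  }
  mesh
}

#' @export
print.tumor_mesh <- function(x, ...) {
  cat(sprintf("Tumor mesh: %d geometrical cells (%.3g cm^3), %.4g cells\n",
              nrow(x$coords), nrow(x$coords) * x$gc_volume,
              sum(x$states)))
  invisible(x)
}

#' Run a tumor simulation
#'
#' Hourly loop over the horizon of \code{schedule}: due drug administrations
#' are applied (cell marking), the cytokinetic update advances every
#' geometrical cell (or the single aggregated state in well-mixed mode), the
#' lattice is rebalanced, and subpopulation totals are recorded.
#'
#' Well-mixed mode treats the tumor as one equivalent homogeneous population
#' initialized at the equilibrium composition; because the model's dynamics
#' are density-independent and linear, its aggregate trajectory coincides
#' with the lattice mode for homogeneous tumors, at a fraction of the cost.
#'
#' @param init initial tumor: a volume in cm^3, a \code{tumor_mesh}
#'   (lattice mode), or a raw cell state vector (well-mixed mode).
#' @param params a [tumor_parameters()] object.
#' @param schedule a [treatment_schedule()]; use
#'   \code{treatment_schedule(horizon_h = n)} for free growth.
#' @param mode \code{"wellmixed"} or \code{"lattice"}.
#' @param cell_density biological cells per cm^3.
#' @param gc_volume geometrical cell volume, cm^3 (lattice mode).
#' @param stochastic apply seeded stochastic rounding of compartment counts
#'   after every step (off by default; the mean-field engine is
#'   deterministic).
#' @param verbose log dose and rebalancing events to stderr.
#' @return Object of class \code{tumor_simulation} with \code{$series}, a
#'   data frame with one row per hour (columns \code{hour, volume_cm3,
#'   total, stem, limp, diff, dormant, proliferating, apoptotic, necrotic,
#'   dead, gc_count}), the final state or mesh, and the run metadata.
#' @export
#' @examples
#' p <- tumor_parameters()
#' free <- run_simulation(1, p, treatment_schedule(horizon_h = 120))
#' tail(free$series$total, 1) / free$series$total[1]  # ~ exp(0.001 * 120)
run_simulation <- function(init, params,
                           schedule = default_siop_schedule(),
                           mode = c("wellmixed", "lattice"),
                           cell_density = 1e9, gc_volume = 1e-3,
                           stochastic = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  horizon <- as.integer(schedule$horizon_h)
  dose_at <- vapply(schedule$administrations, `[[`, numeric(1), "time_h")

  mesh <- NULL; state <- NULL
  if (inherits(init, "tumor_mesh")) {
    if (mode != "lattice") stop("a tumor_mesh input requires lattice mode")
    mesh <- init
  } else if (is.numeric(init) && length(init) == 1) {
    if (mode == "lattice") {
      mesh <- initialize_mesh(init, params, cell_density = cell_density,
                              gc_volume = gc_volume)
    } else {
      eq <- equilibrium_composition(params)
      state <- eq$state * init * cell_density
    }
  } else if (is.numeric(init)) {
    if (mode == "lattice") stop("lattice mode needs a volume or a tumor_mesh")
    state <- init
  } else stop("init must be a volume, a state vector or a tumor_mesh")

  rec <- matrix(NA_real_, nrow = horizon + 1L, ncol = 10L)
  colnames(rec) <- c("total", "stem", "limp", "diff", "dormant",
                     "proliferating", "apoptotic", "necrotic", "dead",
                     "gc_count")
  snap <- function(h) {
    if (mode == "lattice") {
      tl <- state_tallies(rowSums(mesh$states), params)
      rec[h + 1L, ] <<- c(tl[c("total", "stem", "limp", "diff", "dormant",
                               "proliferating", "apoptotic", "necrotic",
                               "dead")], nrow(mesh$coords))
    } else {
      tl <- state_tallies(state, params)
      rec[h + 1L, ] <<- c(tl[c("total", "stem", "limp", "diff", "dormant",
                               "proliferating", "apoptotic", "necrotic",
                               "dead")], NA_real_)
    }
  }
  snap(0L)
  for (t in seq_len(horizon) - 1L) {
    due <- schedule$administrations[dose_at == t]
    if (length(due) > 0 && verbose)
      message(sprintf("hour %d: administration (CKR_VCR=%g, CKR_ACT=%g)",
                      t, due[[1]]$ckr_vcr, due[[1]]$ckr_act))
    if (mode == "lattice") {
      mesh <- scan_update(mesh, due)
      n_before <- nrow(mesh$coords)
      mesh <- rebalance(mesh)
      if (verbose && nrow(mesh$coords) != n_before)
        message(sprintf("hour %d: rebalanced %d -> %d GCs",
                        t + 1L, n_before, nrow(mesh$coords)))
      if (stochastic) mesh$states <- stochastic_round(mesh$states)
    } else {
      for (dose in due) state <- apply_administration(state, dose, params)
      state <- as.numeric(step_state(state, params))
      if (stochastic) state <- stochastic_round(state)
    }
    snap(t + 1L)
  }

  series <- data.frame(hour = 0:horizon,
                       volume_cm3 = rec[, "total"] / cell_density,
                       rec, check.names = FALSE)
  structure(list(series = series, params = params, schedule = schedule,
                 mode = mode, cell_density = cell_density,
                 gc_volume = gc_volume,
                 final_state = state, final_mesh = mesh),
            class = "tumor_simulation")
}

#' @export
print.tumor_simulation <- function(x, ...) {
  s <- x$series
  cat(sprintf("Tumor simulation (%s mode), %d h horizon, %d administrations\n",
              x$mode, max(s$hour), length(x$schedule$administrations)))
  cat(sprintf("  volume: %.3g -> %.3g cm^3 (%+.1f%%)\n",
              s$volume_cm3[1], s$volume_cm3[nrow(s)],
              100 * (s$volume_cm3[nrow(s)] / s$volume_cm3[1] - 1)))
  invisible(x)
}
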