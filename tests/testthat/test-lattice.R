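test_that("mesh initialization fills GCs at density and equilibrium", {
  p <- ref_params()
  mesh <- initialize_mesh(1, p)   # 1 cm^3 at defaults
  expect_equal(nrow(mesh$coords), 1000)
  expect_equal(unname(colSums(mesh$states)), rep(1e6, 1000))
  cs <- state_composition(rowSums(mesh$states), p)
  eqc <- ref_equilibrium()$composition
  expect_equal(unclass(cs), unclass(eqc), tolerance = 1e-6)
  expect_error(initialize_mesh(-1, p), "positive")
})

test_that("disconnected masks are rejected, connected ones accepted", {
  p <- tiny_params()
  m <- array(FALSE, c(5, 5, 5))
  m[1, 1, 1] <- TRUE; m[5, 5, 5] <- TRUE
  expect_error(initialize_mesh(params = p, mask = m), "connected")
  m2 <- array(FALSE, c(4, 4, 4)); m2[2, 2, 2:3] <- TRUE
  mesh <- initialize_mesh(params = p, mask = m2)
  expect_equal(nrow(mesh$coords), 2)
})

test_that("a homogeneous mesh stays homogeneous under the first scan", {
  p <- tiny_params()
  m2 <- array(FALSE, c(4, 4, 4)); m2[2, 2:3, 2:3] <- TRUE
  mesh <- initialize_mesh(params = p, mask = m2)
  mesh2 <- scan_update(mesh)
  expect_equal(max(apply(mesh2$states, 1, function(r) diff(range(r)))), 0)
  # empty mesh: no-op
  empty <- mesh; empty$states <- mesh$states[, 0]; empty$coords <-
    mesh$coords[0, , drop = FALSE]; empty$region <- integer(0)
  expect_equal(ncol(scan_update(empty)$states), 0)
})

test_that("rebalancing conserves every compartment and splits at 2x nbc", {
  p <- tiny_params()
  mesh <- initialize_mesh(1e-3, p)   # a single GC
  expect_equal(nrow(mesh$coords), 1)
  before <- rowSums(mesh$states)
  # idempotent while within bounds
  expect_equal(rebalance(mesh)$states, mesh$states)
  # doubled content: sheds half into a newly created neighbor GC
  mesh$states <- mesh$states * 2
  reb <- rebalance(mesh)
  expect_equal(nrow(reb$coords), 2)
  expect_equal(rowSums(reb$states), 2 * before, tolerance = 1e-12)
  expect_equal(colSums(reb$states)[1], colSums(reb$states)[2])
  # underpopulated GC dissolves into its neighbor
  reb$states[, 2] <- reb$states[, 2] * 0.1
  shrunk <- rebalance(reb)
  expect_equal(nrow(shrunk$coords), 1)
  expect_equal(rowSums(shrunk$states), 1.1 * before, tolerance = 1e-12)
})

test_that("lattice and well-mixed runs agree on aggregate trajectories", {
  p <- ref_params()
  sch <- treatment_schedule(list(drug_administration(24, 0.3, 0.2),
                                 drug_administration(96, 0.3, 0)),
                            horizon_h = 168)
  wm <- run_simulation(0.008, p, sch, mode = "wellmixed")
  lat <- run_simulation(0.008, p, sch, mode = "lattice")
  rel <- abs(lat$series$total / wm$series$total - 1)
  expect_lt(max(rel), 0.01)
  expect_equal(lat$series$dead, wm$series$dead, tolerance = 1e-6)
  # shrinking tumor loses GCs monotonically
  expect_true(all(diff(lat$series$gc_count) <= 0))
  # GC-count volume stays within the rebalancing band of population volume
  n_gc <- lat$series$gc_count
  nbc <- 1e6
  expect_true(all(n_gc * nbc >= lat$series$total / 1.5 - nbc))
  expect_true(all(n_gc * nbc <= lat$series$total / 0.5 + nbc))
})

test_that("free growth from equilibrium has no transient and expands", {
  p <- ref_params()
  lat <- run_simulation(0.004, p, treatment_schedule(horizon_h = 460),
                        mode = "lattice")
  s <- lat$series
  expect_true(all(diff(s$total) > 0))              # monotone growth
  expect_true(all(diff(s$gc_count) >= 0))          # expansion only
  expect_gt(s$gc_count[nrow(s)], s$gc_count[1])    # crosses the max bound
  drift <- abs(100 * s$proliferating / s$total -
                 100 * s$proliferating[1] / s$total[1])
  expect_lt(max(drift[s$hour <= 48]), 1)           # composition drift < 1 pp
  # cells conserved by rebalancing: log-linear growth throughout
  fit <- fit_growth_rate(lat, c(0, 460))
  expect_equal(fit$k, ref_equilibrium()$k, tolerance = 1e-4)
})

test_that("per-region parameter overrides drive regions differently", {
  p <- tiny_params()
  m2 <- array(FALSE, c(4, 4, 4)); m2[2, 2, 2:3] <- TRUE
  mesh <- initialize_mesh(params = p, mask = m2)
  fast <- tumor_parameters(Tc = 8, T_G0 = 6, T_N = 4, T_A = 3, R_A = 0,
                           R_ADiff = 0, R_NDiff = 0, P_G0toG1 = 0.01,
                           N_LIMP = 2, P_sym = 0.9, P_sleep = 0)
  mesh <- set_mesh_region(mesh, 2L, fast)
  for (i in 1:48) mesh <- scan_update(mesh)
  tot <- colSums(mesh$states)
  expect_gt(tot[2], tot[1])
})
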