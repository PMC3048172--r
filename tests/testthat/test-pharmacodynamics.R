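test_that("the default preoperative schedule has the protocol structure", {
  sch <- default_siop_schedule()
  days <- vapply(sch$administrations, `[[`, numeric(1), "time_h") / 24
  expect_equal(days, c(3, 10, 17, 24))
  expect_equal(sch$horizon_h, 28 * 24)
  vcr <- vapply(sch$administrations, `[[`, numeric(1), "ckr_vcr")
  act <- vapply(sch$administrations, `[[`, numeric(1), "ckr_act")
  expect_equal(vcr, rep(0.3, 4))           # vincristine weekly
  expect_equal(act, c(0.2, 0, 0.2, 0))     # actinomycin-D fortnightly
  all4 <- default_siop_schedule(act_events = 1:4)
  expect_equal(vapply(all4$administrations, `[[`, numeric(1), "ckr_act"),
               rep(0.2, 4))
  expect_error(treatment_schedule(list(drug_administration(100),
                                       drug_administration(50))),
               "increasing")
  expect_error(treatment_schedule(list(drug_administration(700)),
                                  horizon_h = 672), "horizon")
})

test_that("marking moves the additive CKR fraction, split by drug", {
  p <- ref_params(); L <- p$layout
  s <- new_cell_state(p)
  s[L$sc] <- 1000 / p$Tc   # 1000 cycling stem cells
  s2 <- apply_administration(s, drug_administration(0, 0.3, 0.2), p)
  expect_equal(sum(s2), 1000)                     # marking conserves cells
  expect_equal(sum(s2[L$hv_s]), 300)
  expect_equal(sum(s2[L$ha_s]), 200)
  expect_equal(sum(s2[L$sc]), 500)

  # kill ratios cap additively at 1: everything marked
  s3 <- apply_administration(s, drug_administration(0, 0.7, 0.6), p)
  expect_equal(sum(s3[L$sc]), 0)
  expect_equal(sum(s3[c(L$hv_s, L$ha_s)]), 1000)
  expect_equal(sum(s3[L$hv_s]) / 1000, 0.7 / 1.3, tolerance = 1e-12)
})

test_that("dormant cells are hit only by actinomycin-D", {
  p <- ref_params(); L <- p$layout
  s <- new_cell_state(p)
  s[L$sg] <- 1000 / p$T_G0
  s2 <- apply_administration(s, drug_administration(0, 0.3, 0.2), p)
  expect_equal(sum(s2[L$sg]), 800)
  expect_equal(s2[L$haG0_s], 200)
  # vincristine alone never touches G0
  s3 <- apply_administration(s, drug_administration(0, 0.9, 0), p)
  expect_equal(s3, s)
  # a zero dose is the identity, bitwise
  expect_identical(apply_administration(s, drug_administration(0, 0, 0), p),
                   s)
})

test_that("hit cells die at their mechanism-specific death points", {
  p <- ref_params(); L <- p$layout
  # vincristine-hit cohort at the last M hour: apoptotic after one step
  s <- new_cell_state(p)
  s[L$hv_s[p$Tc]] <- 500
  s2 <- step_hit_cells(s, p)
  expect_equal(s2[L$ap[1]], 500)
  expect_equal(sum(s2[L$hv_s]), 0)
  expect_equal(sum(s2), 500)

  # ACT-hit dormant cohort: leaves G0 next step, dies after G1 + S
  s <- new_cell_state(p)
  s[L$haG0_s] <- 100
  for (i in 1:(1 + L$posS)) s <- step_hit_cells(s, p)
  expect_equal(s[L$ap[1]], 100)
  expect_equal(sum(s), 100)

  # ACT-hit cell marked in G2 passes end of S and dies at end of M instead
  s <- new_cell_state(p)
  s[L$ha_s[L$posS + 1]] <- 10
  for (i in seq_len(p$Tc - L$posS)) s <- step_hit_cells(s, p)
  expect_equal(s[L$ap[1]], 10)

  # the full engine step performs the same hit advancement
  s <- new_cell_state(p)
  s[L$hv_s[p$Tc]] <- 500
  expect_equal(as.numeric(step_state(s, p))[L$ap[1]], 500)
})

test_that("a zero-CKR schedule reproduces free growth bitwise", {
  p <- tiny_params()
  null_doses <- treatment_schedule(
    list(drug_administration(24, 0, 0), drug_administration(48, 0, 0)),
    horizon_h = 96)
  free <- treatment_schedule(horizon_h = 96)
  r1 <- run_simulation(0.01, p, null_doses)
  r2 <- run_simulation(0.01, p, free)
  expect_identical(r1$series$total, r2$series$total)
  expect_identical(r1$series$stem, r2$series$stem)
})

test_that("volume reduction grows with the combined kill ratio", {
  p <- ref_params()
  sw <- oat_sweep(p, "CKR_total", c(0.3, 0.9), n = 4,
                  selector = "volume_reduction")
  expect_true(all(diff(sw$output) > 0))
})
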