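test_that("stepping conserves cells through the ledger and is linear", {
  set.seed(42)
  for (p in list(ref_params(), tiny_params())) {
    for (rep in 1:5) {
      s <- random_state(p)
      s2 <- step_state(s, p)
      led <- attr(s2, "ledger")
      expect_equal(sum(s2), sum(s) + led$births - led$clearances,
                   tolerance = 1e-9)
      # deaths move cells between compartments without changing the total
      expect_true(led$deaths_apoptosis >= 0 && led$deaths_necrosis >= 0)
      # linearity (no-drug dynamics)
      a <- 3.7
      expect_equal(as.numeric(step_state(a * s, p)), a * as.numeric(s2),
                   tolerance = 1e-12)
    }
  }
})

test_that("an empty state stays empty with a zero ledger", {
  p <- tiny_params()
  s2 <- step_state(new_cell_state(p), p)
  expect_equal(sum(abs(s2)), 0)
  led <- attr(s2, "ledger")
  expect_equal(led$births, 0)
  expect_equal(led$clearances, 0)
})

test_that("a G0 cohort at its deadline splits P_G0toG1 to G1, rest necrotic", {
  p <- tumor_parameters(R_A = 0, P_G0toG1 = 0.01)
  L <- p$layout
  s <- new_cell_state(p)
  s[L$sg[p$T_G0]] <- 1000   # stem cohort one step from the G0 deadline
  s2 <- as.numeric(step_state(s, p))
  expect_equal(s2[L$sc[1]], 10)
  expect_equal(s2[L$ne[1]], 990)
  expect_equal(sum(s2), 1000)
})

test_that("transition matrix reproduces the step kernel exactly", {
  set.seed(7)
  for (p in list(tiny_params(), ref_params())) {
    A <- transition_matrix(p)
    for (rep in 1:5) {
      s <- random_state(p)
      expect_lt(max(abs(A %*% s - as.numeric(step_state(s, p)))),
                1e-10 * max(s))
    }
    # end-of-M column distributes two offspring per mother (plus R_A loss)
    ex <- p$layout$sc_exit
    expect_equal(sum(A[, ex]), (1 - p$R_A) * 2 + p$R_A)
    for (m in seq_len(p$N_LIMP))
      expect_equal(sum(A[, p$layout$lc_exit[m]]), (1 - p$R_A) * 2 + p$R_A)
  }
})

test_that("equilibrium composition is the fixed point of the step map", {
  eq <- ref_equilibrium()
  v <- eq$state
  v2 <- as.numeric(step_state(v, ref_params()))
  nz <- v > 1e-12
  expect_lt(max(abs(v2[nz] / v[nz] - eq$lambda)) / eq$lambda, 1e-6)
  # dominant eigenvalue of the matrix formulation agrees
  A <- transition_matrix(ref_params())
  expect_equal(sum(A %*% v), eq$lambda, tolerance = 1e-10)
})

test_that("pure symmetric renewal doubles every cycle and is all stem", {
  p <- tumor_parameters(P_sym = 1, P_sleep = 0, R_A = 0)
  eq <- equilibrium_composition(p)
  k_expected <- log(2) / p$Tc
  expect_lt(abs(eq$k - k_expected) / k_expected, 0.01)
  expect_equal(eq$composition[["stem"]], 100, tolerance = 0.1)
  expect_equal(eq$composition[["proliferating"]], 100, tolerance = 0.1)
  gr <- intrinsic_growth_rate(p)
  expect_false(gr$shrinking)
  expect_equal(gr$Td_days, log(2) / eq$k / 24)
})

test_that("growth rate rises with P_sym and falls with P_sleep", {
  k_of <- function(...) equilibrium_composition(tumor_parameters(...))$k
  k_sym <- vapply(seq(0.1, 0.9, length.out = 5),
                  function(v) k_of(P_sym = v), numeric(1))
  expect_true(all(diff(k_sym) >= -1e-12))
  k_sleep <- vapply(seq(0, 0.8, length.out = 5),
                    function(v) k_of(P_sleep = v), numeric(1))
  expect_true(all(diff(k_sleep) <= 1e-12))
})

test_that("a shrinking tumor yields a negative rate flag, not an error", {
  p <- tumor_parameters(P_sym = 0.05, P_sleep = 0.9)
  gr <- intrinsic_growth_rate(p)
  expect_true(gr$shrinking)
  expect_lt(gr$k, 0)
})
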