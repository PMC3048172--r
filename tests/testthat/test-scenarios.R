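test_that("packaged scenarios reproduce their defining parameter columns", {
  t4 <- load_scenario("T4")$params
  expect_equal(t4$Tc, 55L)
  expect_equal(t4$T_G0, 40L)
  expect_equal(t4$T_N, 120L)
  expect_equal(t4$R_ADiff, 0.05)
  expect_equal(t4$R_NDiff, 0.05)
  expect_equal(t4$P_sym, 0.76)
  expect_equal(t4$P_sleep, 0.36)
  expect_equal(t4$CKR_VCR, 0.33)
  expect_equal(t4$CKR_ACT, 0.22)
  expect_equal(t4$CKR_total, 0.55)

  t1 <- load_scenario("T1")$params
  expect_equal(t1$P_sym, 0.71)
  expect_equal(t1$P_sleep, 0.40)
  ref <- load_scenario("typical")$params
  for (nm in c("Tc", "T_G0", "T_N", "T_A", "R_A", "R_ADiff", "R_NDiff",
               "P_G0toG1", "N_LIMP", "CKR_VCR", "CKR_ACT"))
    expect_equal(t1[[nm]], ref[[nm]], info = nm)

  t2 <- load_scenario("T2")$params
  expect_equal(t2$Tc, 40L); expect_equal(t2$R_A, 8e-4)
  t3 <- load_scenario("T3")$params
  expect_equal(t3$CKR_VCR, 0.36); expect_equal(t3$CKR_ACT, 0.34)
  expect_equal(t3$CKR_total, 0.7)

  expect_error(load_scenario("T9"), "unknown scenario")
})

test_that("a config file overrides exactly the fields it names", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("name: custom", "Tc: 30", "volume_cm3: 10"), cfg)
  sc <- load_scenario(cfg)
  base <- load_scenario("typical")
  expect_equal(sc$params$Tc, 30L)
  expect_equal(sc$volume_cm3, 10)
  for (nm in c("T_G0", "P_sym", "P_sleep", "CKR_VCR"))
    expect_equal(sc$params[[nm]], base$params[[nm]], info = nm)
  # custom explicit schedule
  cfg2 <- tempfile(fileext = ".yaml")
  writeLines(c("schedule:",
               "  - {day: 1, ckr_vcr: 0.3, ckr_act: 0.2}",
               "  - {day: 8, ckr_vcr: 0.3}",
               "horizon_days: 14"), cfg2)
  sc2 <- load_scenario(cfg2)
  expect_equal(length(sc2$schedule$administrations), 2)
  expect_equal(sc2$schedule$administrations[[2]]$ckr_act, 0)
  expect_equal(sc2$schedule$horizon_h, 14 * 24)
})

test_that("reduction percentages are invariant to the initial volume", {
  sc <- load_scenario("typical")
  red_of <- function(vol) {
    sc$volume_cm3 <- vol
    s <- run_scenario(sc)$series
    volume_reduction(s$total[1], s$total[s$hour == 600])
  }
  expect_equal(red_of(100), red_of(7), tolerance = 1e-9)
})

test_that("table reproduction writes reports and is deterministic", {
  d1 <- file.path(tempdir(), "tables1")
  rep1 <- reproduce_tables(d1)
  expect_equal(nrow(rep1$initial), 5)
  expect_equal(nrow(rep1$final), 5)
  expect_true(all(file.exists(file.path(
    d1, c("initial_characteristics.csv", "final_characteristics.csv",
          "initial_deviation_from_published.csv",
          "final_deviation_from_published.csv")))))
  d2 <- file.path(tempdir(), "tables2")
  reproduce_tables(d2)
  expect_identical(readLines(file.path(d1, "final_characteristics.csv")),
                   readLines(file.path(d2, "final_characteristics.csv")))
})

test_that("the command-line interface runs and signals usage errors", {
  out <- file.path(tempdir(), "t4_series.csv")
  code <- suppressMessages(
    cli(c("simulate", "--scenario", "T4", "--mode", "wellmixed",
          "--out", out)))
  expect_equal(code, 0L)
  series <- read.csv(out)
  expect_equal(nrow(series), 673)
  expect_true(all(c("hour", "volume_cm3", "total", "stem", "dead")
                  %in% names(series)))
  expect_equal(suppressMessages(cli(c("simulate", "--scenario", "nope"))),
               2L)
  expect_equal(suppressMessages(cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(cli(character(0))), 2L)
  sw <- file.path(tempdir(), "sweep.csv")
  code <- suppressMessages(
    cli(c("sweep", "--param", "P_G0toG1", "--low", "0.005", "--high",
          "0.02", "--n", "3", "--selector", "growth_rate", "--out", sw)))
  expect_equal(code, 0L)
  expect_equal(nrow(read.csv(sw)), 3)
})
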