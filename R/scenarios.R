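# Packaged virtual-tumor scenarios and the table-reproduction report.
#
# Five parameter sets are shipped: the reference ("typical") tumor and four
# virtual tumors (T1..T4) adapted to a clinical Wilms' tumor case. T1
# perturbs the stem-division balance (P_sym) and dormancy entry (P_sleep);
# T2 the cycle duration and spontaneous apoptosis; T3 only the drug kill
# ratios; T4 combines cycle, dormancy, differentiated-cell death and kill
# ratio perturbations to also satisfy the case's histology (blastemal tumor:
# almost no differentiated cells, dead fraction near 60% after therapy).

scenario_overrides <- list(
  typical = list(),
  T1 = list(P_sym = 0.71, P_sleep = 0.40),
  T2 = list(Tc = 40, R_A = 0.0008),
  T3 = list(CKR_VCR = 0.36, CKR_ACT = 0.34),
  T4 = list(Tc = 55, T_G0 = 40, T_N = 120, R_ADiff = 0.05, R_NDiff = 0.05,
            P_sym = 0.76, P_sleep = 0.36, CKR_VCR = 0.33, CKR_ACT = 0.22)
)

#' Load a packaged or configured simulation scenario
#'
#' By name: one of \code{"typical", "T1", "T2", "T3", "T4"}. By file: a flat
#' YAML mapping whose keys are the tumor-parameter symbols plus optionally
#' \code{name}, \code{volume_cm3}, \code{act_events} (administration indices
#' carrying actinomycin-D), \code{schedule} (list of \code{{day, ckr_vcr,
#' ckr_act}} entries overriding the default protocol), \code{horizon_days}
#' and \code{final_eval_days_after_last_dose}. Unspecified parameters take
#' their reference values.
#'
#' The evaluation instant for final metrics follows the reporting
#' convention of the packaged scenarios: 1 day after completion of therapy
#' for the typical tumor, 3 days after for T1..T4.
#'
#' @param name scenario name or path to a YAML configuration file.
#' @return Object of class \code{tumor_scenario}: \code{name},
#'   \code{params}, \code{schedule}, \code{volume_cm3},
#'   \code{eval_hour_final}.
#' @export
#' @examples
#' sc <- load_scenario("T4")
#' sc$params$Tc      # 55
load_scenario <- function(name) {
  if (name %in% names(scenario_overrides)) {
    ov <- scenario_overrides[[name]]
    cfg <- list(name = name)
  } else if (file.exists(name)) {
    cfg <- yaml::read_yaml(name)
    if (is.null(cfg$name)) cfg$name <- basename(name)
    ov <- cfg[intersect(names(cfg), names(formals(tumor_parameters)))]
  } else stop("unknown scenario '", name,
              "' (not a packaged name or an existing config file)")
  params <- build_parameters(ov)
  horizon_days <- if (!is.null(cfg$horizon_days)) cfg$horizon_days else 28
  act_events <- if (!is.null(cfg$act_events)) cfg$act_events else c(1L, 3L)
  if (!is.null(cfg$schedule)) {
    evs <- lapply(cfg$schedule, function(e)
      drug_administration(e$day * 24,
                          if (is.null(e$ckr_vcr)) 0 else e$ckr_vcr,
                          if (is.null(e$ckr_act)) 0 else e$ckr_act))
    schedule <- treatment_schedule(evs, horizon_h = horizon_days * 24)
  } else {
    schedule <- default_siop_schedule(ckr_vcr = params$CKR_VCR,
                                      ckr_act = params$CKR_ACT,
                                      act_events = act_events,
                                      horizon_days = horizon_days)
  }
  lag_days <- if (!is.null(cfg$final_eval_days_after_last_dose))
    cfg$final_eval_days_after_last_dose
  else if (identical(cfg$name, "typical")) 1 else 3
  last_dose <- max(vapply(schedule$administrations, `[[`, numeric(1),
                          "time_h"))
  structure(list(name = cfg$name, params = params, schedule = schedule,
                 volume_cm3 = if (!is.null(cfg$volume_cm3))
                   cfg$volume_cm3 else 100,
                 eval_hour_final = min(last_dose + lag_days * 24,
                                       schedule$horizon_h)),
            class = "tumor_scenario")
}

#' @export
print.tumor_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %g cm^3, final metrics at hour %d\n",
              x$name, x$volume_cm3, x$eval_hour_final))
  print(x$params)
  invisible(x)
}

#' Run a scenario end to end
#'
#' @param scenario a \code{tumor_scenario} (or its name).
#' @param mode simulation mode, passed to [run_simulation()].
#' @return A \code{tumor_simulation}.
#' @export
run_scenario <- function(scenario, mode = "wellmixed") {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  run_simulation(scenario$volume_cm3, scenario$params, scenario$schedule,
                 mode = mode)
}

scenario_report_rows <- function(name) {
  sc <- load_scenario(name)
  eq <- equilibrium_composition(sc$params)
  gr <- intrinsic_growth_rate(sc$params)
  sim <- run_scenario(sc)
  s <- sim$series
  fin <- composition_at(sim, sc$eval_hour_final)
  ini <- eq$composition
  list(
    initial = c(scenario = name,
                k_per_h = gr$k, Td_days = gr$Td_days,
                GF_pct = ini[["proliferating"]],
                dormant_pct = ini[["dormant"]], stem_pct = ini[["stem"]],
                limp_pct = ini[["limp"]], diff_pct = ini[["diff"]],
                dead_pct = ini[["dead"]]),
    final = c(scenario = name,
              reduction_pct = volume_reduction(
                s$total[1], s$total[s$hour == sc$eval_hour_final]),
              GF_pct = fin[["proliferating"]],
              dormant_pct = fin[["dormant"]], stem_pct = fin[["stem"]],
              limp_pct = fin[["limp"]], diff_pct = fin[["diff"]],
              dead_pct = fin[["dead"]]))
}

#' Reproduce the initial- and final-characteristics tables
#'
#' Runs all five packaged scenarios end to end and writes two CSV reports:
#' the initial tumor characteristics (growth rate constant, doubling time
#' and equilibrium subpopulation percentages) and the final characteristics
#' (volume reduction percentage and post-therapy subpopulation
#' percentages), plus a comparison against the packaged published reference
#' values with per-cell deviations.
#'
#' @param out_dir output directory (created if needed).
#' @param scenarios scenario names to run.
#' @return Invisibly, a list with the two report data frames and the two
#'   comparison data frames.
#' @export
reproduce_tables <- function(out_dir = ".",
                             scenarios = c("typical", "T1", "T2", "T3",
                                           "T4")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(scenarios, scenario_report_rows)
  num <- function(rs) {
    df <- as.data.frame(do.call(rbind, rs), stringsAsFactors = FALSE)
    df[-1] <- lapply(df[-1], as.numeric)
    df
  }
  initial <- num(lapply(rows, `[[`, "initial"))
  final <- num(lapply(rows, `[[`, "final"))
  utils::write.csv(initial, file.path(out_dir, "initial_characteristics.csv"),
                   row.names = FALSE)
  utils::write.csv(final, file.path(out_dir, "final_characteristics.csv"),
                   row.names = FALSE)

  compare <- function(df, ref_file) {
    ref <- utils::read.csv(system.file("extdata", ref_file,
                                       package = "nephrosim"))
    ref <- ref[match(df$scenario, ref$scenario), ]
    common <- intersect(names(df)[-1], names(ref)[-1])
    dev <- df[c("scenario", common)]
    dev[common] <- df[common] - ref[common]
    dev
  }
  jsonlite::write_json(list(initial = initial, final = final),
                       file.path(out_dir, "scenario_report.json"),
                       dataframe = "rows", digits = NA)
  dev_initial <- compare(initial, "published_table2.csv")
  dev_final <- compare(final, "published_table3.csv")
  utils::write.csv(dev_initial,
                   file.path(out_dir, "initial_deviation_from_published.csv"),
                   row.names = FALSE)
  utils::write.csv(dev_final,
                   file.path(out_dir, "final_deviation_from_published.csv"),
                   row.names = FALSE)
  invisible(list(initial = initial, final = final,
                 dev_initial = dev_initial, dev_final = dev_final))
}
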