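# Shared fixtures. Expensive objects are computed once per test run and
# cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ref_params <- function() cached("ref_params", tumor_parameters())

ref_equilibrium <- function()
  cached("ref_eq", equilibrium_composition(ref_params()))

# a short-cycle parameter set for fast hand-traceable dynamics
tiny_params <- function(...) {
  tumor_parameters(Tc = 8, T_G0 = 6, T_N = 4, T_A = 3, R_A = 0,
                   R_ADiff = 0, R_NDiff = 0, P_G0toG1 = 0.01,
                   N_LIMP = 2, P_sym = 0.5, P_sleep = 0.2, ...)
}

scenario_sim <- function(name) {
  cached(paste0("sim_", name), run_scenario(name))
}

scenario_equilibrium <- function(name) {
  cached(paste0("eq_", name),
         equilibrium_composition(load_scenario(name)$params))
}

# random nonnegative state for property tests
random_state <- function(params, scale = 1000) {
  abs(stats::rnorm(params$layout$n)) * scale
}
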