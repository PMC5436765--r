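# Shared test utilities: an independent RHS oracle, random-state
# generators, and a per-session cache for the heavier simulations.

# Independent oracle: derivatives as stoichiometry matrix x flux vector,
# never via the hand-written balance equations in mass_action_rhs().
oracle_rhs <- function(state, network, circadian_factor = 1) {
  v <- reaction_rates(network, state, circadian_factor)
  drop(network$stoichiometry %*% v)
}

# Log-uniform random state over the physiological span of scales.
random_state <- function(lo = 1e-14, hi = 1e-3) {
  x <- 10^stats::runif(11, log10(lo), log10(hi))
  names(x) <- hpa_species()
  x
}

rel_err <- function(a, b) {
  denom <- pmax(abs(a), abs(b), 1e-300)
  abs(a - b) / denom
}

# Session-level cache so expensive trajectories are simulated once and
# shared across expectations.
.hpa_test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.hpa_test_cache[[key]]))
    assign(key, force(expr), envir = .hpa_test_cache)
  .hpa_test_cache[[key]]
}

sim_control_5d <- function()
  cached("control_5d", simulate_scenario(
    scenario_config("control", tolerances = "standard")))

sim_sham_5d <- function()
  cached("sham_5d", simulate_scenario(
    scenario_config("sham", tolerances = "standard")))
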