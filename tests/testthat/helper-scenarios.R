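# Shared simulation runs, computed once per test session.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, scenario) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_closed_loop(scenario)
  }
  .sim_cache[[key]]
}

nominal_adaptive_sim <- function() {
  cached_sim("nominal-adaptive", preset_scenario("nominal-adaptive"))
}

nominal_backstepping_sim <- function() {
  cached_sim("nominal-backstepping", preset_scenario("nominal-backstepping"))
}

untreated_sim <- function() {
  cached_sim("untreated", preset_scenario("untreated"))
}

table1_params <- function() patient_params()
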