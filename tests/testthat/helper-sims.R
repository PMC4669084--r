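# Shared noise-free simulations, built once per test run.

sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, seed = 1) {
  key <- paste(name, seed, sep = "_")
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_experiment(reference_scenario(name),
                                            seed = seed)
  }
  sim_cache[[key]]
}

# a tiny hand-checkable vial table: one CTRL + one labelled vial per day
toy_vials <- function(days = c(0, 7), lab_delta = 50, ctrl_delta = -20) {
  do.call(rbind, lapply(days, function(d) {
    data.frame(
      vial_id = paste0(c("CTRL", "LC"), "_d", d),
      treatment = c("CTRL", "LC"),
      day = d,
      gas_conc = 60, gas_delta = c(ctrl_delta, lab_delta) - 1,
      water_conc = 40, water_delta = c(ctrl_delta, lab_delta)
    )
  }))
}
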