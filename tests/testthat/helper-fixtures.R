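# Shared fixtures: small models and constant forcings used across tests.

const_series <- function(temp, days, cadence = "daily") {
  temperature_series(rep(temp, if (cadence == "hourly") days * 24 else days),
                     cadence = cadence)
}

quick_model <- function(preset = "calibrated", grid_cells = 100) {
  spuma_preset(preset, grid_cells = grid_cells)
}

# a perturbed starting point for recovery experiments
perturbed_init <- function() {
  list(stages = stage_param_set(
         egg = briere_params(5, 31, v_max = 0.05),
         n1 = briere_params(5, 31, v_max = 0.2),
         n2 = briere_params(5, 31, v_max = 0.2),
         n3 = briere_params(5, 31, v_max = 0.2),
         n4 = briere_params(5, 31, v_max = 0.2),
         n5 = briere_params(5, 31, v_max = 0.2)),
       age_dist = age_distribution(3, 2))
}
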