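# shared fixtures: small scenarios and random state grids, built in code

make_invertase <- function(v_max = 3, k_m = 4, k_i_glc = 5, k_i_frc = 10) {
  invertase_params(v_max, k_m, k_i_glc, k_i_frc)
}

make_scenario <- function(name = "test", v_max = 3, k_m = 4, k_i_glc = 5,
                          k_i_frc = 10, r_in = 0.5,
                          efflux_kind = "michaelis_menten",
                          efflux_v = 1, efflux_k = 5, efflux_rate_k = 0.2) {
  fluxes <- switch(efflux_kind,
    michaelis_menten = flux_params(r_in, "michaelis_menten",
                                   efflux_glc = c(v_max = efflux_v, k_m = efflux_k),
                                   efflux_frc = c(v_max = efflux_v, k_m = efflux_k)),
    first_order = flux_params(r_in, "first_order",
                              efflux_glc = c(k = efflux_rate_k),
                              efflux_frc = c(k = efflux_rate_k)),
    zero = flux_params(r_in, "zero"))
  param_scenario(name, invertase_params(v_max, k_m, k_i_glc, k_i_frc), fluxes)
}

# n random states with concentrations log-uniform in [lo, hi] mM
random_states <- function(n, seed = 1, lo = 1e-2, hi = 1e2) {
  set.seed(seed)
  matrix(exp(runif(3 * n, log(lo), log(hi))), ncol = 3,
         dimnames = list(NULL, c("suc", "glc", "frc")))
}

# the four bundled subcellular scenarios with their default grids
bundled_subcellular <- function() {
  build_subcellular_scenarios(read_scenario_config(bundled_config_path()))
}

# the two bundled whole-cell scenarios with grids
bundled_whole_cell <- function() {
  config <- read_scenario_config(bundled_config_path())
  lapply(c(whole_cell_22C = "whole_cell_22C", whole_cell_4C = "whole_cell_4C"),
         function(nm) scenario_from_config(config, nm))
}
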