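#!/usr/bin/env Rscript

# Time-course analyses: conservation in closed systems, the open-system
# steady state, and tonoplast transport in the coupled cytosol/vacuole model.

suppressPackageStartupMessages(library(metfun))
dir.create("results", showWarnings = FALSE)

config <- read_scenario_config(bundled_config_path())
wc <- scenario_from_config(config, "whole_cell_22C")$scenario

# closed system: no influx, no efflux -- hexose units must be conserved
closed <- param_scenario("whole_cell_22C_closed", wc$invertase,
                         flux_params(r_in = 0, efflux_kind = "zero"))
tc_closed <- simulate(closed, c(5, 1, 1), t_end = 100,
                      rtol = 1e-10, atol = 1e-12)
hu <- hexose_units(tc_closed)
write_time_course_csv(tc_closed, "results/time_course_closed.csv")
message(sprintf("closed system: 2*Suc+Glc+Frc drifts by %.2e (relative) over 100 h",
                max(abs(hu - hu[1])) / hu[1]))

# open system: constant influx balanced by hexose efflux
tc_open <- simulate(wc, c(1, 0.5, 0.5), t_end = 200)
write_time_course_csv(tc_open, "results/time_course_open.csv")
ss <- find_steady_state(wc, as.numeric(tc_open[nrow(tc_open), 2:4]))
message(sprintf("open-system steady state: suc=%.3f glc=%.3f frc=%.3f (residual %.1e, converged: %s)",
                ss$state[1], ss$state[2], ss$state[3], ss$residual,
                ss$converged))

# coupled compartments: sucrose flows into the vacuole, hexoses return
vac <- build_subcellular_scenarios(config)$vacuole_22C$scenario
cpl <- coupled_scenarios(
  param_scenario("cytosol", wc$invertase, wc$fluxes),
  vac,
  transport = list(kind = "first_order", k_suc = 0.3, k_glc = 0.1,
                   k_frc = 0.1))
tc_cpl <- simulate_coupled(cpl, c(10, 1, 1, 0.3, 0.5, 0.5), t_end = 50)
write_time_course_csv(tc_cpl, "results/time_course_coupled.csv")
message(sprintf("coupled model: vacuolar sucrose %.3f -> %.3f mM over 50 h",
                tc_cpl$suc_vac[1], tc_cpl$suc_vac[nrow(tc_cpl)]))
message("wrote results/time_course_{closed,open,coupled}.csv")
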