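test_that("a system with all rates zero stays constant", {
  sc <- make_scenario(v_max = 0, r_in = 0, efflux_kind = "zero")
  tc <- simulate(sc, c(2, 1, 0.5), t_end = 10, n_out = 11)
  expect_true(all(tc$suc == 2))
  expect_true(all(tc$glc == 1))
  expect_true(all(tc$frc == 0.5))
})

test_that("closed systems conserve 2*Suc + Glc + Frc along the trajectory", {
  sc <- make_scenario(r_in = 0, efflux_kind = "zero")
  tc <- simulate(sc, c(5, 1, 1), t_end = 100, rtol = 1e-10, atol = 1e-12)
  hu <- hexose_units(tc)
  expect_lt(max(abs(hu - hu[1])) / hu[1], 1e-8)
  expect_true(all(tc[, c("suc", "glc", "frc")] >= -1e-10))
})

test_that("sucrose initially accumulates at the influx rate from an empty pool", {
  sc <- make_scenario(r_in = 0.5)
  dt <- 1e-3
  tc <- simulate(sc, c(0, 0, 0), times = c(0, dt))
  slope <- tc$suc[2] / dt
  expect_equal(slope, 0.5, tolerance = 0.01)
})

test_that("the hexose-unit balance holds pointwise along a trajectory", {
  sc <- make_scenario(r_in = 0.5)
  tc <- simulate(sc, c(4, 0.5, 0.5), t_end = 20, n_out = 2001,
                 rtol = 1e-10, atol = 1e-12)
  hu <- hexose_units(tc)
  dt <- diff(tc$time)[1]
  mid <- 2:(nrow(tc) - 1)
  d_num <- (hu[mid + 1] - hu[mid - 1]) / (2 * dt)
  d_expected <- 2 * sc$fluxes$r_in -
    efflux_rate(sc$fluxes, "glc", tc$glc[mid]) -
    efflux_rate(sc$fluxes, "frc", tc$frc[mid])
  expect_lt(max(abs(d_num - d_expected)), 1e-4)
})

test_that("a constructed balanced scenario is found as a steady state", {
  inv <- make_invertase()
  x_star <- c(suc = 3, glc = 2, frc = 4)
  r_star <- invertase_rate(inv, x_star[[1]], x_star[[2]], x_star[[3]])
  sc <- param_scenario("balanced", inv,
    flux_params(r_in = r_star, efflux_kind = "first_order",
                efflux_glc = c(k = r_star / x_star[["glc"]]),
                efflux_frc = c(k = r_star / x_star[["frc"]])))
  ss <- find_steady_state(sc, x_star * c(1.7, 0.4, 2.2))
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-10)
  expect_equal(unname(ss$state), unname(x_star), tolerance = 1e-8)
})

test_that("the origin is a steady state of the uptake-free first-order system", {
  sc <- make_scenario(r_in = 0, efflux_kind = "first_order")
  ss <- find_steady_state(sc, c(0.2, 0.1, 0.1))
  expect_true(ss$converged)
  expect_equal(unname(ss$state), c(0, 0, 0), tolerance = 1e-8)
})

test_that("steady states agree with long simulations", {
  sc <- make_scenario(v_max = 4, k_m = 3, k_i_glc = 6, k_i_frc = 12,
                      r_in = 0.6)
  ss <- find_steady_state(sc, c(1, 1, 1))
  expect_true(ss$converged)
  tc <- simulate(sc, c(1, 1, 1), t_end = 1e4, n_out = 21,
                 rtol = 1e-10, atol = 1e-12)
  endpoint <- as.numeric(tc[nrow(tc), c("suc", "glc", "frc")])
  expect_equal(endpoint, unname(ss$state), tolerance = 1e-6)
})

test_that("coupled closed compartments conserve volume-weighted hexose units", {
  inv <- make_invertase()
  closed_fluxes <- flux_params(r_in = 0, efflux_kind = "zero")
  cyt <- param_scenario("cyt", inv, closed_fluxes)
  vac <- param_scenario("vac", make_invertase(v_max = 5, k_m = 2), closed_fluxes)
  cpl <- coupled_scenarios(cyt, vac,
    transport = list(kind = "first_order", k_suc = 0.3, k_glc = 0.1,
                     k_frc = 0.1))
  tc <- simulate_coupled(cpl, c(8, 1, 1, 0.5, 0.2, 0.2), t_end = 100,
                         rtol = 1e-10, atol = 1e-12)
  hu <- hexose_units(tc)
  expect_lt(max(abs(hu - hu[1])) / hu[1], 1e-8)
})

test_that("tonoplast transport moves sucrose into the vacuole", {
  # reactions off: only transport acts, so directionality is unambiguous
  off <- param_scenario("off", invertase_params(0, 1, 1, 1),
                        flux_params(r_in = 0, efflux_kind = "zero"))
  cpl <- coupled_scenarios(off, off,
    transport = list(kind = "first_order", k_suc = 0.3, k_glc = 0.2,
                     k_frc = 0.2))
  tc <- simulate_coupled(cpl, c(8, 1, 1, 0.5, 2, 2), t_end = 10)
  n <- nrow(tc)
  expect_lt(tc$suc_cyt[n], tc$suc_cyt[1])
  expect_gt(tc$suc_vac[n], tc$suc_vac[1])
  expect_gt(tc$glc_cyt[n], tc$glc_cyt[1])   # hexoses return to the cytosol
  expect_lt(tc$glc_vac[n], tc$glc_vac[1])
  hu <- hexose_units(tc)
  expect_lt(max(abs(hu - hu[1])) / hu[1], 1e-6)
})

test_that("time courses round-trip through CSV with sidecar metadata", {
  sc <- make_scenario()
  tc <- simulate(sc, c(2, 1, 1), t_end = 5, n_out = 6)
  path <- tempfile(fileext = ".csv")
  write_time_course_csv(tc, path)
  back <- read_time_course_csv(path)
  for (col in c("time", "suc", "glc", "frc")) {
    expect_equal(back[[col]], tc[[col]], tolerance = 1e-15)
  }
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$scenario$fluxes$r_in, 0.5)
})

test_that("simulation inputs are validated", {
  sc <- make_scenario()
  expect_error(simulate(sc, c(1, 1, 1)), "t_end")
  expect_error(simulate(sc, c(1, 1, 1), times = c(0, 2, 1)), "increasing")
  expect_error(simulate(sc, c(-1, 1, 1), t_end = 1), "non-negative")
})
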