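test_that("a switched-off enzyme without efflux gives zero Jacobian and Hessians", {
  sc <- make_scenario(v_max = 0, r_in = 0.4, efflux_kind = "zero")
  ev <- evaluate_functions(sc, c(2, 3, 1))
  expect_identical(unname(ev$jacobian), matrix(0, 3, 3))
  for (h in ev$hessians) expect_identical(unname(h), matrix(0, 3, 3))
})

test_that("finite-difference oracle reproduces polynomial derivatives", {
  f_const <- function(x) 5
  expect_equal(as.numeric(finite_difference_oracle(f_const, c(1, 2, 3), 1)),
               c(0, 0, 0), tolerance = 1e-9)
  expect_lt(max(abs(finite_difference_oracle(f_const, c(1, 2, 3), 2))), 1e-6)

  f_sq <- function(x) x[1]^2
  g <- finite_difference_oracle(f_sq, c(3, 1, 1), order = 1)
  expect_equal(g[["suc"]], 6, tolerance = 1e-6)

  f_mix <- function(x) x[1]^2 * x[2]     # hessian: [[2 x2, 2 x1, 0], ...]
  H <- finite_difference_oracle(f_mix, c(3, 2, 1), order = 2)
  expect_equal(H[1, 1], 4, tolerance = 1e-4)
  expect_equal(H[1, 2], 6, tolerance = 1e-4)
  expect_equal(H[3, 3], 0, tolerance = 1e-4)
})

test_that("oracle falls back to a flagged one-sided stencil at the boundary", {
  f <- function(x) x[1]^2 + x[2]
  g <- finite_difference_oracle(f, c(0, 5, 5), order = 1)
  expect_true(attr(g, "one_sided"))
  expect_equal(g[["suc"]], 0, tolerance = 1e-5)
  expect_equal(g[["glc"]], 1, tolerance = 1e-6)
})

test_that("analytic Jacobian and Hessians match finite differences over random states", {
  scenarios <- list(
    make_scenario(),
    make_scenario(v_max = 8, k_m = 1.5, k_i_glc = 0.8, k_i_frc = 18,
                  r_in = 0.2, efflux_kind = "first_order"),
    make_scenario(v_max = 0.5, k_m = 9, k_i_glc = 15, k_i_frc = 0.6,
                  efflux_kind = "zero"))
  for (sc in scenarios) {
    for (mode in c(FALSE, TRUE)) {
      states <- random_states(25, seed = 101)
      for (i in seq_len(25)) {
        rep <- derivative_report(sc, states[i, ], include_efflux = mode)
        expect_lt(rep$jacobian_rel_discrepancy, 1e-6)
        expect_lt(rep$hessian_rel_discrepancy, 1e-4)
      }
    }
  }
})

test_that("analytic Jacobian agrees with an independent numerical differentiator", {
  sc <- make_scenario()
  x <- c(1.7, 0.9, 3.2)
  f1 <- function(s) metabolic_functions(sc, s)[["f_suc"]]
  g <- pracma::grad(f1, x)
  J <- analytic_jacobian(sc, x)
  expect_equal(unname(J[1, ]), g, tolerance = 1e-6)
  H <- pracma::hessian(f1, x)
  expect_equal(unname(analytic_hessian(sc, x, "suc")), H, tolerance = 1e-4)
})

test_that("f(Suc) sensitivities carry the expected sign pattern", {
  sc <- make_scenario()
  states <- random_states(200, seed = 23)
  J1 <- t(apply(states, 1, function(x) analytic_jacobian(sc, x)[1, ]))
  expect_true(all(J1[, 1] < 0))
  expect_true(all(J1[, 2] > 0))
  expect_true(all(J1[, 3] > 0))
})

test_that("analytic Hessians are exactly symmetric", {
  sc <- make_scenario()
  states <- random_states(20, seed = 29)
  for (i in seq_len(20)) {
    for (fn in c("suc", "glc", "frc")) {
      H <- analytic_hessian(sc, states[i, ], fn, include_efflux = TRUE)
      expect_identical(H, t(H))
    }
  }
})

test_that("glucose accumulation dampens both hexose sensitivities of f(Suc)", {
  sc <- make_scenario()
  glc_grid <- seq(0.5, 50, length.out = 40)
  j12 <- abs(vapply(glc_grid, function(g)
    analytic_jacobian(sc, c(2, g, 1))[1, 2], numeric(1)))
  j13 <- abs(vapply(glc_grid, function(g)
    analytic_jacobian(sc, c(2, g, 1))[1, 3], numeric(1)))
  expect_true(all(diff(j12) < 0))
  expect_true(all(diff(j13) < 0))
})

test_that("scaled elasticities match their closed-form and log-log definitions", {
  # first-order efflux with the enzyme off: f(Glc) = -k*G, elasticity 1
  sc_lin <- make_scenario(v_max = 0, r_in = 0, efflux_kind = "first_order")
  expect_equal(scaled_elasticity(sc_lin, c(1, 2, 3), "glc", "glc",
                                 include_efflux = TRUE), 1)
  # f(Suc) = r_in when the enzyme is off: zero elasticity w.r.t. glucose
  sc_const <- make_scenario(v_max = 0, r_in = 0.4, efflux_kind = "zero")
  expect_identical(scaled_elasticity(sc_const, c(1, 2, 3), "suc", "glc"), 0)
  # elasticity undefined where the function vanishes
  sc_zero <- make_scenario(v_max = 0, r_in = 0, efflux_kind = "zero")
  expect_error(scaled_elasticity(sc_zero, c(1, 2, 3), "suc", "glc"),
               "undefined")
  # log-log slope oracle at a generic state
  sc <- make_scenario()
  x <- c(2.4, 1.1, 0.7)
  eps <- scaled_elasticity(sc, x, "suc", "frc")
  h <- 1e-5
  f_at <- function(frc) metabolic_functions(sc, c(x[1], x[2], frc))[["f_suc"]]
  slope <- (log(abs(f_at(x[3] * exp(h)))) - log(abs(f_at(x[3] * exp(-h))))) / (2 * h)
  expect_equal(eps, slope, tolerance = 1e-4)
})
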