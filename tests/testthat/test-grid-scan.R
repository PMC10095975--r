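test_that("a single-point grid reproduces direct evaluation", {
  sc <- make_scenario()
  grid <- grid_spec(c(2, 2), c(3, 3), suc_planes = 1.5, n_glc = 1, n_frc = 1)
  res <- scan(sc, grid)
  expect_equal(nrow(res), 1L)
  ev <- evaluate_functions(sc, c(1.5, 2, 3))
  expect_equal(res$f_suc, unname(ev$f[1]))
  expect_equal(c(res$j11, res$j12, res$j13), unname(ev$jacobian[1, ]))
  expect_equal(c(res$hS11, res$hS12, res$hS13),
               unname(ev$hessians$suc[1, ]))
  expect_equal(c(res$hS22, res$hS23, res$hS33),
               c(ev$hessians$suc[2, 2], ev$hessians$suc[2, 3],
                 ev$hessians$suc[3, 3]))
})

test_that("grid ordering is sucrose-plane major with fructose fastest", {
  sc <- make_scenario()
  grid <- grid_spec(c(1, 2), c(10, 20), suc_planes = c(5, 6),
                    n_glc = 2, n_frc = 2)
  res <- scan(sc, grid)
  expect_equal(nrow(res), 8L)
  expect_equal(res$suc, rep(c(5, 6), each = 4))
  expect_equal(res$glc, rep(rep(c(1, 2), each = 2), 2))
  expect_equal(res$frc, rep(c(10, 20), 4))
})

test_that("a switched-off enzyme yields a flat f(Suc) surface", {
  sc <- make_scenario(v_max = 0, r_in = 0.6, efflux_kind = "zero")
  grid <- grid_spec(c(1, 3), c(1, 3), suc_planes = c(1, 2, 3),
                    n_glc = 5, n_frc = 5)
  res <- scan(sc, grid)
  expect_equal(nrow(res), 75L)
  expect_true(all(res$f_suc == 0.6))
  summ <- dynamic_range_summary(res, "f_suc")
  expect_identical(summ$range, 0)
})

test_that("f(Suc) is minimal at the low-product corner of the highest sucrose plane", {
  wc <- bundled_whole_cell()$whole_cell_22C
  res <- scan(wc$scenario, wc$grid)
  i_min <- which.min(res$f_suc)
  expect_equal(res$suc[i_min], max(wc$grid$suc_planes))
  expect_equal(res$glc[i_min], min(res$glc))
  expect_equal(res$frc[i_min], min(res$frc))
})

test_that("every scanned record satisfies the hexose-unit balance", {
  sc <- make_scenario(r_in = 0.5)
  grid <- grid_spec(c(0.5, 8), c(0.5, 8), suc_planes = c(1, 4),
                    n_glc = 6, n_frc = 6)
  res <- scan(sc, grid, include_efflux = TRUE)
  lhs <- 2 * res$f_suc + res$f_glc + res$f_frc
  rhs <- 2 * sc$fluxes$r_in -
    efflux_rate(sc$fluxes, "glc", res$glc) -
    efflux_rate(sc$fluxes, "frc", res$frc)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("scans and their serialised form are reproducible byte-for-byte", {
  sc <- make_scenario()
  grid <- grid_spec(c(1, 3), c(1, 3), suc_planes = c(1, 2), n_glc = 4,
                    n_frc = 4)
  r1 <- scan(sc, grid)
  r2 <- scan(sc, grid)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_scan_csv(r1, p1)
  write_scan_csv(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  sidecar <- jsonlite::read_json(paste0(p1, ".json"))
  expect_equal(sidecar$n_records, 32L)
  expect_equal(sidecar$scenario$invertase$v_max, sc$invertase$v_max)
})

test_that("grid refinement moves the extrema less than the Lipschitz cell bound", {
  wc <- bundled_whole_cell()$whole_cell_22C
  grid_c <- wc$grid; grid_c$n_glc <- 10L; grid_c$n_frc <- 10L
  grid_f <- wc$grid; grid_f$n_glc <- 20L; grid_f$n_frc <- 20L
  coarse <- scan(wc$scenario, grid_c)
  fine <- scan(wc$scenario, grid_f)
  step_g <- diff(grid_c$glc_range) / (grid_c$n_glc - 1)
  step_f <- diff(grid_c$frc_range) / (grid_c$n_frc - 1)
  bound <- max(abs(fine$j12)) * step_g + max(abs(fine$j13)) * step_f
  expect_lt(abs(min(fine$f_suc) - min(coarse$f_suc)), bound)
  expect_lt(abs(max(fine$f_suc) - max(coarse$f_suc)), bound)
})

test_that("dynamic-range summaries report spans in decades", {
  sc <- make_scenario()
  grid <- grid_spec(c(1, 1), c(1, 1), suc_planes = c(1, 2), n_glc = 1,
                    n_frc = 1)
  res <- scan(sc, grid)
  res$f_suc <- c(0.1, 10)   # crafted column: two decades
  expect_equal(dynamic_range_summary(res, "f_suc")$oom_span, 2)
  res$f_glc <- c(0, 0)
  expect_true(is.na(dynamic_range_summary(res, "f_glc")$oom_span))
})

test_that("scenario comparison reports range ratios and j12/j13 interval overlap", {
  sc <- make_scenario()
  grid <- grid_spec(c(0.5, 5), c(0.5, 5), suc_planes = c(1, 3), n_glc = 8,
                    n_frc = 8)
  a <- scan(sc, grid)
  cmp_self <- compare_scenarios(a, a)
  expect_equal(cmp_self$range_ratio, 1)
  expect_equal(cmp_self$overlap_difference, 0)
  b <- a
  for (q in scan_quantities <- setdiff(names(b), c("scenario", "suc", "glc", "frc"))) {
    b[[q]] <- 0.1 * b[[q]]
  }
  cmp <- compare_scenarios(a, b)
  expect_equal(cmp$range_ratio, 10)
  expect_error(compare_scenarios(a, b, quantity = "not_a_column"),
               "not present")
})

test_that("the j12/j13 overlap diagnostic tracks interval separation", {
  sc <- make_scenario()
  grid <- grid_spec(c(0.5, 5), c(0.5, 5), suc_planes = c(1, 3), n_glc = 8,
                    n_frc = 8)
  a <- scan(sc, grid)
  # overlap is 1 when the two sensitivity intervals coincide ...
  b <- a
  b$j13 <- b$j12
  expect_equal(compare_scenarios(b, b)$j12_j13_overlap_a, 1)
  # ... and 0 once they are pushed apart
  c_ <- a
  c_$j13 <- c_$j13 + 10 * max(abs(a$j12), abs(a$j13))
  expect_equal(compare_scenarios(c_, c_)$j12_j13_overlap_a, 0)
})

test_that("grid specifications are validated", {
  expect_error(grid_spec(c(3, 1), c(1, 3), 1), "increasing")
  expect_error(grid_spec(c(1, 1), c(1, 3), 1, n_glc = 5), "degenerate")
  expect_error(grid_spec(c(-1, 3), c(1, 3), 1), "non-negative")
  expect_error(grid_spec(c(1, 3), c(1, 3), numeric(0)), "sucrose plane")
})
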