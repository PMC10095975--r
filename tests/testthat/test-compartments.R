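test_that("effective concentrations follow fraction * amount / volume", {
  whole <- compartment_spec("whole_cell", 1,
                            data.frame(sugar = "sucrose", temperature = "22C",
                                       fraction = 1))
  expect_equal(effective_concentration(2, whole, "sucrose", "22C"), 2)

  comps <- default_compartments()
  expect_equal(effective_concentration(1, comps$vacuole, "sucrose", "22C"),
               0.25 * 1 / 0.80)  # 0.3125 mM
  # same amount and share: cytosol/vacuole concentration ratio is 16
  frac <- data.frame(sugar = "sucrose", temperature = "22C", fraction = 0.4)
  cyt <- compartment_spec("cytosol", 0.05, frac)
  vac <- compartment_spec("vacuole", 0.80, frac)
  expect_equal(effective_concentration(1, cyt, "sucrose", "22C") /
                 effective_concentration(1, vac, "sucrose", "22C"), 16)
})

test_that("effective concentration is linear in amount and fraction, inverse in volume", {
  base <- data.frame(sugar = "hexose", temperature = "4C", fraction = 0.3)
  comp <- compartment_spec("c", 0.2, base)
  c1 <- effective_concentration(2, comp, "hexose", "4C")
  expect_identical(effective_concentration(4, comp, "hexose", "4C"), 2 * c1)
  comp2 <- compartment_spec("c", 0.2, transform(base, fraction = 0.6))
  expect_identical(effective_concentration(2, comp2, "hexose", "4C"), 2 * c1)
  comp3 <- compartment_spec("c", 0.1, base)
  expect_identical(effective_concentration(2, comp3, "hexose", "4C"), 2 * c1)
})

test_that("tissue amounts carry the fresh-weight-to-volume factor", {
  ta <- tissue_amounts(sucrose = 3, glucose = 1, fructose = 2,
                       fw_to_volume = 1.5)
  whole <- compartment_spec("whole_cell", 1,
                            data.frame(sugar = "sucrose", temperature = "22C",
                                       fraction = 1))
  expect_equal(effective_concentration(ta, whole, "sucrose", "22C"), 2)
  expect_error(tissue_amounts(sucrose = -1), "non-negative")
})

test_that("glucose and fructose use the joint hexose distribution", {
  comps <- default_compartments()
  expect_identical(effective_concentration(1, comps$cytosol, "glucose", "22C"),
                   effective_concentration(1, comps$cytosol, "fructose", "22C"))
  expect_error(effective_concentration(1, comps$cytosol, "sucrose", "37C"),
               "no distribution fraction")
})

test_that("dilution factors are volume-fraction ratios", {
  comps <- default_compartments()
  expect_equal(dilution_factor(comps$cytosol, comps$vacuole), 16)
  expect_equal(dilution_factor(comps$cytosol, comps$cytosol), 1)
  frac <- data.frame(sugar = "sucrose", temperature = "22C", fraction = 1)
  a <- compartment_spec("a", 0.10, frac)
  b <- compartment_spec("b", 0.50, frac)
  expect_equal(dilution_factor(a, b), 5)
})

test_that("subcellular scenario builder yields the four temperature/compartment cases", {
  sub <- bundled_subcellular()
  expect_named(sub, c("cytosol_22C", "vacuole_22C", "cytosol_4C", "vacuole_4C"))
  expect_equal(sub$cytosol_22C$grid$suc_planes, c(8, 16, 24))
  expect_equal(sub$vacuole_22C$grid$suc_planes, c(0.25, 0.5, 0.75))
  expect_equal(sub$cytosol_4C$grid$suc_planes, c(25.6, 38.4, 51.2))
  expect_equal(sub$vacuole_4C$grid$suc_planes, c(1.32, 1.98, 2.64))
  # hexose axes are effective concentrations of the whole-cell amount ranges
  expect_equal(sub$cytosol_22C$grid$glc_range, 0.30 * c(1, 3) / 0.05)
  expect_equal(sub$vacuole_4C$grid$glc_range, 0.50 * c(5, 15) / 0.80)
})

test_that("subcellular builder honours subsets and overrides", {
  config <- read_scenario_config(bundled_config_path())
  one <- build_subcellular_scenarios(config, compartment_names = "cytosol")
  expect_length(one, 2L)
  config$subcellular_sucrose_planes$vacuole$`22C` <- c(0.1, 0.9)
  sub <- build_subcellular_scenarios(config)
  expect_equal(sub$vacuole_22C$grid$suc_planes, c(0.1, 0.9))
  config$isoforms$vacuole <- NULL
  expect_error(build_subcellular_scenarios(config), "lacks invertase")
})

test_that("compartment validation rejects out-of-range fractions", {
  frac <- data.frame(sugar = "sucrose", temperature = "22C", fraction = 0.5)
  expect_error(compartment_spec("x", 0, frac), "volume_fraction")
  expect_error(compartment_spec("x", 1.2, frac), "volume_fraction")
  expect_error(compartment_spec("x", 0.5, transform(frac, fraction = 1.4)),
               "fractions")
})
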