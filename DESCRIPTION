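Package: metfun
Title: Metabolic Functions of Invertase-Driven Sucrose Cleavage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic modelling of invertase-catalysed sucrose hydrolysis at
    whole-cell and subcellular (cytosol/vacuole) resolution. Provides
    product-inhibited Michaelis-Menten rate laws, metabolic functions of
    sucrose, glucose and fructose, their closed-form Jacobian and Hessian
    surfaces over concentration grids, compartment-specific effective
    concentrations, stiff ODE time courses, a synthetic parameter-scenario
    generator emulating ambient (22 degree C) versus cold (4 degree C)
    conditions, and weighted least-squares recovery of kinetic parameters
    from time-course data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
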