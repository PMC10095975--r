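config_known_keys <- c("scenarios", "compartments", "isoforms",
                       "subcellular_sucrose_planes",
                       "whole_cell_hexose_amounts")
scenario_known_keys <- c("temperature_label", "compartment_label",
                         "invertase", "fluxes", "grid")

#' Default bundled configuration
#'
#' The configuration behind the packaged example analyses: two whole-cell
#' scenarios (22 C and 4 C) with their grids, the cytosol/vacuole
#' compartment definitions, per-compartment invertase isoform parameters at
#' both temperatures, the compartment-specific sucrose plane ranges, and the
#' whole-cell hexose amount ranges from which subcellular hexose axes are
#' derived.
#'
#' All kinetic numbers here are synthetic placeholders structured like
#' experimentally determined ambient/cold parameter sets (real values would
#' enter via a user config); the concentration ranges are the study
#' conditions of the packaged surface analyses.
#'
#' @return Nested configuration list; see [read_scenario_config()] for the
#'   on-disk form.
#' @export
default_config <- function() {
  list(
    scenarios = list(
      whole_cell_22C = list(
        temperature_label = "22C", compartment_label = "whole_cell",
        invertase = list(v_max = 5, k_m = 5, k_i_glc = 4, k_i_frc = 8),
        fluxes = list(r_in = 0.8, efflux_kind = "michaelis_menten",
                      efflux_glc = list(v_max = 2, k_m = 5),
                      efflux_frc = list(v_max = 2, k_m = 5)),
        grid = list(glc_range = c(1, 3), frc_range = c(1, 3),
                    suc_planes = c(1, 2, 3), n_glc = 50L, n_frc = 50L,
                    units = "umol_gFW")),
      whole_cell_4C = list(
        temperature_label = "4C", compartment_label = "whole_cell",
        invertase = list(v_max = 1.5, k_m = 5, k_i_glc = 4, k_i_frc = 8),
        fluxes = list(r_in = 0.24, efflux_kind = "michaelis_menten",
                      efflux_glc = list(v_max = 2, k_m = 5),
                      efflux_frc = list(v_max = 2, k_m = 5)),
        grid = list(glc_range = c(5, 15), frc_range = c(5, 15),
                    suc_planes = c(4, 6, 8), n_glc = 50L, n_frc = 50L,
                    units = "umol_gFW"))
    ),
    compartments = list(
      cytosol = list(volume_fraction = 0.05,
                     sugar_fractions = list(
                       sucrose = list(`22C` = 0.50, `4C` = 0.40),
                       hexose = list(`22C` = 0.30, `4C` = 0.30))),
      vacuole = list(volume_fraction = 0.80,
                     sugar_fractions = list(
                       sucrose = list(`22C` = 0.25, `4C` = 0.33),
                       hexose = list(`22C` = 0.55, `4C` = 0.50)))
    ),
    isoforms = list(
      cytosol = list(  # neutral invertase
        `22C` = list(v_max = 5, k_m = 8, k_i_glc = 4, k_i_frc = 8, r_in = 0.8),
        `4C` = list(v_max = 1.5, k_m = 8, k_i_glc = 4, k_i_frc = 8, r_in = 0.24)),
      vacuole = list(  # acidic invertase
        `22C` = list(v_max = 8, k_m = 2, k_i_glc = 4, k_i_frc = 8, r_in = 0.2),
        `4C` = list(v_max = 2.4, k_m = 2, k_i_glc = 4, k_i_frc = 8, r_in = 0.06))
    ),
    subcellular_sucrose_planes = list(
      cytosol = list(`22C` = c(8, 16, 24), `4C` = c(25.6, 38.4, 51.2)),
      vacuole = list(`22C` = c(0.25, 0.5, 0.75), `4C` = c(1.32, 1.98, 2.64))
    ),
    whole_cell_hexose_amounts = list(`22C` = c(1, 3), `4C` = c(5, 15))
  )
}

validate_config <- function(config) {
  unknown <- setdiff(names(config), config_known_keys)
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    bad <- setdiff(names(sc), scenario_known_keys)
    if (length(bad) > 0L) {
      stop("scenario '", nm, "' has unknown keys: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (is.null(sc$invertase) || is.null(sc$fluxes)) {
      stop("scenario '", nm, "' must define invertase and fluxes",
           call. = FALSE)
    }
  }
  invisible(config)
}

#' Read a scenario configuration file
#'
#' YAML (\code{.yaml}/\code{.yml}) or JSON (\code{.json}), validated against
#' the known key set (unknown keys are rejected rather than silently
#' ignored).
#'
#' @param path configuration file path.
#' @return Validated configuration list.
#' @export
read_scenario_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE),
    stop("unsupported config format: .", ext, call. = FALSE))
  validate_config(config)
}

#' Write a scenario configuration file
#'
#' @param config configuration list (validated before writing).
#' @param path output path; format chosen by extension as in
#'   [read_scenario_config()].
#' @return \code{path}, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  validate_config(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(config, path, precision = 17L),
    json = jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  invisible(path)
}

#' Path of the bundled synthetic example configuration
#'
#' @return File path of \code{scenarios_synthetic.yaml} shipped with the
#'   package (identical in content to [default_config()]).
#' @export
bundled_config_path <- function() {
  system.file("extdata", "scenarios_synthetic.yaml", package = "metfun",
              mustWork = TRUE)
}

fluxes_from_config <- function(fl) {
  as_vec <- function(x) if (is.null(x)) NULL else unlist(x)
  flux_params(r_in = fl$r_in %||% 0,
              efflux_kind = fl$efflux_kind %||% "zero",
              efflux_glc = as_vec(fl$efflux_glc),
              efflux_frc = as_vec(fl$efflux_frc))
}

#' Instantiate a scenario (and its grid) from a configuration
#'
#' @param config configuration list (see [default_config()]).
#' @param name scenario name under \code{config$scenarios}.
#' @return List with elements \code{scenario} ([param_scenario()]) and
#'   \code{grid} ([grid_spec()] or NULL when the entry defines none).
#' @export
scenario_from_config <- function(config, name) {
  sc <- config$scenarios[[name]]
  if (is.null(sc)) stop("no scenario named '", name, "' in config", call. = FALSE)
  inv <- sc$invertase
  scenario <- param_scenario(
    name = name,
    invertase = invertase_params(inv$v_max, inv$k_m, inv$k_i_glc, inv$k_i_frc),
    fluxes = fluxes_from_config(sc$fluxes),
    temperature_label = sc$temperature_label %||% "",
    compartment_label = sc$compartment_label %||% "")
  grid <- NULL
  if (!is.null(sc$grid)) {
    g <- sc$grid
    grid <- grid_spec(glc_range = unlist(g$glc_range),
                      frc_range = unlist(g$frc_range),
                      suc_planes = unlist(g$suc_planes),
                      n_glc = g$n_glc %||% 50L, n_frc = g$n_frc %||% 50L,
                      units = g$units %||% "umol_gFW")
  }
  list(scenario = scenario, grid = grid)
}

scenario_to_config_entry <- function(scenario, grid = NULL) {
  entry <- list(
    temperature_label = scenario$temperature_label,
    compartment_label = scenario$compartment_label,
    invertase = unclass(scenario$invertase),
    fluxes = Filter(Negate(is.null), list(
      r_in = scenario$fluxes$r_in,
      efflux_kind = scenario$fluxes$efflux_kind,
      efflux_glc = as.list(scenario$fluxes$efflux_glc),
      efflux_frc = as.list(scenario$fluxes$efflux_frc))))
  if (!is.null(grid)) entry$grid <- unclass(grid)
  entry
}

#' Write a generated scenario pair as a configuration fixture
#'
#' Serialises the warm and cold scenarios of a [generate_scenario_pair()]
#' result, with their grids, in the same configuration format
#' [read_scenario_config()] consumes, so generated fixtures round-trip
#' through the ordinary configuration path.
#'
#' @param pair a [generate_scenario_pair()] result.
#' @param path output path (\code{.yaml} or \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_scenario_pair_config <- function(pair, path) {
  stopifnot(inherits(pair, "scenario_pair"))
  config <- list(scenarios = stats::setNames(list(
    scenario_to_config_entry(pair$warm, pair$grids$warm),
    scenario_to_config_entry(pair$cold, pair$grids$cold)),
    c(pair$warm$name, pair$cold$name)))
  write_scenario_config(config, path)
}

# compartment_spec objects from the nested config representation
compartments_from_config <- function(config) {
  lapply(stats::setNames(names(config$compartments),
                         names(config$compartments)), function(nm) {
    cc <- config$compartments[[nm]]
    sf <- cc$sugar_fractions
    rows <- do.call(rbind, lapply(names(sf), function(sugar) {
      data.frame(sugar = sugar, temperature = names(sf[[sugar]]),
                 fraction = unlist(sf[[sugar]], use.names = FALSE))
    }))
    compartment_spec(nm, cc$volume_fraction, rows)
  })
}
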