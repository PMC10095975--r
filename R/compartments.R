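#' Compartment specification
#'
#' Volume share and sugar-distribution fractions of one subcellular
#' compartment. The defaults used throughout are cytosol = 5 % and
#' vacuole = 80 % of total cell volume.
#'
#' @param name compartment label (e.g. \code{"cytosol"}).
#' @param volume_fraction fraction of total cell volume, in (0, 1].
#' @param sugar_fractions data frame with columns \code{sugar} (here
#'   \code{"sucrose"} or \code{"hexose"}), \code{temperature} (label, e.g.
#'   \code{"22C"}) and \code{fraction} (share of the whole-tissue amount
#'   residing in this compartment, in [0, 1]).
#' @return An object of class \code{"compartment_spec"}.
#' @export
compartment_spec <- function(name, volume_fraction, sugar_fractions) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(volume_fraction), length(volume_fraction) == 1L)
  if (volume_fraction <= 0 || volume_fraction > 1) {
    stop("volume_fraction must be in (0, 1]", call. = FALSE)
  }
  stopifnot(is.data.frame(sugar_fractions),
            all(c("sugar", "temperature", "fraction") %in% names(sugar_fractions)))
  if (any(sugar_fractions$fraction < 0 | sugar_fractions$fraction > 1)) {
    stop("sugar fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, volume_fraction = volume_fraction,
                 sugar_fractions = sugar_fractions),
            class = "compartment_spec")
}

#' Default cytosol and vacuole compartments
#'
#' Cytosol 5 % and vacuole 80 % of cell volume, with the subcellular sugar
#' distribution used for the subcellular analyses: at 22 C, 50 % of sucrose
#' and 30 % of hexoses cytosolic, 25 % of sucrose and 55 % of hexoses
#' vacuolar; at 4 C, 40 %/30 % cytosolic and 33 %/50 % vacuolar.
#'
#' @return Named list with elements \code{cytosol} and \code{vacuole}.
#' @export
default_compartments <- function() {
  frac <- function(suc22, hex22, suc4, hex4) {
    data.frame(sugar = rep(c("sucrose", "hexose"), 2L),
               temperature = rep(c("22C", "4C"), each = 2L),
               fraction = c(suc22, hex22, suc4, hex4))
  }
  list(
    cytosol = compartment_spec("cytosol", 0.05, frac(0.50, 0.30, 0.40, 0.30)),
    vacuole = compartment_spec("vacuole", 0.80, frac(0.25, 0.55, 0.33, 0.50))
  )
}

#' Whole-tissue sugar amounts
#'
#' @param sucrose,glucose,fructose amounts (umol gFW^-1), non-negative.
#' @param fw_to_volume fresh-weight-to-volume conversion (ml gFW^-1);
#'   default 1 under the 1 g fresh weight = 1 ml water assumption.
#' @return An object of class \code{"tissue_amounts"}.
#' @export
tissue_amounts <- function(sucrose = 0, glucose = 0, fructose = 0,
                           fw_to_volume = 1) {
  vals <- c(sucrose = sucrose, glucose = glucose, fructose = fructose)
  if (any(vals < 0)) stop("amounts must be non-negative", call. = FALSE)
  if (fw_to_volume <= 0) stop("fw_to_volume must be > 0", call. = FALSE)
  structure(list(amounts = vals, fw_to_volume = fw_to_volume),
            class = "tissue_amounts")
}

lookup_fraction <- function(comp, sugar, temperature) {
  # glucose/fructose share the jointly measured "hexose" distribution
  category <- if (sugar %in% c("glucose", "fructose", "hexose")) "hexose" else sugar
  sf <- comp$sugar_fractions
  hit <- sf$sugar == category & sf$temperature == temperature
  if (!any(hit)) {
    stop("no distribution fraction defined for ", sugar, " at ", temperature,
         " in compartment ", comp$name, call. = FALSE)
  }
  sf$fraction[which(hit)[1L]]
}

#' Compartment-specific effective concentration
#'
#' Converts a whole-tissue sugar amount into the molar concentration inside
#' one compartment:
#' \deqn{c = \frac{\mathrm{fraction} \cdot \mathrm{amount}}
#'   {\mathrm{volume\_fraction} \cdot \mathrm{fw\_to\_volume}}}
#' in mM, where \code{fraction} is the compartment's share of the amount at
#' the given temperature. With the default volume fractions, equal amounts and
#' shares yield a 16-fold lower concentration in the vacuole than in the
#' cytosol.
#'
#' @param amounts a [tissue_amounts()] object, or a numeric amount
#'   (umol gFW^-1) interpreted with \code{fw_to_volume = 1}. Numeric amounts
#'   may be vectors.
#' @param comp a [compartment_spec()].
#' @param sugar \code{"sucrose"}, \code{"glucose"}, \code{"fructose"} or
#'   \code{"hexose"}.
#' @param temperature temperature label matching the compartment's fractions.
#' @return Effective concentration(s) in mM.
#' @export
effective_concentration <- function(amounts, comp, sugar, temperature) {
  stopifnot(inherits(comp, "compartment_spec"))
  if (inherits(amounts, "tissue_amounts")) {
    amount <- amounts$amounts[[sugar]]
    fw <- amounts$fw_to_volume
  } else {
    if (any(amounts < 0)) stop("amounts must be non-negative", call. = FALSE)
    amount <- amounts
    fw <- 1
  }
  frac <- lookup_fraction(comp, sugar, temperature)
  frac * amount / (comp$volume_fraction * fw)
}

#' Concentration fold ratio between two compartments
#'
#' The dilution experienced by a given amount moved from compartment
#' \code{a} into compartment \code{b}: \code{volume_fraction(b) /
#' volume_fraction(a)}. Cytosol (5 %) versus vacuole (80 %) gives 16.
#'
#' @param comp_a,comp_b [compartment_spec()] objects.
#' @return Fold ratio (dimensionless).
#' @export
dilution_factor <- function(comp_a, comp_b) {
  stopifnot(inherits(comp_a, "compartment_spec"),
            inherits(comp_b, "compartment_spec"))
  if (comp_a$volume_fraction <= 0 || comp_b$volume_fraction <= 0) {
    stop("volume fractions must be > 0", call. = FALSE)
  }
  comp_b$volume_fraction / comp_a$volume_fraction
}

#' Build subcellular parameter scenarios with their default grids
#'
#' Constructs one [param_scenario()] per temperature x compartment
#' combination, each paired with a [grid_spec()] whose sucrose planes are the
#' compartment-specific ranges analysed in the subcellular study (cytosol
#' 22 C: 8-24 mM; vacuole 22 C: 0.25-0.75 mM; cytosol 4 C: 25.6-51.2 mM;
#' vacuole 4 C: 1.32-2.64 mM) and whose hexose axes are effective
#' concentrations derived from whole-tissue hexose amount ranges via
#' [effective_concentration()].
#'
#' Note an asymmetry kept on purpose: the sucrose plane ranges are fixed
#' reference values (they are not all reproducible from the distribution
#' fractions under a single formula), while the hexose axes are derived
#' from the formula.
#'
#' @param config configuration list as returned by [default_config()] (or
#'   read with [read_scenario_config()]); must contain \code{compartments},
#'   \code{isoforms} (per-compartment invertase parameters at each
#'   temperature), \code{subcellular_sucrose_planes} and
#'   \code{whole_cell_hexose_amounts}.
#' @param temperatures temperature labels to build (default both).
#' @param compartment_names compartments to build (default both).
#' @return Named list (e.g. \code{"cytosol_22C"}) of lists with elements
#'   \code{scenario} and \code{grid}.
#' @export
build_subcellular_scenarios <- function(config = default_config(),
                                        temperatures = c("22C", "4C"),
                                        compartment_names = c("cytosol", "vacuole")) {
  comps <- compartments_from_config(config)
  out <- list()
  for (temp in temperatures) {
    for (cn in compartment_names) {
      iso <- config$isoforms[[cn]][[temp]]
      if (is.null(iso)) {
        stop("config lacks invertase parameters for ", cn, " at ", temp,
             call. = FALSE)
      }
      planes <- config$subcellular_sucrose_planes[[cn]][[temp]]
      if (is.null(planes)) {
        stop("config lacks sucrose planes for ", cn, " at ", temp,
             call. = FALSE)
      }
      hex_amounts <- config$whole_cell_hexose_amounts[[temp]]
      hex_range <- effective_concentration(hex_amounts, comps[[cn]],
                                           "hexose", temp)
      sc <- param_scenario(
        name = paste(cn, temp, sep = "_"),
        invertase = invertase_params(iso$v_max, iso$k_m, iso$k_i_glc,
                                     iso$k_i_frc),
        fluxes = flux_params(r_in = iso$r_in, efflux_kind = "zero"),
        temperature_label = temp, compartment_label = cn)
      grid <- grid_spec(glc_range = hex_range, frc_range = hex_range,
                        suc_planes = planes, units = "mM")
      out[[sc$name]] <- list(scenario = sc, grid = grid)
    }
  }
  out
}
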