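# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runif1 <- function(range) stats::runif(1L, range[1L], range[2L])

#' Template for synthetic ambient/cold scenario pairs
#'
#' Describes the distribution from which 22 C parameter sets are drawn and
#' how the 4 C counterpart is derived: maximal invertase rate and sucrose
#' influx are attenuated by factors in (0, 1] (cold reduces enzymatic
#' capacity and carbon uptake), binding constants are kept
#' temperature-stable, and the concentration grids are shifted upward
#' (cold-induced sugar accumulation). The defaults are synthetic placeholders
#' structured like experimentally determined ambient/cold parameter sets:
#' \code{v_max} in
#' [1, 10] umol h^-1 gFW^-1, \code{K_M} in the low-millimolar range [1, 10]
#' mM, inhibition constants in [0.5, 20] mM, \code{r_in} in [0.1, 1], cold
#' attenuation in [0.2, 0.8]. Whole-cell grids default to sucrose planes
#' 1-3 umol/gFW at 22 C and 4-8 at 4 C with hexose axes 1-3 and 5-15
#' umol/gFW.
#'
#' @param v_max_range,k_m_range,k_i_range,r_in_range uniform draw ranges for
#'   the 22 C invertase and influx parameters.
#' @param vmax_attenuation_range,rin_attenuation_range uniform ranges of the
#'   multiplicative 4 C attenuation factors, within (0, 1].
#' @param warm_suc_planes,cold_suc_planes sucrose plane values (umol/gFW).
#' @param warm_hexose_range length-2 hexose axis range at 22 C (umol/gFW).
#' @param cold_hexose_multiplier factor applied to both ends of the hexose
#'   range at 4 C (default 5).
#' @param n_hexose grid resolution per hexose axis.
#' @param efflux_vmax_range,efflux_km_range draw ranges for the (shared)
#'   Michaelis-Menten hexose efflux parameters.
#' @param seed integer seed recorded in every generated artefact.
#' @return An object of class \code{"scenario_template"}.
#' @export
scenario_template <- function(v_max_range = c(1, 10),
                              k_m_range = c(1, 10),
                              k_i_range = c(0.5, 20),
                              r_in_range = c(0.1, 1),
                              vmax_attenuation_range = c(0.2, 0.8),
                              rin_attenuation_range = c(0.2, 0.8),
                              warm_suc_planes = c(1, 2, 3),
                              cold_suc_planes = c(4, 6, 8),
                              warm_hexose_range = c(1, 3),
                              cold_hexose_multiplier = 5,
                              n_hexose = 50L,
                              efflux_vmax_range = c(0.5, 5),
                              efflux_km_range = c(1, 10),
                              seed = 1L) {
  for (r in list(v_max_range, k_m_range, k_i_range, r_in_range,
                 vmax_attenuation_range, rin_attenuation_range,
                 warm_hexose_range, efflux_vmax_range, efflux_km_range)) {
    stopifnot(length(r) == 2L, r[1L] <= r[2L], all(r > 0))
  }
  if (any(vmax_attenuation_range > 1) || any(rin_attenuation_range > 1)) {
    stop("attenuation factors must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(v_max_range = v_max_range, k_m_range = k_m_range,
         k_i_range = k_i_range, r_in_range = r_in_range,
         vmax_attenuation_range = vmax_attenuation_range,
         rin_attenuation_range = rin_attenuation_range,
         warm_suc_planes = warm_suc_planes,
         cold_suc_planes = cold_suc_planes,
         warm_hexose_range = warm_hexose_range,
         cold_hexose_multiplier = cold_hexose_multiplier,
         n_hexose = as.integer(n_hexose),
         efflux_vmax_range = efflux_vmax_range,
         efflux_km_range = efflux_km_range,
         seed = as.integer(seed)),
    class = "scenario_template"
  )
}

#' Generate a matched 22 C / 4 C scenario pair
#'
#' Draws one ambient parameter set from the template, derives the cold set by
#' attenuating \code{v_max} and \code{r_in} (binding constants shared), and
#' builds the two default whole-cell grids (cold grid shifted upward). The
#' same seed always regenerates the identical pair.
#'
#' @param template a [scenario_template()].
#' @return List of class \code{"scenario_pair"}: \code{warm}, \code{cold}
#'   ([param_scenario()]s), \code{grids} (list \code{warm}, \code{cold} of
#'   [grid_spec()]s), \code{attenuation} (the drawn factors),
#'   \code{template}, \code{seed}.
#' @export
generate_scenario_pair <- function(template) {
  stopifnot(inherits(template, "scenario_template"))
  with_seed(template$seed, {
    v_max <- runif1(template$v_max_range)
    k_m <- runif1(template$k_m_range)
    k_i_glc <- runif1(template$k_i_range)
    k_i_frc <- runif1(template$k_i_range)
    r_in <- runif1(template$r_in_range)
    eff_v <- runif1(template$efflux_vmax_range)
    eff_k <- runif1(template$efflux_km_range)
    a_vmax <- runif1(template$vmax_attenuation_range)
    a_rin <- runif1(template$rin_attenuation_range)

    make_fluxes <- function(r) {
      flux_params(r_in = r, efflux_kind = "michaelis_menten",
                  efflux_glc = c(v_max = eff_v, k_m = eff_k),
                  efflux_frc = c(v_max = eff_v, k_m = eff_k))
    }
    warm <- param_scenario(
      name = sprintf("synthetic_22C_seed%d", template$seed),
      invertase = invertase_params(v_max, k_m, k_i_glc, k_i_frc),
      fluxes = make_fluxes(r_in),
      temperature_label = "22C", compartment_label = "whole_cell")
    cold <- param_scenario(
      name = sprintf("synthetic_4C_seed%d", template$seed),
      invertase = invertase_params(v_max * a_vmax, k_m, k_i_glc, k_i_frc),
      fluxes = make_fluxes(r_in * a_rin),
      temperature_label = "4C", compartment_label = "whole_cell")

    hex_warm <- template$warm_hexose_range
    hex_cold <- hex_warm * template$cold_hexose_multiplier
    grids <- list(
      warm = grid_spec(hex_warm, hex_warm, template$warm_suc_planes,
                       n_glc = template$n_hexose, n_frc = template$n_hexose),
      cold = grid_spec(hex_cold, hex_cold, template$cold_suc_planes,
                       n_glc = template$n_hexose, n_frc = template$n_hexose))
    structure(list(warm = warm, cold = cold, grids = grids,
                   attenuation = c(v_max = a_vmax, r_in = a_rin),
                   template = template, seed = template$seed),
              class = "scenario_pair")
  })
}

#' Generate a noisy synthetic time course
#'
#' Simulates the scenario and applies multiplicative log-normal observation
#' noise, \code{obs = sim * exp(eps)}, \code{eps ~ N(0, noise_sd)} i.i.d. per
#' observation -- metabolite measurements are positive and typically
#' heteroscedastic. The generating scenario, clean trajectory, seed and noise
#' level are attached as attributes for exact regeneration and for
#' truth-aware error reporting in [fit_parameters()].
#'
#' @param scenario a [param_scenario()].
#' @param initial initial state.
#' @param times output time grid (h), starting at 0.
#' @param noise_sd relative (log-scale) noise standard deviation, >= 0.
#' @param seed integer seed for the noise draws.
#' @return Data frame with columns \code{time, suc, glc, frc} and attributes
#'   \code{truth} (scenario), \code{clean} (noise-free trajectory),
#'   \code{noise_sd}, \code{seed}, \code{initial}.
#' @export
generate_time_course_data <- function(scenario, initial, times,
                                      noise_sd = 0.05, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  tc <- simulate(scenario, initial, times = times)
  clean <- as.matrix(tc[, c("suc", "glc", "frc")])
  noisy <- with_seed(seed, {
    eps <- matrix(stats::rnorm(length(clean), 0, noise_sd), nrow(clean))
    clean * exp(eps)
  })
  obs <- data.frame(time = tc$time, suc = noisy[, 1L], glc = noisy[, 2L],
                    frc = noisy[, 3L])
  structure(obs, truth = scenario, clean = as.data.frame(clean),
            noise_sd = noise_sd, seed = as.integer(seed),
            initial = as_state(initial))
}
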