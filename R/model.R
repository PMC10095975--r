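#' Metabolic state
#'
#' Concentrations of the three state variables in the fixed ordering
#' (sucrose, glucose, fructose) used for all vectors and matrices in the
#' package: index 1 = Suc, 2 = Glc, 3 = Frc.
#'
#' @param suc,glc,frc concentrations (mM), non-negative scalars.
#' @return Named numeric vector \code{c(suc=, glc=, frc=)} of class
#'   \code{"metabolic_state"}.
#' @export
metabolic_state <- function(suc, glc, frc) {
  x <- c(suc = suc, glc = glc, frc = frc)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  structure(x, class = c("metabolic_state", "numeric"))
}

as_state <- function(state) {
  if (inherits(state, "metabolic_state")) return(unclass(state))
  x <- unname(unlist(state))
  if (length(x) != 3L) stop("state must have 3 entries (suc, glc, frc)", call. = FALSE)
  if (any(x < 0)) stop("concentrations must be non-negative", call. = FALSE)
  c(suc = x[1L], glc = x[2L], frc = x[3L])
}

#' Parameter scenario
#'
#' A named bundle of all kinetic constants for one temperature x compartment
#' context (e.g. \code{"22C_cytosol"}), the unit at which scans, simulations
#' and fits operate.
#'
#' @param name scenario label, unique within a configuration.
#' @param invertase an [invertase_params()] object.
#' @param fluxes a [flux_params()] object.
#' @param temperature_label free-text temperature tag (e.g. \code{"22C"}).
#' @param compartment_label free-text compartment tag (e.g. \code{"whole_cell"}).
#' @return An object of class \code{"param_scenario"}.
#' @export
param_scenario <- function(name, invertase, fluxes,
                           temperature_label = "", compartment_label = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            inherits(invertase, "invertase_params"),
            inherits(fluxes, "flux_params"))
  structure(
    list(name = name, invertase = invertase, fluxes = fluxes,
         temperature_label = temperature_label,
         compartment_label = compartment_label),
    class = "param_scenario"
  )
}

#' @export
print.param_scenario <- function(x, ...) {
  cat("<param_scenario>", x$name, "\n")
  cat("  invertase: v_max =", x$invertase$v_max, " k_m =", x$invertase$k_m,
      " k_i_glc =", x$invertase$k_i_glc, " k_i_frc =", x$invertase$k_i_frc, "\n")
  cat("  fluxes: r_in =", x$fluxes$r_in, " efflux =", x$fluxes$efflux_kind, "\n")
  invisible(x)
}

#' Metabolic functions of sucrose, glucose and fructose
#'
#' The metabolic function of a species is the sum of reaction rates affecting
#' it, i.e. the right-hand side of its ODE. For sucrose,
#' \eqn{f(Suc) = r_{in} - r_{inv}}. In scan mode
#' (\code{include_efflux = FALSE}, the default used for the surface analyses)
#' the hexose functions are the hydrolysis gain alone,
#' \eqn{f(Glc) = f(Frc) = r_{inv}}; in full ODE mode the hexose efflux is
#' subtracted.
#'
#' @param scenario a [param_scenario()].
#' @param state a [metabolic_state()] (or numeric length-3 vector ordered
#'   suc, glc, frc).
#' @param include_efflux logical; subtract hexose efflux terms from
#'   \eqn{f(Glc)} and \eqn{f(Frc)}.
#' @return Named numeric vector \code{c(f_suc=, f_glc=, f_frc=)}
#'   (umol h^-1 gFW^-1).
#' @export
metabolic_functions <- function(scenario, state, include_efflux = FALSE) {
  stopifnot(inherits(scenario, "param_scenario"))
  x <- as_state(state)
  r_inv <- invertase_rate(scenario$invertase, x[["suc"]], x[["glc"]], x[["frc"]])
  out_g <- if (include_efflux) efflux_rate(scenario$fluxes, "glc", x[["glc"]]) else 0
  out_f <- if (include_efflux) efflux_rate(scenario$fluxes, "frc", x[["frc"]]) else 0
  c(f_suc = scenario$fluxes$r_in - r_inv,
    f_glc = r_inv - out_g,
    f_frc = r_inv - out_f)
}

#' ODE right-hand side
#'
#' Time derivatives (dSuc/dt, dGlc/dt, dFrc/dt): identical to
#' [metabolic_functions()] with \code{include_efflux = TRUE}.
#'
#' @inheritParams metabolic_functions
#' @return Unnamed numeric vector of length 3, ordered (Suc, Glc, Frc).
#' @export
ode_rhs <- function(scenario, state) {
  unname(metabolic_functions(scenario, state, include_efflux = TRUE))
}

#' Evaluate metabolic functions with their Jacobian and Hessians
#'
#' Bundles the function values, the 3x3 Jacobian \eqn{\partial f_i/\partial x_j}
#' and the three symmetric 3x3 Hessians (one per metabolic function) at one
#' state. Row 1 of the Jacobian is \eqn{(j_{11}, j_{12}, j_{13})} of
#' \eqn{f(Suc)}; the \code{suc} Hessian holds
#' \eqn{h_{f(Suc),11}, h_{f(Suc),12}, h_{f(Suc),13}} in its first row.
#'
#' @inheritParams metabolic_functions
#' @return List of class \code{"function_evaluation"} with elements
#'   \code{state}, \code{f}, \code{jacobian}, \code{hessians} (named list
#'   \code{suc}, \code{glc}, \code{frc}).
#' @export
evaluate_functions <- function(scenario, state, include_efflux = FALSE) {
  x <- as_state(state)
  structure(
    list(state = x,
         f = metabolic_functions(scenario, x, include_efflux),
         jacobian = analytic_jacobian(scenario, x, include_efflux),
         hessians = list(
           suc = analytic_hessian(scenario, x, "suc", include_efflux),
           glc = analytic_hessian(scenario, x, "glc", include_efflux),
           frc = analytic_hessian(scenario, x, "frc", include_efflux))),
    class = "function_evaluation"
  )
}
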