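#' Integrate the single-compartment ODE system
#'
#' Solves dSuc/dt = r_in - r_inv, dGlc/dt = r_inv - r_out,Glc,
#' dFrc/dt = r_inv - r_out,Frc with a stiff-capable integrator
#' (\code{deSolve::ode}, method \code{"lsoda"} by default) using the analytic
#' Jacobian. Small negative excursions produced by the integrator are guarded
#' by evaluating rates at \code{max(x, 0)}.
#'
#' @param scenario a [param_scenario()].
#' @param initial initial [metabolic_state()] (or numeric length-3 vector).
#' @param t_end end time (h), > 0.
#' @param times optional explicit output time grid (overrides \code{t_end}
#'   and \code{n_out}); must start at 0 and be strictly increasing.
#' @param n_out number of equally spaced output times (default 201).
#' @param rtol,atol relative/absolute solver tolerances (defaults 1e-8 and
#'   1e-10 mM).
#' @param method \code{deSolve} integration method (default \code{"lsoda"}).
#' @return Data frame of class \code{"time_course"} with columns
#'   \code{time, suc, glc, frc}; solver diagnostics in attribute
#'   \code{"diagnostics"}, the scenario in attribute \code{"scenario"}.
#' @export
simulate <- function(scenario, initial, t_end = NULL, times = NULL,
                     n_out = 201L, rtol = 1e-8, atol = 1e-10,
                     method = "lsoda") {
  stopifnot(inherits(scenario, "param_scenario"))
  y0 <- as_state(initial)
  if (is.null(times)) {
    if (is.null(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
    times <- seq(0, t_end, length.out = n_out)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  rhs <- function(t, y, parms) {
    list(ode_rhs(scenario, pmax(y, 0)))
  }
  jac <- function(t, y, parms) {
    analytic_jacobian(scenario, pmax(y, 0), include_efflux = TRUE)
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      jacfunc = jac, jactype = "fullusr",
                      method = method, rtol = rtol, atol = atol)
  diagn <- attributes(sol)[c("istate", "rstate")]
  if (any(!is.finite(sol[, -1L])) || nrow(sol) < length(times)) {
    stop("ODE integration failed (istate = ",
         paste(diagn$istate, collapse = ","), ")", call. = FALSE)
  }
  df <- as.data.frame(sol)
  names(df) <- c("time", "suc", "glc", "frc")
  structure(df, class = c("time_course", "data.frame"),
            scenario = scenario,
            diagnostics = list(istate = diagn$istate, rtol = rtol, atol = atol,
                               method = method))
}

#' Coupled cytosol/vacuole system
#'
#' Assembles a two-compartment model: each compartment runs its own
#' invertase/flux scenario on its local concentrations, and the sugars are
#' exchanged across the tonoplast -- sucrose from cytosol into the vacuole,
#' hexoses from vacuole back to the cytosol -- at rates first-order in the
#' donor concentration (Michaelis-Menten transport optional). Concentration
#' changes are volume-consistent: a transfer removing \code{k * c_donor} from
#' the donor adds \code{k * c_donor * phi_donor / phi_acceptor} to the
#' acceptor, so the volume-weighted total amount is conserved.
#'
#' @param cytosol,vacuole [param_scenario()] objects acting on local
#'   concentrations.
#' @param transport list with per-sugar transport parameters: for
#'   \code{kind = "first_order"} rate constants \code{k_suc, k_glc, k_frc}
#'   (h^-1); for \code{kind = "michaelis_menten"} lists
#'   \code{suc = c(v_max=, k_m=)} etc.
#' @param volume_fractions named numeric, default
#'   \code{c(cytosol = 0.05, vacuole = 0.80)}.
#' @return An object of class \code{"coupled_scenarios"} usable with
#'   [simulate_coupled()].
#' @export
coupled_scenarios <- function(cytosol, vacuole,
                              transport = list(kind = "first_order",
                                               k_suc = 0, k_glc = 0, k_frc = 0),
                              volume_fractions = c(cytosol = 0.05, vacuole = 0.80)) {
  stopifnot(inherits(cytosol, "param_scenario"),
            inherits(vacuole, "param_scenario"),
            all(c("cytosol", "vacuole") %in% names(volume_fractions)),
            all(volume_fractions > 0))
  kind <- transport$kind %||% "first_order"
  if (!kind %in% c("first_order", "michaelis_menten")) {
    stop("unknown transport kind: ", kind, call. = FALSE)
  }
  structure(list(cytosol = cytosol, vacuole = vacuole,
                 transport = transport,
                 volume_fractions = volume_fractions),
            class = "coupled_scenarios")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

transport_rate <- function(transport, sugar, donor_conc) {
  if ((transport$kind %||% "first_order") == "first_order") {
    k <- transport[[paste0("k_", sugar)]] %||% 0
    k * donor_conc
  } else {
    par <- transport[[sugar]]
    if (is.null(par)) return(0)
    par[["v_max"]] * donor_conc / (par[["k_m"]] + donor_conc)
  }
}

coupled_rhs <- function(cpl, y) {
  y <- pmax(y, 0)
  phi_c <- cpl$volume_fractions[["cytosol"]]
  phi_v <- cpl$volume_fractions[["vacuole"]]
  fc <- metabolic_functions(cpl$cytosol, y[1:3], include_efflux = TRUE)
  fv <- metabolic_functions(cpl$vacuole, y[4:6], include_efflux = TRUE)
  t_suc <- transport_rate(cpl$transport, "suc", y[1L])  # cytosol -> vacuole
  t_glc <- transport_rate(cpl$transport, "glc", y[5L])  # vacuole -> cytosol
  t_frc <- transport_rate(cpl$transport, "frc", y[6L])
  c(fc[1L] - t_suc,
    fc[2L] + t_glc * phi_v / phi_c,
    fc[3L] + t_frc * phi_v / phi_c,
    fv[1L] + t_suc * phi_c / phi_v,
    fv[2L] - t_glc,
    fv[3L] - t_frc)
}

#' Integrate the coupled two-compartment system
#'
#' @param cpl a [coupled_scenarios()] object.
#' @param initial numeric length-6 initial state, ordered
#'   (suc_cyt, glc_cyt, frc_cyt, suc_vac, glc_vac, frc_vac), non-negative.
#' @inheritParams simulate
#' @return Data frame of class \code{"time_course"} with columns \code{time,
#'   suc_cyt, glc_cyt, frc_cyt, suc_vac, glc_vac, frc_vac}.
#' @export
simulate_coupled <- function(cpl, initial, t_end = NULL, times = NULL,
                             n_out = 201L, rtol = 1e-8, atol = 1e-10,
                             method = "lsoda") {
  stopifnot(inherits(cpl, "coupled_scenarios"), length(initial) == 6L)
  if (any(initial < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  if (is.null(times)) {
    if (is.null(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
    times <- seq(0, t_end, length.out = n_out)
  }
  nm <- c("suc_cyt", "glc_cyt", "frc_cyt", "suc_vac", "glc_vac", "frc_vac")
  y0 <- stats::setNames(as.numeric(initial), nm)
  rhs <- function(t, y, parms) list(coupled_rhs(cpl, y))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (any(!is.finite(sol[, -1L])) || nrow(sol) < length(times)) {
    stop("coupled ODE integration failed", call. = FALSE)
  }
  df <- as.data.frame(sol)
  names(df) <- c("time", nm)
  structure(df, class = c("time_course", "data.frame"),
            coupled = cpl,
            diagnostics = list(rtol = rtol, atol = atol, method = method))
}

#' Total hexose units of a trajectory
#'
#' The conserved quantity of the closed system: 2*Suc + Glc + Frc for a
#' single compartment, or its volume-fraction-weighted sum across the two
#' compartments of a coupled trajectory.
#'
#' @param tc a [simulate()] or [simulate_coupled()] time course.
#' @return Numeric vector, one value per time point.
#' @export
hexose_units <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  if ("suc_cyt" %in% names(tc)) {
    phi <- attr(tc, "coupled")$volume_fractions
    phi[["cytosol"]] * (2 * tc$suc_cyt + tc$glc_cyt + tc$frc_cyt) +
      phi[["vacuole"]] * (2 * tc$suc_vac + tc$glc_vac + tc$frc_vac)
  } else {
    2 * tc$suc + tc$glc + tc$frc
  }
}

#' Locate a steady state of the single-compartment system
#'
#' Damped Newton iteration on the ODE right-hand side using the analytic
#' Jacobian, constrained to non-negative concentrations. A finite steady
#' state with \code{r_in > 0} requires nonzero hexose efflux.
#'
#' @param scenario a [param_scenario()].
#' @param initial_guess starting [metabolic_state()].
#' @param tol convergence threshold on \code{max(abs(ode_rhs))}
#'   (default 1e-10).
#' @param max_iter maximum Newton iterations.
#' @return List with \code{state} (named vector), \code{residual}
#'   (max abs RHS), \code{converged} (logical), \code{iterations}. A
#'   non-convergent search is reported explicitly, never as a silent root.
#' @export
find_steady_state <- function(scenario, initial_guess, tol = 1e-10,
                              max_iter = 200L) {
  stopifnot(inherits(scenario, "param_scenario"))
  x <- as_state(initial_guess)
  res <- function(x) ode_rhs(scenario, x)
  r <- res(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    J <- analytic_jacobian(scenario, x, include_efflux = TRUE)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) {
      # singular Jacobian: fall back to a scaled gradient-descent step on |r|^2
      step <- -as.numeric(t(J) %*% r)
      nrm <- sqrt(sum(step^2))
      if (nrm > 0) step <- step / nrm * max(1e-3, sqrt(sum(r^2)))
    }
    lambda <- 1
    improved <- FALSE
    for (k in 1:30) {
      x_new <- pmax(x + lambda * step, 0)
      r_new <- res(x_new)
      if (sum(r_new^2) < sum(r^2)) {
        x <- x_new; r <- r_new; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  converged <- max(abs(r)) < tol
  list(state = x, residual = max(abs(r)), converged = converged,
       iterations = if (exists("it")) it else 0L)
}

#' Write a time course as CSV with a JSON sidecar
#'
#' @param tc a [simulate()] or [simulate_coupled()] result.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_time_course_csv <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  df <- as.data.frame(tc)
  df[] <- lapply(df, function(x) format(x, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  scen <- attr(tc, "scenario")
  sidecar <- list(
    scenario = if (!is.null(scen)) list(
      name = scen$name, invertase = unclass(scen$invertase),
      fluxes = unclass(scen$fluxes)) else NULL,
    diagnostics = attr(tc, "diagnostics"),
    n_times = nrow(tc),
    package_version = as.character(utils::packageVersion("metfun"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a time course written by [write_time_course_csv()]
#'
#' @param path CSV path.
#' @return Data frame of class \code{"time_course"}.
#' @export
read_time_course_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("time_course", "data.frame"))
}
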