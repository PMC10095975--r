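#' Mass-action rate law specification
#'
#' Describes a (possibly reversible) reaction obeying the law of mass action:
#' the net rate is \eqn{k_f \prod_i S_i^{m_i} - k_b \prod_j P_j^{m_j}}, where
#' the molecularities \eqn{m} give the number of molecules of each reactant
#' participating in one reaction event.
#'
#' @param k_f forward rate constant (>= 0; units absorb the concentration
#'   powers).
#' @param k_b backward rate constant (>= 0). Default 0 (irreversible).
#' @param substrates named integer vector of substrate molecularities,
#'   e.g. \code{c(suc = 1)}. Molecularities must be integers >= 1.
#' @param products named integer vector of product molecularities, or
#'   \code{NULL} for an irreversible reaction.
#' @return An object of class \code{"mass_action_spec"}.
#' @seealso [mass_action_rate()]
#' @export
mass_action_spec <- function(k_f, k_b = 0, substrates, products = NULL) {
  stopifnot(is.numeric(k_f), length(k_f) == 1L, is.numeric(k_b), length(k_b) == 1L)
  if (k_f < 0 || k_b < 0) {
    stop("rate constants must be non-negative", call. = FALSE)
  }
  check_molecularities <- function(m, what) {
    if (is.null(m)) return(invisible(NULL))
    if (length(m) == 0L || is.null(names(m)) || any(!nzchar(names(m)))) {
      stop(what, " molecularities must be a named vector", call. = FALSE)
    }
    if (any(m < 1) || any(m != round(m))) {
      stop(what, " molecularities must be integers >= 1", call. = FALSE)
    }
  }
  check_molecularities(substrates, "substrate")
  check_molecularities(products, "product")
  structure(
    list(k_f = k_f, k_b = k_b,
         substrates = substrates, products = products),
    class = "mass_action_spec"
  )
}

#' Net mass-action rate at a state
#'
#' @param spec a [mass_action_spec()].
#' @param state named numeric vector of species concentrations (all species
#'   referenced by \code{spec} must be present, concentrations >= 0).
#' @return Net rate (concentration per time).
#' @export
mass_action_rate <- function(spec, state) {
  stopifnot(inherits(spec, "mass_action_spec"))
  species <- c(names(spec$substrates), names(spec$products))
  missing <- setdiff(species, names(state))
  if (length(missing) > 0L) {
    stop("state is missing species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(state[species] < 0)) {
    stop("negative concentration in state", call. = FALSE)
  }
  fwd <- spec$k_f * prod(state[names(spec$substrates)]^spec$substrates)
  bwd <- if (is.null(spec$products)) 0 else
    spec$k_b * prod(state[names(spec$products)]^spec$products)
  unname(fwd - bwd)
}

#' Invertase kinetic parameters
#'
#' Parameters of the product-inhibited Michaelis-Menten rate law for
#' invertase-catalysed sucrose hydrolysis. Glucose acts as a non-competitive
#' inhibitor (scales the whole rate), fructose as a competitive inhibitor
#' (raises the apparent \eqn{K_M}).
#'
#' Units follow the 1 g fresh weight = 1 ml water convention, under which
#' amounts in umol/gFW are numerically mM and rates in umol/h/gFW are mM/h.
#'
#' @param v_max maximal rate (umol h^-1 gFW^-1, i.e. mM/h); >= 0 (0 switches
#'   the reaction off, useful for degenerate/control cases).
#' @param k_m Michaelis constant for sucrose (mM); > 0.
#' @param k_i_glc non-competitive inhibition constant for glucose (mM); > 0.
#' @param k_i_frc competitive inhibition constant for fructose (mM); > 0.
#' @return An object of class \code{"invertase_params"}.
#' @export
invertase_params <- function(v_max, k_m, k_i_glc, k_i_frc) {
  vals <- c(v_max = v_max, k_m = k_m, k_i_glc = k_i_glc, k_i_frc = k_i_frc)
  if (any(!is.finite(vals)) || v_max < 0 || any(vals[-1L] <= 0)) {
    stop("invertase constants must be finite and positive (v_max may be 0)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "invertase_params")
}

#' Invertase reaction rate with product inhibition
#'
#' Computes
#' \deqn{r_{inv} = \frac{v_{max}\,S}{\left(K_M (1 + F/K_{i,F}) + S\right)\,
#'   \left(1 + G/K_{i,G}\right)}}
#' the standard mixed-inhibition encoding of competitive inhibition by
#' fructose and non-competitive inhibition by glucose. The rate is bounded by
#' \code{v_max}, increasing in sucrose and decreasing in each hexose.
#'
#' @param p an [invertase_params()] object.
#' @param suc,glc,frc concentrations (mM), non-negative; vectors are recycled
#'   to a common length.
#' @return Rate(s), same length as the longest input.
#' @export
invertase_rate <- function(p, suc, glc, frc) {
  stopifnot(inherits(p, "invertase_params"))
  if (any(suc < 0) || any(glc < 0) || any(frc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  d1 <- p$k_m * (1 + frc / p$k_i_frc) + suc
  d2 <- 1 + glc / p$k_i_glc
  p$v_max * suc / (d1 * d2)
}

# All first and second partial derivatives of the invertase rate with respect
# to (suc, glc, frc), in closed form. Shared by the analytic Jacobian/Hessian
# and the vectorised grid scan. With A = K_M*(1+F/KiF), D1 = A+S, D2 = 1+G/KiG:
#   r    =  V S / (D1 D2)
#   r_S  =  V A / (D1^2 D2)          r_SS = -2 V A / (D1^3 D2)
#   r_G  = -V S / (KiG D1 D2^2)      r_GG =  2 V S / (KiG^2 D1 D2^3)
#   r_F  = -V S K / (KiF D1^2 D2)    r_FF =  2 V S K^2 / (KiF^2 D1^3 D2)
#   r_SG = -V A / (KiG D1^2 D2^2)
#   r_SF =  V (K/KiF) (S - A) / (D1^3 D2)
#   r_GF =  V S K / (KiG KiF D1^2 D2^2)
invertase_derivs <- function(p, suc, glc, frc) {
  V <- p$v_max; K <- p$k_m; kg <- p$k_i_glc; kf <- p$k_i_frc
  A <- K * (1 + frc / kf)
  d1 <- A + suc
  d2 <- 1 + glc / kg
  list(
    r   = V * suc / (d1 * d2),
    dS  = V * A / (d1^2 * d2),
    dG  = -V * suc / (kg * d1 * d2^2),
    dF  = -V * suc * K / (kf * d1^2 * d2),
    hSS = -2 * V * A / (d1^3 * d2),
    hSG = -V * A / (kg * d1^2 * d2^2),
    hSF = V * (K / kf) * (suc - A) / (d1^3 * d2),
    hGG = 2 * V * suc / (kg^2 * d1 * d2^3),
    hGF = V * suc * K / (kg * kf * d1^2 * d2^2),
    hFF = 2 * V * suc * K^2 / (kf^2 * d1^3 * d2)
  )
}

#' Influx and hexose-efflux parameters
#'
#' Sucrose enters the pool at a constant biosynthesis rate \code{r_in};
#' glucose and fructose are consumed (e.g. phosphorylated by hexokinase) by an
#' efflux law that is irreversible Michaelis-Menten by default, optionally
#' first-order or absent.
#'
#' @param r_in constant sucrose influx rate (umol h^-1 gFW^-1); >= 0.
#' @param efflux_kind one of \code{"michaelis_menten"}, \code{"first_order"},
#'   \code{"zero"}.
#' @param efflux_glc,efflux_frc efflux law parameters per hexose: for
#'   \code{michaelis_menten} a named vector \code{c(v_max=, k_m=)}; for
#'   \code{first_order} \code{c(k=)}; ignored for \code{"zero"}.
#' @return An object of class \code{"flux_params"}.
#' @export
flux_params <- function(r_in = 0,
                        efflux_kind = c("michaelis_menten", "first_order", "zero"),
                        efflux_glc = NULL, efflux_frc = NULL) {
  efflux_kind <- match.arg(efflux_kind)
  if (!is.numeric(r_in) || length(r_in) != 1L || r_in < 0) {
    stop("r_in must be a single non-negative number", call. = FALSE)
  }
  check_efflux <- function(par, hexose) {
    needed <- switch(efflux_kind,
                     michaelis_menten = c("v_max", "k_m"),
                     first_order = "k",
                     zero = character(0))
    if (length(needed) == 0L) return(NULL)
    if (is.null(par) || !all(needed %in% names(par))) {
      stop("efflux parameters for ", hexose, " must supply: ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    par <- par[needed]
    if (any(par < 0)) stop("efflux parameters must be >= 0", call. = FALSE)
    par
  }
  structure(
    list(r_in = r_in, efflux_kind = efflux_kind,
         efflux_glc = check_efflux(efflux_glc, "glucose"),
         efflux_frc = check_efflux(efflux_frc, "fructose")),
    class = "flux_params"
  )
}

#' Hexose efflux rate
#'
#' @param p a [flux_params()] object.
#' @param hexose \code{"glc"} or \code{"frc"}.
#' @param conc hexose concentration(s) (mM), non-negative.
#' @return Efflux rate(s); 0 at zero concentration for every law.
#' @export
efflux_rate <- function(p, hexose = c("glc", "frc"), conc) {
  stopifnot(inherits(p, "flux_params"))
  hexose <- match.arg(hexose)
  if (any(conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  par <- if (hexose == "glc") p$efflux_glc else p$efflux_frc
  switch(p$efflux_kind,
    michaelis_menten = par[["v_max"]] * conc / (par[["k_m"]] + conc),
    first_order = par[["k"]] * conc,
    zero = rep(0, length(conc))
  )
}

# rate plus first and second derivative of the efflux law w.r.t. its hexose
efflux_derivs <- function(p, hexose, conc) {
  par <- if (hexose == "glc") p$efflux_glc else p$efflux_frc
  switch(p$efflux_kind,
    michaelis_menten = {
      v <- par[["v_max"]]; k <- par[["k_m"]]
      list(r = v * conc / (k + conc),
           d1 = v * k / (k + conc)^2,
           d2 = -2 * v * k / (k + conc)^3)
    },
    first_order = list(r = par[["k"]] * conc,
                       d1 = rep(par[["k"]], length(conc)),
                       d2 = rep(0, length(conc))),
    zero = list(r = rep(0, length(conc)),
                d1 = rep(0, length(conc)),
                d2 = rep(0, length(conc)))
  )
}
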