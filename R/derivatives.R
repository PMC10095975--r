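species_names <- c("suc", "glc", "frc")

#' Analytic Jacobian of the metabolic functions
#'
#' Closed-form matrix \eqn{J_{ij} = \partial f_i/\partial x_j} in the ordering
#' (Suc, Glc, Frc), hand-derived from the product-inhibited rate law (and, in
#' full ODE mode, the efflux laws). Under the default rate law the first row
#' satisfies \eqn{j_{11} \le 0}, \eqn{j_{12} \ge 0}, \eqn{j_{13} \ge 0}.
#'
#' @inheritParams metabolic_functions
#' @return 3x3 numeric matrix with dimnames (suc, glc, frc).
#' @export
analytic_jacobian <- function(scenario, state, include_efflux = FALSE) {
  stopifnot(inherits(scenario, "param_scenario"))
  x <- as_state(state)
  d <- invertase_derivs(scenario$invertase, x[["suc"]], x[["glc"]], x[["frc"]])
  grad_inv <- c(d$dS, d$dG, d$dF)
  J <- rbind(-grad_inv, grad_inv, grad_inv)
  if (include_efflux) {
    J[2L, 2L] <- J[2L, 2L] - efflux_derivs(scenario$fluxes, "glc", x[["glc"]])$d1
    J[3L, 3L] <- J[3L, 3L] - efflux_derivs(scenario$fluxes, "frc", x[["frc"]])$d1
  }
  dimnames(J) <- list(species_names, species_names)
  J
}

#' Analytic Hessian of one metabolic function
#'
#' Closed-form symmetric matrix of second partial derivatives
#' \eqn{\partial^2 f/\partial x_k \partial x_l} of the chosen metabolic
#' function. Symmetry is exact (identical expressions), not merely numerical.
#'
#' @inheritParams metabolic_functions
#' @param which_function \code{"suc"}, \code{"glc"} or \code{"frc"}.
#' @return 3x3 symmetric numeric matrix with dimnames (suc, glc, frc).
#' @export
analytic_hessian <- function(scenario, state,
                             which_function = c("suc", "glc", "frc"),
                             include_efflux = FALSE) {
  stopifnot(inherits(scenario, "param_scenario"))
  which_function <- match.arg(which_function)
  x <- as_state(state)
  d <- invertase_derivs(scenario$invertase, x[["suc"]], x[["glc"]], x[["frc"]])
  H_inv <- matrix(c(d$hSS, d$hSG, d$hSF,
                    d$hSG, d$hGG, d$hGF,
                    d$hSF, d$hGF, d$hFF), 3L, 3L)
  H <- if (which_function == "suc") -H_inv else H_inv
  if (include_efflux && which_function == "glc") {
    H[2L, 2L] <- H[2L, 2L] - efflux_derivs(scenario$fluxes, "glc", x[["glc"]])$d2
  }
  if (include_efflux && which_function == "frc") {
    H[3L, 3L] <- H[3L, 3L] - efflux_derivs(scenario$fluxes, "frc", x[["frc"]])$d2
  }
  dimnames(H) <- list(species_names, species_names)
  H
}

# first-derivative stencil in one coordinate: central unless the step would
# cross the non-negativity boundary, then second-order forward (one-sided)
fd_stencil_1 <- function(x_i, h) {
  if (x_i - h < 0) {
    list(offsets = c(0, h, 2 * h), weights = c(-3, 4, -1) / (2 * h),
         one_sided = TRUE)
  } else {
    list(offsets = c(-h, h), weights = c(-1, 1) / (2 * h), one_sided = FALSE)
  }
}

# pure second derivative stencil in one coordinate (same boundary rule)
fd_stencil_2 <- function(x_i, h) {
  if (x_i - h < 0) {
    list(offsets = c(0, h, 2 * h, 3 * h), weights = c(2, -5, 4, -1) / h^2,
         one_sided = TRUE)
  } else {
    list(offsets = c(-h, 0, h), weights = c(1, -2, 1) / h^2, one_sided = FALSE)
  }
}

#' Finite-difference derivative oracle
#'
#' Central-difference gradient (\code{order = 1}) or Hessian
#' (\code{order = 2}) of a scalar function of a state, used as an independent
#' numerical check on the analytic derivatives. Steps that would cross the
#' non-negativity boundary of a concentration fall back to a second-order
#' one-sided stencil; the result then carries attribute
#' \code{"one_sided" = TRUE}.
#'
#' @param f function taking a numeric length-3 state vector (suc, glc, frc)
#'   and returning a scalar.
#' @param state evaluation point (a [metabolic_state()] or numeric vector).
#' @param order 1 (gradient) or 2 (Hessian).
#' @param rel_step relative step size; defaults to \code{1e-6} for gradients
#'   and \code{1e-3} for Hessians (the larger second-order step balances
#'   truncation against float cancellation, which dominates where the
#'   curvature is many orders of magnitude below the function value). The
#'   absolute step in coordinate i is \code{rel_step * max(abs(x_i), 1)}.
#' @return Length-3 gradient or 3x3 Hessian matrix.
#' @export
finite_difference_oracle <- function(f, state, order = 1,
                                     rel_step = if (order == 1) 1e-6 else 1e-3) {
  x <- as_state(state)
  n <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  one_sided <- FALSE
  shift_eval <- function(i_offsets) {
    # i_offsets: named offsets per coordinate index
    xx <- x
    for (i in seq_along(i_offsets)) {
      xx[names(i_offsets)[i]] <- xx[names(i_offsets)[i]] + i_offsets[i]
    }
    f(unname(xx))
  }
  if (order == 1) {
    g <- numeric(n)
    for (i in seq_len(n)) {
      st <- fd_stencil_1(x[i], h[i])
      one_sided <- one_sided || st$one_sided
      vals <- vapply(st$offsets, function(o) {
        off <- o; names(off) <- names(x)[i]; shift_eval(off)
      }, numeric(1))
      g[i] <- sum(st$weights * vals)
    }
    names(g) <- names(x)
    return(structure(g, one_sided = one_sided))
  }
  if (order != 2) stop("order must be 1 or 2", call. = FALSE)
  H <- matrix(0, n, n, dimnames = list(names(x), names(x)))
  for (i in seq_len(n)) {
    st <- fd_stencil_2(x[i], h[i])
    one_sided <- one_sided || st$one_sided
    vals <- vapply(st$offsets, function(o) {
      off <- o; names(off) <- names(x)[i]; shift_eval(off)
    }, numeric(1))
    H[i, i] <- sum(st$weights * vals)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      si <- fd_stencil_1(x[i], h[i])
      sj <- fd_stencil_1(x[j], h[j])
      one_sided <- one_sided || si$one_sided || sj$one_sided
      acc <- 0
      for (a in seq_along(si$offsets)) {
        for (b in seq_along(sj$offsets)) {
          off <- c(si$offsets[a], sj$offsets[b])
          names(off) <- c(names(x)[i], names(x)[j])
          acc <- acc + si$weights[a] * sj$weights[b] * shift_eval(off)
        }
      }
      H[i, j] <- H[j, i] <- acc
    }
  }
  structure(H, one_sided = one_sided)
}

#' Scaled elasticity of a metabolic function
#'
#' The dimensionless log-log sensitivity
#' \eqn{\epsilon_{ij} = (x_j / f_i) \, \partial f_i / \partial x_j},
#' i.e. the relative change of metabolic function \eqn{f_i} per relative
#' change of concentration \eqn{x_j}.
#'
#' @inheritParams metabolic_functions
#' @param i function index (1 = Suc, 2 = Glc, 3 = Frc) or name.
#' @param j variable index or name, same convention.
#' @return Scalar elasticity. Errors if \eqn{f_i = 0} at the state
#'   (elasticity undefined).
#' @export
scaled_elasticity <- function(scenario, state, i, j, include_efflux = FALSE) {
  x <- as_state(state)
  idx <- function(k) if (is.character(k)) match(k, species_names) else as.integer(k)
  i <- idx(i); j <- idx(j)
  stopifnot(i %in% 1:3, j %in% 1:3)
  f <- metabolic_functions(scenario, x, include_efflux)
  if (f[i] == 0) {
    stop("elasticity undefined: metabolic function is zero at this state",
         call. = FALSE)
  }
  J <- analytic_jacobian(scenario, x, include_efflux)
  unname(x[j] / f[i] * J[i, j])
}

# max |a - b| relative to the largest magnitude entry of either matrix
# (scale-relative max-norm discrepancy; robust for near-zero entries)
matrix_rel_discrepancy <- function(a, b) {
  scale <- max(abs(a), abs(b), .Machine$double.xmin)
  max(abs(a - b)) / scale
}

#' Cross-check analytic derivatives against the finite-difference oracle
#'
#' Evaluates the analytic Jacobian and the three Hessians at a state,
#' recomputes them by central differences, and records the maximum
#' scale-relative discrepancy (max absolute entry difference divided by the
#' largest entry magnitude of the pair of matrices).
#'
#' @inheritParams metabolic_functions
#' @return List of class \code{"derivative_report"} with elements
#'   \code{analytic}, \code{numeric} (each with \code{jacobian} and
#'   \code{hessians}), \code{jacobian_rel_discrepancy},
#'   \code{hessian_rel_discrepancy}, \code{max_rel_discrepancy}.
#' @export
derivative_report <- function(scenario, state, include_efflux = FALSE) {
  x <- as_state(state)
  analytic <- evaluate_functions(scenario, x, include_efflux)
  f_i <- function(i) {
    function(s) metabolic_functions(scenario, s, include_efflux)[[i]]
  }
  num_jac <- t(vapply(1:3, function(i) {
    as.numeric(finite_difference_oracle(f_i(i), x, order = 1))
  }, numeric(3)))
  dimnames(num_jac) <- list(species_names, species_names)
  num_hess <- lapply(1:3, function(i) {
    finite_difference_oracle(f_i(i), x, order = 2)
  })
  names(num_hess) <- species_names
  jac_disc <- matrix_rel_discrepancy(analytic$jacobian, num_jac)
  hess_disc <- max(vapply(species_names, function(s) {
    matrix_rel_discrepancy(analytic$hessians[[s]], num_hess[[s]])
  }, numeric(1)))
  structure(
    list(analytic = list(jacobian = analytic$jacobian,
                         hessians = analytic$hessians),
         numeric = list(jacobian = num_jac, hessians = num_hess),
         jacobian_rel_discrepancy = jac_disc,
         hessian_rel_discrepancy = hess_disc,
         max_rel_discrepancy = max(jac_disc, hess_disc)),
    class = "derivative_report"
  )
}
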