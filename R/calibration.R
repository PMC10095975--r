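# map free parameter names into/out of a scenario
free_param_get <- function(scenario, name) {
  switch(name,
    v_max = scenario$invertase$v_max,
    k_m = scenario$invertase$k_m,
    k_i_glc = scenario$invertase$k_i_glc,
    k_i_frc = scenario$invertase$k_i_frc,
    r_in = scenario$fluxes$r_in,
    stop("unknown free parameter: ", name, call. = FALSE)
  )
}

free_param_set <- function(scenario, values) {
  for (name in names(values)) {
    v <- values[[name]]
    if (name %in% c("v_max", "k_m", "k_i_glc", "k_i_frc")) {
      scenario$invertase[[name]] <- v
    } else if (name == "r_in") {
      scenario$fluxes$r_in <- v
    } else {
      stop("unknown free parameter: ", name, call. = FALSE)
    }
  }
  scenario
}

#' Recover kinetic parameters from time-course data
#'
#' Weighted least squares on the log scale: the objective is the sum of
#' squared residuals \code{log(model + eps) - log(obs + eps)} over all time
#' points and species, minimised in log-parameter space (which enforces
#' positivity and handles scale-spanning parameters) with
#' \code{minpack.lm::nls.lm} under box constraints. Multiple starts
#' (the supplied initial guess plus random log-uniform perturbations) guard
#' against local optima; the best converged start is returned.
#'
#' Identifiability note: the inhibition constants \code{k_i_glc}/\code{k_i_frc}
#' are only weakly identifiable unless the experiment includes
#' hexose-perturbed initial conditions; by default only \code{v_max},
#' \code{k_m} and \code{r_in} are fitted.
#'
#' @param data observation table with columns \code{time, suc, glc, frc},
#'   e.g. from [generate_time_course_data()] or
#'   [read_time_course_csv()]. Rows may be in any order.
#' @param skeleton a [param_scenario()] supplying the model structure and the
#'   values of all parameters not being fitted.
#' @param free character vector of parameter names to fit, among
#'   \code{"v_max", "k_m", "k_i_glc", "k_i_frc", "r_in"}.
#' @param initial initial state for the simulations; defaults to the
#'   \code{initial} attribute of \code{data} if present.
#' @param init named numeric initial guesses (defaults: the skeleton values).
#' @param lower,upper named positive bounds (defaults: init / 100 and
#'   init * 100).
#' @param n_starts number of starts (default 10).
#' @param start_spread multiplicative spread of the random starts (each start
#'   perturbs init by factors log-uniform in [1/spread, spread]; default 3).
#' @param seed integer seed for the start perturbations.
#' @return List of class \code{"fit_result"}: \code{estimates} (named),
#'   \code{rss}, \code{converged}, \code{n_starts_converged}, \code{seed},
#'   and, when the data carry a generating truth, \code{relative_errors}.
#' @export
fit_parameters <- function(data, skeleton, free = c("v_max", "k_m", "r_in"),
                           initial = attr(data, "initial"),
                           init = NULL, lower = NULL, upper = NULL,
                           n_starts = 10L, start_spread = 3, seed = 1L) {
  stopifnot(inherits(skeleton, "param_scenario"),
            all(c("time", "suc", "glc", "frc") %in% names(data)))
  if (is.null(initial)) stop("initial state required", call. = FALSE)
  data <- data[order(data$time), , drop = FALSE]
  times <- data$time
  if (times[1L] > 0) times <- c(0, times)
  obs <- log(as.matrix(data[, c("suc", "glc", "frc")]) + 1e-9)

  if (is.null(init)) {
    init <- vapply(free, function(p) free_param_get(skeleton, p), numeric(1))
  }
  init <- init[free]
  if (any(is.na(init)) || any(init <= 0)) {
    stop("initial guesses must be positive for all free parameters",
         call. = FALSE)
  }
  if (is.null(lower)) lower <- init / 100
  if (is.null(upper)) upper <- init * 100
  if (any(lower <= 0)) stop("bounds must be positive", call. = FALSE)

  residuals_fn <- function(log_par) {
    par <- exp(log_par)
    names(par) <- free
    scen <- free_param_set(skeleton, as.list(par))
    tc <- tryCatch(
      simulate(scen, initial, times = times),
      error = function(e) NULL)
    if (is.null(tc)) return(rep(1e6, length(obs)))
    pred <- as.matrix(tc[match(data$time, tc$time), c("suc", "glc", "frc")])
    as.numeric(log(pred + 1e-9) - obs)
  }

  starts <- with_seed(seed, {
    c(list(init), lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
      init * exp(stats::runif(length(init), -log(start_spread),
                              log(start_spread)))
    }))
  })
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  best <- NULL
  n_conv <- 0L
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(s), lower = log(lower), upper = log(upper),
                         fn = residuals_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    if (ok) n_conv <- n_conv + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss, converged = ok)
    }
  }
  if (is.null(best)) {
    return(structure(list(estimates = stats::setNames(rep(NA_real_,
                                                          length(free)), free),
                          rss = NA_real_, converged = FALSE,
                          n_starts_converged = 0L, seed = seed),
                     class = "fit_result"))
  }
  estimates <- stats::setNames(exp(best$fit$par), free)
  result <- list(estimates = estimates, rss = best$rss,
                 converged = best$converged,
                 n_starts_converged = n_conv, seed = seed)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    true_vals <- vapply(free, function(p) free_param_get(truth, p), numeric(1))
    result$relative_errors <- abs(estimates - true_vals) / true_vals
  }
  structure(result, class = "fit_result")
}

#' Write a fit result as JSON
#'
#' @param fit a [fit_parameters()] result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- unclass(fit)
  out$estimates <- as.list(out$estimates)
  if (!is.null(out$relative_errors)) {
    out$relative_errors <- as.list(out$relative_errors)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
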