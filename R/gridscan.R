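#' Concentration grid specification
#'
#' A 3-D grid of hexose concentrations (glucose x fructose) evaluated on one
#' or more sucrose planes, mirroring the surface analyses in which each plane
#' corresponds to one sucrose concentration.
#'
#' @param glc_range,frc_range length-2 numeric ranges (min, max); a
#'   degenerate range is only allowed with a single point.
#' @param suc_planes explicit vector of sucrose plane values (>= 1 plane).
#' @param n_glc,n_frc number of grid points per hexose axis (default 50).
#' @param units unit flag, \code{"umol_gFW"} (numerically mM under the
#'   1 gFW = 1 ml convention) or \code{"mM"}; metadata carried through to
#'   serialised output.
#' @return An object of class \code{"grid_spec"}.
#' @export
grid_spec <- function(glc_range, frc_range, suc_planes,
                      n_glc = 50L, n_frc = 50L,
                      units = c("umol_gFW", "mM")) {
  units <- match.arg(units)
  check_axis <- function(range, n, what) {
    stopifnot(length(range) == 2L, is.numeric(range))
    if (any(range < 0)) stop(what, " range must be non-negative", call. = FALSE)
    if (range[2L] < range[1L]) stop(what, " range must be increasing", call. = FALSE)
    if (range[1L] == range[2L] && n != 1L) {
      stop(what, " range is degenerate but more than one point requested",
           call. = FALSE)
    }
    if (n < 1L) stop(what, " point count must be >= 1", call. = FALSE)
  }
  check_axis(glc_range, n_glc, "glc")
  check_axis(frc_range, n_frc, "frc")
  if (length(suc_planes) < 1L || any(suc_planes < 0)) {
    stop("at least one non-negative sucrose plane required", call. = FALSE)
  }
  structure(list(glc_range = as.numeric(glc_range),
                 frc_range = as.numeric(frc_range),
                 suc_planes = as.numeric(suc_planes),
                 n_glc = as.integer(n_glc), n_frc = as.integer(n_frc),
                 units = units),
            class = "grid_spec")
}

axis_points <- function(range, n) {
  if (n == 1L) mean(range) else seq(range[1L], range[2L], length.out = n)
}

scan_columns <- c("scenario", "suc", "glc", "frc",
                  "f_suc", "f_glc", "f_frc",
                  "j11", "j12", "j13", "j21", "j22", "j23",
                  "j31", "j32", "j33",
                  "hS11", "hS12", "hS13", "hS22", "hS23", "hS33",
                  "hG11", "hG12", "hG13", "hG22", "hG23", "hG33",
                  "hF11", "hF12", "hF13", "hF22", "hF23", "hF33")

#' Scan metabolic functions and derivatives over a concentration grid
#'
#' Evaluates \eqn{f(Suc)}, \eqn{f(Glc)}, \eqn{f(Frc)}, the full 3x3 Jacobian
#' and the unique entries of the three Hessians at every grid point, in the
#' deterministic ordering sucrose-plane major, then glucose, then fructose
#' (fructose fastest). All quantities come from the closed-form expressions,
#' vectorised over the grid.
#'
#' @param scenario a [param_scenario()].
#' @param grid a [grid_spec()].
#' @param include_efflux logical, as in [metabolic_functions()]; the surface
#'   analyses use \code{FALSE}.
#' @return Long-format data frame of class \code{"grid_scan_result"} with the
#'   fixed column set \code{scenario, suc, glc, frc, f_suc, f_glc, f_frc,
#'   j11..j33, hS11..hS33, hG11..hG33, hF11..hF33} (Hessians as upper
#'   triangles; symmetric). Grid spec, scenario and mode are carried as
#'   attributes.
#' @export
scan <- function(scenario, grid, include_efflux = FALSE) {
  stopifnot(inherits(scenario, "param_scenario"), inherits(grid, "grid_spec"))
  glc_pts <- axis_points(grid$glc_range, grid$n_glc)
  frc_pts <- axis_points(grid$frc_range, grid$n_frc)
  pts <- expand.grid(frc = frc_pts, glc = glc_pts, suc = grid$suc_planes,
                     KEEP.OUT.ATTRS = FALSE)  # frc fastest, suc slowest
  suc <- pts$suc; glc <- pts$glc; frc <- pts$frc
  n <- length(suc)

  d <- invertase_derivs(scenario$invertase, suc, glc, frc)
  fx <- scenario$fluxes
  if (include_efflux) {
    eg <- efflux_derivs(fx, "glc", glc)
    ef <- efflux_derivs(fx, "frc", frc)
  } else {
    zero <- rep(0, n)
    eg <- ef <- list(r = zero, d1 = zero, d2 = zero)
  }

  out <- data.frame(
    scenario = rep(scenario$name, n),
    suc = suc, glc = glc, frc = frc,
    f_suc = fx$r_in - d$r,
    f_glc = d$r - eg$r,
    f_frc = d$r - ef$r,
    j11 = -d$dS, j12 = -d$dG, j13 = -d$dF,
    j21 = d$dS, j22 = d$dG - eg$d1, j23 = d$dF,
    j31 = d$dS, j32 = d$dG, j33 = d$dF - ef$d1,
    hS11 = -d$hSS, hS12 = -d$hSG, hS13 = -d$hSF,
    hS22 = -d$hGG, hS23 = -d$hGF, hS33 = -d$hFF,
    hG11 = d$hSS, hG12 = d$hSG, hG13 = d$hSF,
    hG22 = d$hGG - eg$d2, hG23 = d$hGF, hG33 = d$hFF,
    hF11 = d$hSS, hF12 = d$hSG, hF13 = d$hSF,
    hF22 = d$hGG, hF23 = d$hGF, hF33 = d$hFF - ef$d2,
    stringsAsFactors = FALSE
  )
  if (anyNA(out)) stop("scan produced missing values", call. = FALSE)
  structure(out,
            class = c("grid_scan_result", "data.frame"),
            grid = grid, scenario = scenario,
            include_efflux = include_efflux)
}

scan_quantities <- function(result) {
  setdiff(names(result), c("scenario", "suc", "glc", "frc"))
}

#' Dynamic-range summary of a grid scan
#'
#' Per quantity: minimum, maximum, range (max - min), and the
#' order-of-magnitude span \code{log10(max(|x|) / min(|x| > 0))} of the
#' nonzero magnitudes (NA for an all-zero column).
#'
#' @param result a [scan()] result.
#' @param quantities columns to summarise; default all value columns.
#' @return Data frame with columns \code{quantity, min, max, range, oom_span}.
#' @export
dynamic_range_summary <- function(result, quantities = scan_quantities(result)) {
  stopifnot(inherits(result, "grid_scan_result"), nrow(result) > 0L)
  rows <- lapply(quantities, function(q) {
    x <- result[[q]]
    a <- abs(x[x != 0])
    data.frame(quantity = q, min = min(x), max = max(x),
               range = max(x) - min(x),
               oom_span = if (length(a) == 0L) NA_real_ else
                 log10(max(a) / min(a)))
  })
  do.call(rbind, rows)
}

interval_jaccard <- function(a, b) {
  # overlap of two closed intervals given as c(lo, hi)
  inter <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  union <- max(a[2L], b[2L]) - min(a[1L], b[1L])
  if (union == 0) return(if (a[1L] == b[1L]) 1 else 0)
  inter / union
}

j12_j13_overlap <- function(result) {
  interval_jaccard(range(result$j12), range(result$j13))
}

#' Compare two grid-scan results
#'
#' Reports the ratio of dynamic ranges of a chosen quantity and the degree of
#' overlap between the value intervals of \eqn{j_{12}} and \eqn{j_{13}}
#' (Jaccard overlap of their [min, max] ranges across the grid) in each scan
#' -- the diagnostic by which the warm scenario shows strongly overlapping
#' glucose and fructose sensitivities while the cold scenario separates them.
#'
#' @param a,b [scan()] results.
#' @param quantity value column to compare (default \code{"f_suc"}).
#' @return List with elements \code{quantity}, \code{range_a}, \code{range_b},
#'   \code{range_ratio} (a/b), \code{j12_j13_overlap_a},
#'   \code{j12_j13_overlap_b}, \code{overlap_difference} (a - b).
#' @export
compare_scenarios <- function(a, b, quantity = "f_suc") {
  stopifnot(inherits(a, "grid_scan_result"), inherits(b, "grid_scan_result"))
  if (!quantity %in% names(a) || !quantity %in% names(b)) {
    stop("quantity ", quantity, " not present in both scans", call. = FALSE)
  }
  range_a <- diff(range(a[[quantity]]))
  range_b <- diff(range(b[[quantity]]))
  ov_a <- j12_j13_overlap(a)
  ov_b <- j12_j13_overlap(b)
  list(quantity = quantity,
       range_a = range_a, range_b = range_b,
       range_ratio = range_a / range_b,
       j12_j13_overlap_a = ov_a,
       j12_j13_overlap_b = ov_b,
       overlap_difference = ov_a - ov_b)
}

#' Write a grid scan as CSV with a JSON sidecar
#'
#' The CSV carries the fixed column set of [scan()]; the sidecar
#' (\code{<path>.json}) records the scenario parameters, grid specification,
#' units, efflux mode and package version so the scan can be regenerated
#' exactly. Output is byte-deterministic for a given result.
#'
#' @param result a [scan()] result.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_scan_csv <- function(result, path) {
  stopifnot(inherits(result, "grid_scan_result"))
  df <- as.data.frame(result)[, scan_columns]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  grid <- attr(result, "grid")
  scenario <- attr(result, "scenario")
  sidecar <- list(
    scenario = list(name = scenario$name,
                    invertase = unclass(scenario$invertase),
                    fluxes = unclass(scenario$fluxes),
                    temperature_label = scenario$temperature_label,
                    compartment_label = scenario$compartment_label),
    grid = unclass(grid),
    units = grid$units,
    include_efflux = attr(result, "include_efflux"),
    n_records = nrow(result),
    package_version = as.character(utils::packageVersion("metfun"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
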