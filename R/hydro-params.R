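#' Physical parameters for the two-phase droplet model
#'
#' Bundles the physical constants of the contracting-network / cytosol model.
#' Units are fixed package-wide: lengths in micrometres, time in minutes,
#' forces in piconewtons; network density is in arbitrary units normalised so
#' that the turnover balance `k_a / k_d` equals one by default.
#'
#' The default parameter set is a calibration, not a measurement: `gamma` is
#' an M-phase-like contraction rate (order 1/turnover-time), `k_a = k_d = 1`
#' fixes the density scale, `eta = 1` sets the viscosity scale, and `zeta0`
#' is chosen once so that the simulated peak recentering speed of a 50 um
#' droplet falls in the experimentally observed 5-10 um/min band (see the
#' methods vignette). All values can be overridden.
#'
#' @param gamma Network contraction rate (1/min): slope of the inward network
#'   speed versus distance from the aggregate surface.
#' @param k_a Network assembly rate (density-units/min).
#' @param k_d Network disassembly rate (1/min).
#' @param eta Cytosol viscosity (pN min / um^2).
#' @param zeta0 Darcy friction coefficient scale (pN min / um^4 per
#'   density-unit^zeta_exp); the local friction is
#'   `zeta(rho) = zeta0 * eta * rho^zeta_exp`.
#' @param zeta_exp Exponent of the density dependence of the Darcy friction
#'   (default 0.3, calibrated; permeability decreases as `rho^(-zeta_exp)`).
#'   The linear law (`zeta_exp = 1`) overstates the sensitivity of centering
#'   to network turnover and understates its sensitivity to the contraction
#'   rate, inverting the observed hierarchy; see the methods vignette.
#' @param Gamma_agg Aggregate drag coefficient (pN min / um). `NULL` (default)
#'   derives a Stokes-like drag `6 * pi * eta_eff * a` at solve time, with
#'   `eta_eff = eta_eff_factor * eta`.
#' @param eta_eff_factor Dimensionless factor relating the effective viscosity
#'   felt by the moving aggregate to the cytosol viscosity.
#' @param grid_h Grid spacing (um). `NULL` (default) uses `a / 5`, which
#'   resolves the aggregate and makes the discretisation scale with geometry.
#' @param tol_ss Steady-state tolerance: pseudo-time stepping stops when
#'   `max |d rho/dt| < tol_ss * k_a`.
#' @param tol_div Divergence tolerance for the incompressible cytosol flow
#'   (1/min).
#' @param zeta_floor Friction floor keeping the pressure problem non-singular
#'   in network-free regions. `NULL` uses `1e-6 * zeta0 * eta * k_a / k_d`.
#'
#' @return An object of class `hydro_params`.
#' @export
hydro_params <- function(gamma = 0.2, k_a = 1, k_d = 1, eta = 1,
                         zeta0 = 1.25e-3, zeta_exp = 0.3, Gamma_agg = NULL,
                         eta_eff_factor = 1, grid_h = NULL, tol_ss = 1e-6,
                         tol_div = 1e-8, zeta_floor = NULL) {
  assert_scalar_num(gamma, "gamma", nonneg = TRUE)
  assert_scalar_num(k_a, "k_a", positive = TRUE)
  assert_scalar_num(k_d, "k_d", positive = TRUE)
  assert_scalar_num(eta, "eta", positive = TRUE)
  assert_scalar_num(zeta0, "zeta0", positive = TRUE)
  assert_scalar_num(zeta_exp, "zeta_exp", nonneg = TRUE)
  assert_scalar_num(eta_eff_factor, "eta_eff_factor", positive = TRUE)
  if (!is.null(Gamma_agg)) assert_scalar_num(Gamma_agg, "Gamma_agg", positive = TRUE)
  if (!is.null(grid_h)) assert_scalar_num(grid_h, "grid_h", positive = TRUE)
  assert_scalar_num(tol_ss, "tol_ss", positive = TRUE)
  assert_scalar_num(tol_div, "tol_div", positive = TRUE)
  if (is.null(zeta_floor)) zeta_floor <- 1e-6 * zeta0 * eta * (k_a / k_d)^zeta_exp
  assert_scalar_num(zeta_floor, "zeta_floor", positive = TRUE)
  structure(list(gamma = gamma, k_a = k_a, k_d = k_d, eta = eta,
                 zeta0 = zeta0, zeta_exp = zeta_exp, Gamma_agg = Gamma_agg,
                 eta_eff_factor = eta_eff_factor, grid_h = grid_h,
                 tol_ss = tol_ss, tol_div = tol_div, zeta_floor = zeta_floor),
            class = "hydro_params")
}

#' Droplet and aggregate geometry
#'
#' @param R Droplet radius (um).
#' @param a Aggregate radius (um), `0 < a < R`.
#' @param d Displacement of the aggregate centre from the droplet centre (um),
#'   along the symmetry axis; must satisfy `0 <= d <= R - a`.
#'
#' @return An object of class `droplet_geometry`.
#' @export
droplet_geometry <- function(R, a, d = 0) {
  assert_scalar_num(R, "R", positive = TRUE)
  assert_scalar_num(a, "a", positive = TRUE)
  assert_scalar_num(d, "d")
  if (a >= R) stop("aggregate radius `a` must be smaller than droplet radius `R`",
                   call. = FALSE)
  if (abs(d) > R - a) {
    stop(sprintf("aggregate displacement d = %.3g exceeds R - a = %.3g (aggregate outside droplet)",
                 d, R - a), call. = FALSE)
  }
  structure(list(R = R, a = a, d = d), class = "droplet_geometry")
}

#' @export
print.hydro_params <- function(x, ...) {
  cat("<hydro_params> gamma =", x$gamma, "/min, k_a =", x$k_a,
      ", k_d =", x$k_d, "/min, eta =", x$eta, ", zeta0 =", x$zeta0, "\n")
  invisible(x)
}

#' @export
print.droplet_geometry <- function(x, ...) {
  cat(sprintf("<droplet_geometry> R = %g um, a = %g um, d = %g um\n",
              x$R, x$a, x$d))
  invisible(x)
}

# Stokes-like aggregate drag (pN min / um)
aggregate_drag <- function(params, geom) {
  params$Gamma_agg %||% (6 * pi * params$eta_eff_factor * params$eta * geom$a)
}

#' Read a model parameter file
#'
#' Parameter files are flat JSON objects with keys
#' `{gamma, k_a, k_d, eta, zeta0, Gamma_agg, R, a_frac, d, grid_h, tol_ss,
#' tol_div, zeta_floor}`. Missing keys fall back to package defaults;
#' `a_frac` is the aggregate-to-droplet radius ratio.
#'
#' @param path Path to a JSON parameter file.
#' @return A list with elements `params` ([hydro_params]) and `geom`
#'   ([droplet_geometry]).
#' @export
read_hydro_config <- function(path) {
  cfg <- read_json_config(path)
  hydro_config_from_list(cfg)
}

hydro_config_from_list <- function(cfg) {
  def <- hydro_params()
  p <- hydro_params(
    gamma = cfg$gamma %||% def$gamma,
    k_a = cfg$k_a %||% def$k_a,
    k_d = cfg$k_d %||% def$k_d,
    eta = cfg$eta %||% def$eta,
    zeta0 = cfg$zeta0 %||% def$zeta0,
    zeta_exp = cfg$zeta_exp %||% def$zeta_exp,
    Gamma_agg = cfg$Gamma_agg,
    eta_eff_factor = cfg$eta_eff_factor %||% def$eta_eff_factor,
    grid_h = cfg$grid_h,
    tol_ss = cfg$tol_ss %||% def$tol_ss,
    tol_div = cfg$tol_div %||% def$tol_div,
    zeta_floor = cfg$zeta_floor
  )
  geom <- NULL
  if (!is.null(cfg$R)) {
    a_frac <- cfg$a_frac %||% 0.2
    geom <- droplet_geometry(R = cfg$R, a = a_frac * cfg$R, d = cfg$d %||% 0)
  }
  list(params = p, geom = geom)
}

#' Write a model parameter file
#'
#' @param params A [hydro_params] object.
#' @param geom Optionally a [droplet_geometry]; written as `R`, `a_frac`, `d`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_hydro_config <- function(params, path, geom = NULL) {
  cfg <- unclass(params)
  if (!is.null(geom)) {
    cfg$R <- geom$R
    cfg$a_frac <- geom$a / geom$R
    cfg$d <- geom$d
  }
  write_json_out(cfg[!vapply(cfg, is.null, logical(1))], path)
}
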