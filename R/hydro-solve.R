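# Steady-state and pseudo-time solvers for the two-phase Darcy model.
#
# Governing equations (axisymmetric, units um / min / pN):
#   network mass balance   d rho/dt + div(rho V) = k_a - k_d rho
#   Darcy closure          zeta(rho) (U - V) = -grad P,  div U = 0
#   friction law           zeta(rho) = zeta0 * eta * rho (floored)
# with no-inflow of network at the droplet shell (exterior density zero) and
# no-penetration of the cytosol at both the shell and the aggregate surface.
# Advective fluxes across masked faces are zero: the network velocity points
# toward the aggregate everywhere and vanishes on its surface, so this is the
# consistent discrete counterpart and conserves network mass exactly.

# one conservative upwind/MUSCL flux evaluation; returns d(rho)/dt
density_rhs <- function(grid, vel, rho, k_a, k_d, muscl = TRUE) {
  r_up <- rho[vel$up]
  if (muscl) {
    slope <- minmod(ifelse(vel$uu_ok, r_up - rho[vel$uu], 0),
                    rho[vel$dn] - r_up)
    r_face <- r_up + 0.5 * slope
  } else {
    r_face <- r_up
  }
  flux <- grid$area * vel$vn * r_face
  drho <- as.numeric(grid$S %*% flux) / grid$vol
  drho[grid$cyto] <- drho[grid$cyto] + k_a - k_d * rho[grid$cyto]
  drho[!grid$cyto] <- 0
  drho
}

# one Heun (RK2) step; forward Euler is unstable with the second-order
# reconstruction, Heun damps the limiter limit-cycle
density_step <- function(grid, vel, rho, k_a, k_d, dt, muscl = TRUE) {
  k1 <- density_rhs(grid, vel, rho, k_a, k_d, muscl = muscl)
  r1 <- pmax(rho + dt * k1, 0)
  k2 <- density_rhs(grid, vel, r1, k_a, k_d, muscl = muscl)
  pmax(rho + dt * (k1 + k2) / 2, 0)
}

# advance rho by `tspan` of (pseudo-)time with CFL-limited explicit steps
advance_density <- function(grid, vel, rho, k_a, k_d, tspan,
                            cfl = 0.5, muscl = TRUE) {
  dt_max <- min(cfl * grid$h / max(abs(vel$vn), 1e-12), 0.5 / k_d)
  nstep <- max(1L, as.integer(ceiling(tspan / dt_max)))
  dt <- tspan / nstep
  for (k in seq_len(nstep)) {
    rho <- density_step(grid, vel, rho, k_a, k_d, dt, muscl = muscl)
  }
  rho
}

#' Steady-state network density
#'
#' Relaxes the network mass balance
#' `d rho/dt + div(rho V) = k_a - k_d * rho` to its dynamic steady state by
#' explicit pseudo-time stepping (CFL 0.5) with a conservative finite-volume
#' advection scheme (second-order MUSCL/minmod reconstruction by default,
#' first-order upwind available). Convergence is declared when
#' `max |d rho/dt| < tol_ss * k_a`.
#'
#' @param grid An [build_geometry()] grid.
#' @param vel A [network_velocity_field()] object on the same grid.
#' @param k_a,k_d Assembly (density-units/min) and disassembly (1/min) rates.
#' @param tol_ss Relative steady-state tolerance (default `1e-6`).
#' @param max_iter Maximum pseudo-time iterations before a diagnostic failure.
#' @param muscl Use the second-order reconstruction (default `TRUE`).
#' @param rho0 Optional initial density (full-grid vector); defaults to the
#'   uniform turnover balance `k_a / k_d` on cytoplasm cells.
#' @return An object of class `network_state`: fields `rho` (full-grid
#'   vector, zero outside the cytoplasm), `vel`, convergence diagnostics
#'   `iterations`, `residual`, `res_history`.
#' @export
steady_state_density <- function(grid, vel, k_a, k_d, tol_ss = 1e-6,
                                 max_iter = 20000L, muscl = TRUE,
                                 rho0 = NULL) {
  assert_scalar_num(k_a, "k_a", positive = TRUE)
  assert_scalar_num(k_d, "k_d", positive = TRUE)
  rho <- rho0 %||% ifelse(grid$cyto, k_a / k_d, 0)
  dt <- min(0.5 * grid$h / max(abs(vel$vn), 1e-12), 0.5 / k_d)
  res_history <- numeric(0)
  res <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    rho_new <- density_step(grid, vel, rho, k_a, k_d, dt, muscl = muscl)
    res <- max(abs(rho_new - rho)[grid$cyto]) / dt
    rho <- rho_new
    if (iter %% 25L == 0L || res < tol_ss * k_a) {
      res_history <- c(res_history, res)
    }
    if (res < tol_ss * k_a) break
  }
  if (res >= tol_ss * k_a) {
    stop(sprintf(paste0("steady_state_density did not converge in %d iterations ",
                        "(residual %.3g, tolerance %.3g); residual history: %s"),
                 max_iter, res, tol_ss * k_a,
                 paste(signif(utils::tail(res_history, 8), 3), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(rho = rho, vel = vel, iterations = iter, residual = res,
                 res_history = res_history, tol_ss = tol_ss),
            class = "network_state")
}

#' Cytosol pressure and flow (Darcy problem)
#'
#' Solves `zeta(rho) (U - V) = -grad P` with `div U = 0` and no-penetration
#' on the droplet shell and the aggregate surface. Eliminating `U` yields a
#' variable-coefficient Poisson problem for the pressure,
#' `div( grad P / zeta ) = div V`, a pure-Neumann system solved sparsely with
#' the gauge fixed to volume-weighted zero mean. The friction coefficient is
#' `zeta = zeta0 * eta * rho^zeta_exp`, floored at `zeta_floor` to keep the system
#' non-singular where the network is absent.
#'
#' @param grid An `axi_grid`.
#' @param rho Network density (full-grid vector), e.g. from
#'   [steady_state_density()].
#' @param vel The [network_velocity_field()] used for `rho`.
#' @param eta Cytosol viscosity (pN min / um^2).
#' @param zeta0 Friction coefficient scale.
#' @param zeta_exp Exponent of the density dependence (see [hydro_params()]).
#' @param zeta_floor Strictly positive friction floor.
#' @param tol_div Acceptable maximum cell divergence of `U` (1/min).
#' @return An object of class `fluid_state`: gauge-fixed pressure `P`,
#'   cell-centred velocity components `Us`, `Uz`, face-normal velocities
#'   `u_face`, cell-centred pressure gradients `gradPs`, `gradPz`, and the
#'   divergence diagnostic `max_div`.
#' @export
solve_cytosol_flow <- function(grid, rho, vel, eta, zeta0, zeta_exp = 1,
                               zeta_floor = NULL, tol_div = 1e-8) {
  if (inherits(rho, "network_state")) rho <- rho$rho
  assert_scalar_num(eta, "eta", positive = TRUE)
  assert_scalar_num(zeta0, "zeta0", positive = TRUE)
  zeta_floor <- zeta_floor %||% (1e-6 * zeta0 * eta * max(rho))
  if (zeta_floor <= 0) {
    if (all(rho[grid$cyto] <= 0)) {
      stop("all-zero network density with zeta_floor = 0: Darcy system is singular",
           call. = FALSE)
    }
    stop("zeta_floor must be strictly positive", call. = FALSE)
  }

  zeta <- pmax(zeta0 * eta * rho^zeta_exp, zeta_floor)
  zeta[!grid$cyto] <- zeta_floor
  zf <- 2 / (1 / zeta[grid$fp] + 1 / zeta[grid$fq])  # harmonic face friction
  cf <- grid$area / (zf * grid$h)                    # face conductance

  cyto_id <- which(grid$cyto)
  m <- length(cyto_id)
  comp <- integer(length(grid$cyto))
  comp[cyto_id] <- seq_len(m)
  p_c <- comp[grid$fp]; q_c <- comp[grid$fq]

  ti <- c(p_c, q_c, p_c, q_c)
  tj <- c(p_c, q_c, q_c, p_c)
  tx <- c(cf, cf, -cf, -cf)
  b <- as.numeric(grid$S %*% (grid$area * vel$vn))[cyto_id]

  pin <- 1L
  keep <- ti != pin
  L <- Matrix::sparseMatrix(i = c(ti[keep], pin), j = c(tj[keep], pin),
                            x = c(tx[keep], 1), dims = c(m, m))
  b[pin] <- 0
  P_c <- as.numeric(Matrix::solve(L, b))
  P_c <- P_c - wmean(P_c, grid$vol[cyto_id])

  P <- numeric(length(grid$cyto))
  P[cyto_id] <- P_c

  gP_face <- (P[grid$fq] - P[grid$fp]) / grid$h
  u_face <- vel$vn - gP_face / zf
  div <- as.numeric(grid$S %*% (grid$area * u_face)) / grid$vol
  max_div <- max(abs(div[grid$cyto]))
  # tolerance is relative to the advective velocity scale max|V| / h
  div_scale <- max(abs(vel$vn), 1e-300) / grid$h
  if (max_div > tol_div * div_scale) {
    stop(sprintf("cytosol flow solve failed: max |div U| = %.3g exceeds tol_div * max|V|/h = %.3g",
                 max_div, tol_div * div_scale), call. = FALSE)
  }

  is_s <- grid$fdir == 1L
  gradPs <- as.numeric(grid$Ws %*% gP_face[is_s])
  gradPz <- as.numeric(grid$Wz %*% gP_face[!is_s])
  Us <- ifelse(grid$cyto, vel$Vs - gradPs / zeta, 0)
  Uz <- ifelse(grid$cyto, vel$Vz - gradPz / zeta, 0)

  structure(list(P = P, Us = Us, Uz = Uz, u_face = u_face,
                 gradPs = gradPs, gradPz = gradPz, zeta = zeta,
                 div = div, max_div = max_div, tol_div = tol_div),
            class = "fluid_state")
}

#' Net hydrodynamic force on the aggregate
#'
#' Integrates the Darcy friction force density over the cytoplasm:
#' `F = -Int zeta(rho) (V - U) dOmega`. The friction the contracting network
#' exerts on the cytosol is transmitted, by reaction, through the network to
#' the aggregate it is anchored to; by axisymmetry only the axial component
#' is non-zero (the transverse component vanishes identically in the
#' axisymmetric representation). A discrete Newton's-third-law check compares
#' the friction integral with the volume integral of the pressure gradient,
#' which is the force on the fluid with opposite sign.
#'
#' @param grid An `axi_grid`.
#' @param rho Network density (vector or `network_state`).
#' @param fluid A [solve_cytosol_flow()] result.
#' @param vel The matching [network_velocity_field()].
#' @return An object of class `force_result`: `F` (length-2: transverse,
#'   axial; pN), `integrand_z` (axial Darcy force density per cell, pN/um^3),
#'   and `newton_rel`, the relative third-law mismatch.
#' @export
net_centering_force <- function(grid, rho, fluid, vel) {
  if (inherits(rho, "network_state")) rho <- rho$rho
  w <- grid$vol
  cy <- grid$cyto
  # friction route: -sum zeta (V - U) vol
  fric_z <- fluid$zeta * (vel$Vz - fluid$Uz)
  F_fric <- -sum(fric_z[cy] * w[cy])
  # pressure-gradient route: fluid force balance gives zeta (V - U) = grad P
  F_press <- -sum(fluid$gradPz[cy] * w[cy])
  scale <- max(abs(F_fric), abs(F_press), 1e-300)
  newton_rel <- abs(F_fric - F_press) / scale
  structure(list(F = c(0, F_fric), integrand_z = -fric_z,
                 F_pressure_route = F_press, newton_rel = newton_rel),
            class = "force_result")
}

#' One-call steady-state solve
#'
#' Convenience wrapper: builds the grid, the prescribed network velocity,
#' relaxes the density to steady state, solves the cytosol flow and computes
#' the net force on the aggregate.
#'
#' @param params A [hydro_params].
#' @param geom A [droplet_geometry].
#' @param h Grid spacing; default `params$grid_h`, falling back to `a / 5`.
#' @return List with `grid`, `vel`, `network` (class `network_state`),
#'   `fluid` (class `fluid_state`) and `force` (class `force_result`).
#' @export
hydro_steady_state <- function(params, geom, h = NULL) {
  stopifnot(inherits(params, "hydro_params"))
  h <- h %||% params$grid_h %||% (geom$a / 5)
  grid <- build_geometry(geom, h)
  vel <- network_velocity_field(grid, geom, params$gamma)
  network <- steady_state_density(grid, vel, params$k_a, params$k_d,
                                  tol_ss = params$tol_ss)
  fluid <- solve_cytosol_flow(grid, network, vel, params$eta, params$zeta0,
                              zeta_exp = params$zeta_exp,
                              zeta_floor = params$zeta_floor,
                              tol_div = params$tol_div)
  force <- net_centering_force(grid, network, fluid, vel)
  list(grid = grid, vel = vel, network = network, fluid = fluid, force = force)
}

#' Force-displacement curve
#'
#' Holds the aggregate fixed at each requested displacement, lets the network
#' reach its dynamic steady state, and records the net axial force. Per-point
#' solver failures are reported as `NA` rows with a warning, so partial
#' curves remain usable.
#'
#' @param params A [hydro_params].
#' @param geom_base A [droplet_geometry]; its `d` is ignored.
#' @param displacements Numeric vector of displacements (um) in `[0, R - a)`.
#' @param h Grid spacing (default as in [hydro_steady_state()]).
#' @return A data.frame with columns `R_um`, `d_um`, `F_pN` of class
#'   `force_displacement_curve`.
#' @export
force_displacement_curve <- function(params, geom_base, displacements,
                                     h = NULL) {
  if (any(displacements < 0 | displacements >= geom_base$R - geom_base$a)) {
    stop("all displacements must lie in [0, R - a)", call. = FALSE)
  }
  F_pN <- vapply(displacements, function(d) {
    geom <- droplet_geometry(geom_base$R, geom_base$a, d)
    tryCatch(hydro_steady_state(params, geom, h = h)$force$F[2],
             error = function(e) {
               warning(sprintf("solver failed at d = %g um: %s", d,
                               conditionMessage(e)), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  out <- data.frame(R_um = geom_base$R, d_um = displacements, F_pN = F_pN)
  class(out) <- c("force_displacement_curve", "data.frame")
  out
}

#' Fit the effective spring constant
#'
#' Linear fit of the restoring force through the origin, `F = -k * d`. The
#' goodness of fit is the uncentred R-squared of the constrained fit.
#'
#' @param curve A [force_displacement_curve()] result (or any data.frame with
#'   `d_um` and `F_pN`).
#' @return An object of class `spring_fit` with fields `k` (pN/um), `r2`,
#'   and the points used.
#' @export
fit_spring_constant <- function(curve) {
  ok <- is.finite(curve$F_pN)
  d <- curve$d_um[ok]; F <- curve$F_pN[ok]
  if (sum(d > 0) < 1L) {
    stop("fit_spring_constant needs at least one non-zero displacement",
         call. = FALSE)
  }
  k <- -sum(F * d) / sum(d^2)
  ss_res <- sum((F + k * d)^2)
  ss_tot <- sum(F^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(k = k, r2 = r2, d_um = d, F_pN = F), class = "spring_fit")
}

#' @export
print.spring_fit <- function(x, ...) {
  cat(sprintf("<spring_fit> k = %.4g pN/um (r2 = %.4f, %d points)\n",
              x$k, x$r2, length(x$d_um)))
  invisible(x)
}

#' Scaling exponent of the spring constant with droplet radius
#'
#' Repeats the fixed-displacement steady-state solve across droplet radii
#' with proportional geometry (`a = c_a * R`, probe displacement
#' `d = d_frac * R`, grid spacing `a / 5`) and fits the log-log slope of the
#' effective spring constant versus radius.
#'
#' @param params A [hydro_params].
#' @param radii Numeric vector of droplet radii (um); at least 3 values
#'   spanning a factor of 2 or more.
#' @param c_a Aggregate-to-droplet radius ratio (default 0.2).
#' @param d_frac Probe displacement as a fraction of `R` (default 0.2).
#' @return List with `exponent`, the per-radius table `k_table`
#'   (columns `R_um`, `k_pN_per_um`) and the underlying `lm` fit.
#' @export
spring_scaling_exponent <- function(params, radii, c_a = 0.2, d_frac = 0.2) {
  if (length(radii) < 3L) stop("need at least 3 radii", call. = FALSE)
  if (max(radii) / min(radii) < 2) {
    stop("radii must span at least a factor of 2", call. = FALSE)
  }
  k <- vapply(radii, function(R) {
    geom <- droplet_geometry(R, c_a * R, 0)
    curve <- force_displacement_curve(params, geom, d_frac * R, h = c_a * R / 5)
    fit_spring_constant(curve)$k
  }, numeric(1))
  if (any(!is.finite(k) | k <= 0)) {
    stop("non-positive or failed spring constant in scaling scan", call. = FALSE)
  }
  fit <- stats::lm(log(k) ~ log(radii))
  list(exponent = unname(stats::coef(fit)[2]),
       k_table = data.frame(R_um = radii, k_pN_per_um = k),
       fit = fit)
}
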