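# Dynamic recentering of a displaced aggregate under the hydrodynamic force.

#' Simulate aggregate recentering after a large displacement
#'
#' In-silico twin of the magnetic-perturbation experiment: the initial network
#' density is the centred steady-state distribution displaced sideways
#' together with the aggregate, and the system then evolves freely. At each
#' time step the network density is advanced in real time (one relaxation
#' sweep of pseudo-time `dt` per step; or fully re-equilibrated in
#' quasi-static mode), the cytosol flow is re-solved, and the aggregate moves
#' overdamped, `delta d = (F / Gamma_agg) * dt`, with the Stokes-like drag
#' from [hydro_params()].
#'
#' The aggregate position is kept on the lab grid; the mask and operators are
#' rebuilt each step, carrying the density field over (cells vacated by the
#' aggregate start network-free). If the aggregate reaches the droplet
#' boundary the run terminates with status `"escaped"`.
#'
#' @param params A [hydro_params].
#' @param geom A [droplet_geometry]; `geom$d` is ignored, use `d0`.
#' @param d0 Initial displacement (um), `0 <= d0 < R - a`. Snapped to the
#'   nearest grid multiple so the displaced density field is a pure shift.
#' @param T Duration (min).
#' @param dt Time step (min); must keep the per-step motion below one cell.
#' @param mode `"coevolve"` (default): density is time-stepped in real time,
#'   reproducing the reorganisation lag; `"quasistatic"`: density fully
#'   re-equilibrated each step.
#' @param h Grid spacing (default `params$grid_h`, else `a / 5`).
#' @param stop_d Optional early-stop threshold: terminate once `d < stop_d`.
#' @return An object of class `recenter_trajectory`: data.frame-like list
#'   with `times`, `d` (um), `v` (um/min, signed, positive = outward),
#'   `asym` (normalised far-minus-near network mass), `status`
#'   (`"ok"`, `"escaped"` or `"stopped"`), `d0` (the snapped initial
#'   displacement) and the parameters used.
#' @export
simulate_recentering <- function(params, geom, d0, T, dt = 0.1,
                                 mode = c("coevolve", "quasistatic"),
                                 h = NULL, stop_d = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "hydro_params"), inherits(geom, "droplet_geometry"))
  h <- h %||% params$grid_h %||% (geom$a / 5)
  if (d0 < 0 || d0 >= geom$R - geom$a) {
    stop("d0 must lie in [0, R - a)", call. = FALSE)
  }
  Gamma <- aggregate_drag(params, geom)

  # centred steady state, then displace network + aggregate together
  geom0 <- droplet_geometry(geom$R, geom$a, 0)
  grid0 <- build_geometry(geom0, h)
  vel0 <- network_velocity_field(grid0, geom0, params$gamma)
  ns0 <- steady_state_density(grid0, vel0, params$k_a, params$k_d,
                              tol_ss = params$tol_ss)
  shift <- round(d0 / h)
  d <- shift * h
  rho <- matrix(ns0$rho, grid0$Ns, grid0$Nz)
  if (shift > 0) {
    rho <- cbind(matrix(0, grid0$Ns, shift), rho[, seq_len(grid0$Nz - shift)])
  }
  rho <- as.numeric(rho)

  nstep <- as.integer(ceiling(T / dt))
  times <- numeric(nstep + 1L)
  ds <- numeric(nstep + 1L)
  vs <- numeric(nstep + 1L)
  asym <- numeric(nstep + 1L)
  status <- "ok"
  dmax <- geom$R - geom$a

  t <- 0
  for (k in seq_len(nstep + 1L)) {
    geom_t <- droplet_geometry(geom$R, geom$a, d)
    grid <- build_geometry(geom_t, h)
    rho[!grid$cyto] <- 0
    vel <- network_velocity_field(grid, geom_t, params$gamma)
    if (mode == "quasistatic") {
      ns <- steady_state_density(grid, vel, params$k_a, params$k_d,
                                 tol_ss = params$tol_ss, rho0 = rho)
      rho <- ns$rho
    } else if (k > 1L) {
      rho <- advance_density(grid, vel, rho, params$k_a, params$k_d, dt)
    }
    fluid <- solve_cytosol_flow(grid, rho, vel, params$eta, params$zeta0,
                                zeta_exp = params$zeta_exp,
                                zeta_floor = params$zeta_floor,
                                tol_div = params$tol_div)
    force <- net_centering_force(grid, rho, fluid, vel)
    v <- force$F[2] / Gamma

    cy <- grid$cyto
    m_far <- sum((rho * grid$vol)[cy & grid$zc < d])
    m_near <- sum((rho * grid$vol)[cy & grid$zc > d])
    times[k] <- t; ds[k] <- d; vs[k] <- v
    asym[k] <- (m_far - m_near) / max(m_far + m_near, 1e-300)

    if (k == nstep + 1L) break
    step <- v * dt
    if (abs(step) > h) {
      stop(sprintf("time step too large: |delta d| = %.3g um exceeds grid h = %.3g um",
                   abs(step), h), call. = FALSE)
    }
    d <- abs(d + step)            # reflective at the centre (axisymmetry)
    t <- t + dt
    if (d >= dmax - h) {
      status <- "escaped"
      times <- times[seq_len(k)]; ds <- ds[seq_len(k)]
      vs <- vs[seq_len(k)]; asym <- asym[seq_len(k)]
      break
    }
    if (d < stop_d) {
      status <- "stopped"
      times <- times[seq_len(k)]; ds <- ds[seq_len(k)]
      vs <- vs[seq_len(k)]; asym <- asym[seq_len(k)]
      break
    }
  }

  structure(list(times = times, d = ds, v = vs, asym = asym,
                 status = status, d0 = shift * h, dt = dt, mode = mode,
                 params = params, geom = geom, Gamma_agg = Gamma),
            class = "recenter_trajectory")
}

#' @export
print.recenter_trajectory <- function(x, ...) {
  cat(sprintf("<recenter_trajectory> d0 = %g um, %d samples over %g min, status '%s'\n",
              x$d0, length(x$times), max(x$times), x$status))
  invisible(x)
}

#' Half-recentering time
#'
#' First time at which the displacement falls below half its initial value
#' (linear interpolation between samples).
#'
#' @param traj A [simulate_recentering()] trajectory.
#' @return Time in minutes, or `NA` if the trajectory never halves.
#' @export
recentering_half_time <- function(traj) {
  first_crossing_time(traj$times, traj$d, traj$d0 / 2)
}

#' Convert a recentering trajectory to a data.frame
#'
#' Columns follow the trajectory CSV schema
#' `{t_min, d_um, v_um_per_min, asym_index}`.
#' @param x A `recenter_trajectory`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.recenter_trajectory <- function(x, ...) {
  data.frame(t_min = x$times, d_um = x$d, v_um_per_min = x$v,
             asym_index = x$asym)
}

#' Compare recentering between cell-cycle phases
#'
#' Runs a pair of recentering simulations differing only in the network
#' contraction rate: the second ("interphase-like") uses
#' `gamma / contraction_ratio`. With `contraction_ratio = 3` this mirrors the
#' roughly three-fold slower contraction of interphase extract.
#'
#' @param params_M [hydro_params] for the reference (M-phase-like) condition.
#' @param geom A [droplet_geometry].
#' @param contraction_ratio Positive factor by which contraction is slowed.
#' @param d0,T,dt,h Passed to [simulate_recentering()]; `T` defaults to a
#'   duration long enough to capture both half-times.
#' @return List with `M`, `I` (trajectories) and `t_half` (named numeric,
#'   first times below `d0 / 2`).
#' @export
phase_comparison <- function(params_M, geom, contraction_ratio, d0, T = 30,
                             dt = 0.1, h = NULL) {
  assert_scalar_num(contraction_ratio, "contraction_ratio", positive = TRUE)
  params_I <- params_M
  params_I$gamma <- params_M$gamma / contraction_ratio
  trj_M <- simulate_recentering(params_M, geom, d0, T, dt, h = h)
  trj_I <- simulate_recentering(params_I, geom, d0, T, dt, h = h)
  list(M = trj_M, I = trj_I,
       t_half = c(M = recentering_half_time(trj_M),
                  I = recentering_half_time(trj_I)))
}
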