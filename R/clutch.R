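# Effective stochastic clutch model of aggregate positioning.
#
# The aggregate position obeys a competition between the deterministic
# hydrodynamic centering (relaxation rate lambda = k / Gamma_agg, with the
# spring law k ~ R^3 and Stokes-like drag Gamma ~ a ~ R, hence lambda ~ R^2)
# and a transient "clutch" engagement with the droplet boundary: engagement
# switches on with rate k_on = kon0 / b and off with rate k_off = koff0 * b,
# where b is the distance between the aggregate surface and the closest
# boundary. While engaged the aggregate moves at constant speed v_clutch
# toward the closest boundary point; while disengaged it relaxes toward the
# centre with positional noise D_eff. Reaching the boundary is absorbing
# (stable polar state).
#
# The disengaged dynamics are simulated as a full 3D Ornstein-Uhlenbeck
# process (exact per-axis discretisation), so the centred-state statistics
# are exactly 3D-consistent: stationary RMS distance sqrt(3 D_eff / lambda).

#' Parameters of the stochastic clutch positioning model
#'
#' @param kon0 On-rate scale (um/min); engagement rate is `kon0 / b` with `b`
#'   the aggregate-boundary clearance.
#' @param koff0 Off-rate scale (1/(um min)); disengagement rate is
#'   `koff0 * b`.
#' @param v_clutch Speed toward the closest boundary while engaged (um/min).
#' @param D_eff Effective positional diffusion of the disengaged aggregate
#'   (um^2/min); default the measured centred-state value 0.32.
#' @param lam_ref Centering relaxation rate `k / Gamma_agg` (1/min) at the
#'   reference radius `R_ref`. The default 0.083/min makes the disengaged
#'   stationary state match the observed confined fluctuations
#'   (`lambda = 3 D_eff / Rc^2` with `Rc = 3.4` um); use
#'   [clutch_lambda_from_spring()] to derive it from the hydrodynamic model
#'   instead.
#' @param R_ref Reference radius (um) for `lam_ref`.
#' @param lam_power Exponent of the radius dependence of lambda; default 2
#'   (spring constant ~ R^3, drag ~ a ~ R).
#' @param b_min Clearance floor (um) preventing rate divergence at contact.
#' @param c_a Aggregate-to-droplet radius ratio (default 0.2).
#' @param geometry `"sphere"` or `"pancake"` (squished droplet).
#' @param height Pancake height `h_p` (um, total); required and `< 2 R` when
#'   `geometry = "pancake"`.
#' @return An object of class `clutch_params`.
#' @export
clutch_params <- function(kon0 = 2, koff0 = 0.003, v_clutch = 1,
                          D_eff = 0.32, lam_ref = 0.083, R_ref = 50,
                          lam_power = 2, b_min = 0.5, c_a = 0.2,
                          geometry = c("sphere", "pancake"), height = NULL) {
  geometry <- match.arg(geometry)
  assert_scalar_num(kon0, "kon0", nonneg = TRUE)
  assert_scalar_num(koff0, "koff0", nonneg = TRUE)
  assert_scalar_num(v_clutch, "v_clutch", nonneg = TRUE)
  if (kon0 > 0 && v_clutch <= 0) {
    stop("v_clutch must be positive when kon0 > 0", call. = FALSE)
  }
  assert_scalar_num(D_eff, "D_eff", nonneg = TRUE)
  assert_scalar_num(lam_ref, "lam_ref", nonneg = TRUE)
  assert_scalar_num(R_ref, "R_ref", positive = TRUE)
  assert_scalar_num(b_min, "b_min", positive = TRUE)
  assert_scalar_num(c_a, "c_a", positive = TRUE)
  if (geometry == "pancake") {
    if (is.null(height)) stop("pancake geometry requires `height`", call. = FALSE)
    assert_scalar_num(height, "height", positive = TRUE)
  }
  structure(list(kon0 = kon0, koff0 = koff0, v_clutch = v_clutch,
                 D_eff = D_eff, lam_ref = lam_ref, R_ref = R_ref,
                 lam_power = lam_power, b_min = b_min, c_a = c_a,
                 geometry = geometry, height = height),
            class = "clutch_params")
}

#' Centering relaxation rate for a droplet radius
#' @param cp A [clutch_params].
#' @param R Droplet radius (um).
#' @return `lam_ref * (R / R_ref)^lam_power` (1/min).
#' @export
clutch_lambda <- function(cp, R) cp$lam_ref * (R / cp$R_ref)^cp$lam_power

#' Derive the clutch relaxation rate from the hydrodynamic spring fit
#'
#' Runs the two-phase model at a small probe displacement, fits the spring
#' constant, and divides by the Stokes-like aggregate drag.
#'
#' @param params A [hydro_params].
#' @param R Droplet radius (um).
#' @param c_a Aggregate-to-droplet radius ratio.
#' @param d_frac Probe displacement as a fraction of `R`.
#' @return Relaxation rate lambda (1/min).
#' @export
clutch_lambda_from_spring <- function(params, R, c_a = 0.2, d_frac = 0.2) {
  geom <- droplet_geometry(R, c_a * R, 0)
  curve <- force_displacement_curve(params, geom, d_frac * R, h = c_a * R / 5)
  fit_spring_constant(curve)$k / aggregate_drag(params, geom)
}

# validity bound for the per-step exponential-clock switching probabilities
clutch_dt_max <- function(cp, R) {
  a <- cp$c_a * R
  kmax <- max(cp$kon0 / cp$b_min, cp$koff0 * (R - a), 1e-12)
  0.1 / kmax
}

# vectorised lockstep simulation of n independent droplets; the work-horse
# behind both the single-trajectory and the population interfaces.
# Returns final state plus (optionally) per-step recordings for droplet 1
# and polar status snapshots at `record_times`.
clutch_engine <- function(cp, R, d0, T, dt, record_first = FALSE,
                          record_times = NULL, engaged0 = FALSE) {
  n <- length(R)
  a <- cp$c_a * R
  lam <- clutch_lambda(cp, R)
  if (cp$geometry == "pancake") {
    hp <- cp$height
    if (any(hp >= 2 * R)) stop("pancake height must be < 2 R (actually squished)",
                               call. = FALSE)
    if (any(hp / 2 <= a)) stop("pancake height too small: aggregate does not fit",
                               call. = FALSE)
  }
  if (dt > min(vapply(R, function(r) clutch_dt_max(cp, r), numeric(1)))) {
    stop(sprintf("dt = %g too large for switching-probability validity (need <= %g)",
                 dt, min(vapply(R, function(r) clutch_dt_max(cp, r), numeric(1)))),
         call. = FALSE)
  }

  # state
  X <- cbind(numeric(n), numeric(n), d0)   # displacement along z initially
  engaged <- rep(engaged0, length.out = n)
  frozen <- logical(n)
  t_polar <- rep(NA_real_, n)
  break_axial <- rep(NA, n)                # pancake: axial vs lateral arrival
  nstep <- as.integer(ceiling(T / dt))

  rec_d <- if (record_first) numeric(nstep + 1L) else NULL
  rec_eng <- if (record_first) logical(nstep + 1L) else NULL
  n_onsets <- integer(n)
  snap <- if (!is.null(record_times)) {
    matrix(NA, length(record_times), n,
           dimnames = list(paste0("t", record_times), NULL))
  } else NULL

  # pre-draw nothing: draws depend on active set sizes; rely on R's RNG stream
  decay <- exp(-lam * dt)
  sig <- sqrt((cp$D_eff / pmax(lam, 1e-12)) * (1 - decay^2))
  sig[lam <= 1e-12] <- sqrt(2 * cp$D_eff * dt)   # free-diffusion limit

  clearance <- function(X, idx) {
    Ri <- R[idx]; ai <- a[idx]
    if (cp$geometry == "sphere") {
      dvec <- sqrt(rowSums(X^2))
      list(b = pmax(Ri - ai - dvec, cp$b_min), ax = NULL,
           lat = NULL, dvec = dvec, hit = dvec >= Ri - ai - 1e-9)
    } else {
      rxy <- sqrt(X[, 1]^2 + X[, 2]^2)
      ax <- cp$height / 2 - abs(X[, 3]) - ai
      lat <- Ri - rxy - ai
      list(b = pmax(pmin(ax, lat), cp$b_min), ax = ax, lat = lat,
           dvec = sqrt(rowSums(X^2)), hit = pmin(ax, lat) <= 0)
    }
  }

  t <- 0
  if (record_first) rec_d[1] <- sqrt(sum(X[1, ]^2))
  snap_i <- 1L
  for (k in seq_len(nstep)) {
    act <- which(!frozen)
    if (length(act) > 0L) {
      cl <- clearance(X[act, , drop = FALSE], act)
      kon <- cp$kon0 / cl$b
      koff <- cp$koff0 * cl$b
      u <- stats::runif(length(act))
      prev <- engaged[act]
      p_switch <- ifelse(prev, 1 - exp(-koff * dt), 1 - exp(-kon * dt))
      eng <- xor(prev, u < p_switch)
      engaged[act] <- eng
      n_onsets[act] <- n_onsets[act] + as.integer(!prev & eng)

      Xa <- X[act, , drop = FALSE]
      # engaged: constant speed toward the closest boundary point
      ie <- which(eng)
      if (length(ie) > 0L) {
        Xe <- Xa[ie, , drop = FALSE]
        if (cp$geometry == "sphere") {
          nrm <- sqrt(rowSums(Xe^2))
          dir <- Xe / ifelse(nrm > 0, nrm, 1)
          zero <- nrm == 0
          if (any(zero)) {   # random direction from the exact centre
            nz <- sum(zero)
            g <- matrix(stats::rnorm(3 * nz), nz, 3)
            dir[zero, ] <- g / sqrt(rowSums(g^2))
          }
          Xe <- Xe + cp$v_clutch * dt * dir
        } else {
          ax <- cl$ax[ie]; lat <- cl$lat[ie]
          axial <- ax <= lat
          dz <- sign(Xe[, 3])
          dz[dz == 0] <- sample(c(-1, 1), sum(dz == 0), replace = TRUE)
          rxy <- sqrt(Xe[, 1]^2 + Xe[, 2]^2)
          dirx <- ifelse(rxy > 0, Xe[, 1] / rxy, 1)
          diry <- ifelse(rxy > 0, Xe[, 2] / rxy, 0)
          Xe[, 3] <- Xe[, 3] + ifelse(axial, cp$v_clutch * dt * dz, 0)
          Xe[, 1] <- Xe[, 1] + ifelse(axial, 0, cp$v_clutch * dt * dirx)
          Xe[, 2] <- Xe[, 2] + ifelse(axial, 0, cp$v_clutch * dt * diry)
        }
        Xa[ie, ] <- Xe
      }
      # disengaged: exact OU relaxation toward the centre
      id <- which(!eng)
      if (length(id) > 0L) {
        gi <- act[id]
        Xa[id, ] <- Xa[id, , drop = FALSE] * decay[gi] +
          sig[gi] * matrix(stats::rnorm(3 * length(id)), length(id), 3)
      }
      X[act, ] <- Xa

      # absorption at the boundary: stable polar state
      cl2 <- clearance(X[act, , drop = FALSE], act)
      hit <- cl2$hit
      if (any(hit)) {
        gh <- act[hit]
        frozen[gh] <- TRUE
        t_polar[gh] <- t + dt
        if (cp$geometry == "sphere") {
          nrm <- sqrt(rowSums(X[gh, , drop = FALSE]^2))
          X[gh, ] <- X[gh, , drop = FALSE] * ((R[gh] - a[gh]) / nrm)
        } else {
          break_axial[gh] <- cl2$ax[hit] <= cl2$lat[hit]
        }
      }
    }
    t <- t + dt
    if (record_first) {
      rec_d[k + 1L] <- sqrt(sum(X[1, ]^2))
      rec_eng[k + 1L] <- engaged[1]
    }
    if (!is.null(record_times) && snap_i <= length(record_times) &&
        t >= record_times[snap_i] - dt / 2) {
      snap[snap_i, ] <- frozen
      snap_i <- snap_i + 1L
    }
  }

  dvec <- if (cp$geometry == "sphere") {
    pmin(sqrt(rowSums(X^2)), R - a)
  } else sqrt(rowSums(X^2))
  list(d = dvec, frozen = frozen, t_polar = t_polar, engaged = engaged,
       break_axial = break_axial, rec_d = rec_d, rec_eng = rec_eng,
       n_onsets = n_onsets, snap = snap, nstep = nstep, dt = dt)
}

#' Simulate a single clutch trajectory
#'
#' Two-state Markov switching between a disengaged, centering state
#' (3D Ornstein-Uhlenbeck relaxation toward the droplet centre) and an
#' engaged state moving at constant speed toward the closest boundary;
#' reaching the boundary is absorbing.
#'
#' @param cp A [clutch_params].
#' @param R Droplet radius (um).
#' @param d0 Initial displacement (um).
#' @param T Duration (min).
#' @param dt Time step (min); must satisfy
#'   `dt <= 0.1 / max(k_on(b_min), k_off(R - a))`.
#' @param seed Integer seed (mandatory: no implicit randomness).
#' @param engaged0 Start in the engaged state (default `FALSE`).
#' @return An object of class `clutch_trajectory`: `times`, `d`, `engaged`,
#'   `status` (`"centered"` or `"polar"`), `t_polar`, `n_onsets` (number of
#'   engagement onsets) and the parameters.
#' @export
simulate_clutch_trajectory <- function(cp, R, d0 = 0, T = 60, dt = 0.01,
                                       seed, engaged0 = FALSE) {
  stopifnot(inherits(cp, "clutch_params"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  assert_scalar_num(R, "R", positive = TRUE)
  if (d0 < 0 || d0 > R - cp$c_a * R) stop("d0 outside [0, R - a]", call. = FALSE)
  set.seed(seed)
  out <- clutch_engine(cp, R, d0, T, dt, record_first = TRUE,
                       engaged0 = engaged0)
  structure(list(times = seq(0, by = dt, length.out = out$nstep + 1L),
                 d = out$rec_d, engaged = out$rec_eng,
                 status = if (out$frozen[1]) "polar" else "centered",
                 t_polar = out$t_polar[1], n_onsets = out$n_onsets[1],
                 R = R, params = cp, seed = seed),
            class = "clutch_trajectory")
}

#' @export
print.clutch_trajectory <- function(x, ...) {
  cat(sprintf("<clutch_trajectory> R = %g um, %d steps, status '%s'%s\n",
              x$R, length(x$times) - 1L, x$status,
              if (!is.na(x$t_polar)) sprintf(" (t_polar = %.2f min)", x$t_polar) else ""))
  invisible(x)
}

#' Simulate a droplet population
#'
#' Independent clutch trajectories across droplet radii (aggregate radius
#' `a = c_a * R`, centering rate `lambda ~ R^lam_power`), producing rows
#' suitable for [classify_symmetry()].
#'
#' @param cp A [clutch_params].
#' @param radii Numeric vector of droplet radii (um).
#' @param T Duration (min).
#' @param dt Time step (min).
#' @param seed Integer seed.
#' @param d0 Initial displacement (um, default 0: all start centred).
#' @param record_times Optional times (min) at which to snapshot the polar
#'   status of every droplet (for time-evolution statistics without
#'   re-simulating).
#' @return An object of class `population_result`: data.frame with columns
#'   `droplet_id, R_um, T_min, d_um, d_over_R, status, t_polar_min, seed`,
#'   with the snapshot matrix (if requested) in `attr(, "snapshots")`.
#' @export
simulate_population <- function(cp, radii, T = 40, dt = 0.01, seed,
                                d0 = 0, record_times = NULL) {
  stopifnot(inherits(cp, "clutch_params"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  out <- clutch_engine(cp, radii, d0, T, dt, record_times = record_times)
  res <- data.frame(droplet_id = seq_along(radii), R_um = radii, T_min = T,
                    d_um = out$d, d_over_R = out$d / radii,
                    status = ifelse(out$frozen, "polar", "centered"),
                    t_polar_min = out$t_polar, seed = seed)
  attr(res, "n_onsets") <- out$n_onsets
  attr(res, "snapshots") <- out$snap
  class(res) <- c("population_result", "data.frame")
  res
}

#' Polar fraction per size bin
#' @param pop A [simulate_population()] result.
#' @param breaks Radius bin edges (um).
#' @return data.frame with bin, n and polar fraction.
#' @export
polar_fraction_by_size <- function(pop, breaks) {
  bin <- cut(pop$R_um, breaks)
  agg <- tapply(pop$status == "polar", bin, mean)
  data.frame(bin = names(agg), n = as.integer(table(bin)),
             polar_fraction = as.numeric(agg))
}

#' Symmetric-to-polar transition radius of a population
#'
#' Logistic fit of polar status versus radius; the transition radius is the
#' radius of 50% polar probability.
#'
#' @param pop A [simulate_population()] result.
#' @return Radius (um); `NA` with a warning if the fit is degenerate.
#' @export
polar_transition_radius <- function(pop) {
  y <- as.integer(pop$status == "polar")
  if (all(y == 0L) || all(y == 1L)) {
    warning("population is all one class; transition radius undefined")
    return(NA_real_)
  }
  fit <- suppressWarnings(stats::glm(y ~ pop$R_um, family = stats::binomial()))
  co <- stats::coef(fit)
  unname(-co[1] / co[2])
}

#' Breaking directions in squished (pancake) droplets
#'
#' Simulates symmetry breaking in an oblate geometry (lateral radius `R`,
#' total height `height < 2 R`): the clearance entering the clutch rates and
#' the engaged motion use the closest of the top/bottom interfaces and the
#' lateral rim. Returns the distribution of breaking directions.
#'
#' @param cp A [clutch_params] with `geometry = "pancake"`.
#' @param R Lateral droplet radius (um).
#' @param n Number of independent droplets.
#' @param T Duration (min); droplets that have not broken by `T` are
#'   reported as `undecided`.
#' @param dt Time step (min).
#' @param seed Integer seed.
#' @return List with `counts` (named: axial, lateral, undecided) and the
#'   per-droplet data.frame `runs`.
#' @export
pancake_breaking_directions <- function(cp, R, n, T = 120, dt = 0.01, seed) {
  stopifnot(inherits(cp, "clutch_params"))
  if (cp$geometry != "pancake") {
    stop("pancake_breaking_directions requires clutch_params(geometry = 'pancake')",
         call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  out <- clutch_engine(cp, rep(R, n), 0, T, dt)
  dir <- ifelse(!out$frozen, "undecided",
                ifelse(out$break_axial, "axial", "lateral"))
  counts <- c(axial = sum(dir == "axial"), lateral = sum(dir == "lateral"),
              undecided = sum(dir == "undecided"))
  list(counts = counts,
       runs = data.frame(droplet_id = seq_len(n), direction = dir,
                         t_polar_min = out$t_polar))
}
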