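# Synthetic-data generators with ground-truth metadata. Everything is
# reproducible from (spec, seed): no implicit randomness, exact
# discretisation of the Ornstein-Uhlenbeck updates (no integrator bias).

# exact OU update for an n x 3 state: relaxation rate theta, stationary
# per-axis variance s2, time step dt
ou_step <- function(X, theta, s2, dt) {
  dec <- exp(-theta * dt)
  X * dec + sqrt(s2 * (1 - dec^2)) * matrix(stats::rnorm(length(X)), nrow(X))
}

#' Generate a confined (centred-state) track
#'
#' 3D Ornstein-Uhlenbeck process per axis with free diffusion coefficient
#' `D` and stationary RMS distance from the centre `Rc`: per-axis variance
#' `sigma^2 = Rc^2 / 3`, relaxation rate `D / sigma^2`, exact-discretisation
#' updates at `dt`, initial position drawn from the stationary distribution.
#'
#' @param D Free diffusion coefficient (um^2/min), `> 0`.
#' @param Rc Stationary RMS distance from the centre (um), `> 0`.
#' @param dt Sampling interval (min).
#' @param T Duration (min).
#' @param R Droplet radius (um).
#' @param a Aggregate radius (um); default `0.2 R`.
#' @param seed Integer seed (mandatory).
#' @param droplet_id Identifier.
#' @param noise_sd Optional localisation error: isotropic Gaussian of this
#'   standard deviation (um) added to each recorded position (default 0).
#' @return A [track] with truth metadata in `attr(, "truth")`
#'   (`kind`, `D`, `Rc`, `seed`).
#' @export
gen_confined_track <- function(D, Rc, dt = 0.5, T = 60, R = 35, a = 0.2 * R,
                               seed, droplet_id = "confined_1",
                               noise_sd = 0) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  assert_scalar_num(D, "D", nonneg = TRUE)
  assert_scalar_num(Rc, "Rc", positive = TRUE)
  assert_scalar_num(dt, "dt", positive = TRUE)
  if (T <= dt) stop("T must exceed dt", call. = FALSE)
  if (Rc > R - a) {
    stop(sprintf("confinement Rc = %.3g exceeds available space R - a = %.3g",
                 Rc, R - a), call. = FALSE)
  }
  set.seed(seed)
  s2 <- Rc^2 / 3
  theta <- D / s2
  times <- seq(0, T, by = dt)
  n <- length(times)
  X <- matrix(NA_real_, n, 3)
  X[1, ] <- stats::rnorm(3, sd = sqrt(s2))
  if (D == 0) {            # zero-noise limit: frozen at the initial point
    X <- matrix(X[1, ], n, 3, byrow = TRUE)
  } else {
    for (i in seq_len(n - 1L)) {
      X[i + 1L, ] <- ou_step(X[i, , drop = FALSE], theta, s2, dt)
    }
  }
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  # confinement is statistical; clip the (practically impossible) excursions
  r <- sqrt(rowSums(X^2))
  over <- r > R - a
  if (any(over)) X[over, ] <- X[over, , drop = FALSE] * ((R - a) / r[over])
  tr <- track(droplet_id, times, X, R, a)
  attr(tr, "truth") <- list(kind = "confined", D = D, Rc = Rc, dt = dt,
                            T = T, seed = seed)
  tr
}

#' Generate a symmetry-breaking track
#'
#' Confined phase (tight 3D Ornstein-Uhlenbeck fluctuations of RMS radius
#' `Rc_pre`) until `t_break`, then directed outward motion at constant speed
#' `v` along a fixed direction (radially outward from the position at the
#' onset; random from the exact centre) plus isotropic diffusion `D_break`,
#' until the aggregate reaches the boundary (`|x| = R - a`), where it stays
#' (stable polar state).
#'
#' @param v Outward speed during the break (um/min), `> 0`.
#' @param D Isotropic diffusion during the confined phase (um^2/min).
#' @param D_break Isotropic diffusion during the directed phase; defaults to
#'   `D`, set to 0 for a deterministic outward run.
#' @param t_break Onset time of the break (min), `< T`.
#' @param dt Sampling interval (min).
#' @param T Duration (min).
#' @param R Droplet radius (um).
#' @param a Aggregate radius (um); default `0.2 R`.
#' @param Rc_pre RMS confinement radius before the break (um, default 1).
#' @param seed Integer seed (mandatory).
#' @param droplet_id Identifier.
#' @return A [track] with truth metadata (`t_break`, `v`, `direction`,
#'   `t_reach` - the first boundary time or `NA`, `u_final`).
#' @export
gen_breaking_track <- function(v, D, t_break, dt = 0.5, T = 60, R = 40,
                               a = 0.2 * R, Rc_pre = 1, seed,
                               droplet_id = "breaking_1", D_break = D) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  assert_scalar_num(v, "v", positive = TRUE)
  assert_scalar_num(D, "D", nonneg = TRUE)
  if (t_break >= T) stop("t_break must be smaller than T", call. = FALSE)
  if (D_break == 0 && v * (T - t_break) < R - a) {
    warning("v * (T - t_break) < R - a with D = 0: the event will not complete")
  }
  set.seed(seed)
  s2 <- Rc_pre^2 / 3
  theta <- if (D > 0) D / s2 else 0
  times <- seq(0, T, by = dt)
  n <- length(times)
  X <- matrix(NA_real_, n, 3)
  X[1, ] <- if (D > 0) stats::rnorm(3, sd = sqrt(s2)) else c(0, 0, 0)
  dir <- NULL          # fixed at break onset: radially outward (random at 0)
  dmax <- R - a
  reached <- FALSE
  t_reach <- NA_real_
  for (i in seq_len(n - 1L)) {
    if (reached) { X[i + 1L, ] <- X[i, ]; next }
    if (times[i + 1L] <= t_break) {
      X[i + 1L, ] <- if (D > 0) ou_step(X[i, , drop = FALSE], theta, s2, dt) else X[i, ]
    } else {
      if (is.null(dir)) {
        r0 <- sqrt(sum(X[i, ]^2))
        dir <- if (r0 > 0) X[i, ] / r0 else {
          g <- stats::rnorm(3); g / sqrt(sum(g^2))
        }
      }
      X[i + 1L, ] <- X[i, ] + v * dt * dir +
        if (D_break > 0) stats::rnorm(3, sd = sqrt(2 * D_break * dt)) else 0
    }
    r <- sqrt(sum(X[i + 1L, ]^2))
    if (r >= dmax && times[i + 1L] > t_break) {
      X[i + 1L, ] <- X[i + 1L, ] * (dmax / r)
      reached <- TRUE
      t_reach <- times[i + 1L]
    } else if (r > dmax) {
      X[i + 1L, ] <- X[i + 1L, ] * (dmax / r)   # pre-break clip (rare)
    }
  }
  tr <- track(droplet_id, times, X, R, a)
  attr(tr, "truth") <- list(kind = "breaking", v = v, D = D,
                            D_break = D_break,
                            t_break = t_break, direction = dir,
                            t_reach = t_reach,
                            u_final = sqrt(sum(X[n, ]^2)) / R, seed = seed)
  tr
}

#' Generate a droplet population with a size-dependent symmetry transition
#'
#' Radii are drawn uniformly in `r_range` (or taken from `radii`); each
#' droplet is assigned polar or centred by a logistic rule in radius around
#' `transition_R` with steepness `sharpness` (1/um; `Inf` gives a perfect
#' step). Polar droplets get a normalised displacement `u` uniform in
#' `[0.8, 1 - c_a]`, centred droplets `u` uniform in `[0, 0.15]`: bimodal by
#' construction in the transition zone.
#'
#' @param n Number of droplets (at least 30).
#' @param transition_R Transition radius (um).
#' @param sharpness Logistic steepness (1/um); `Inf` for a step.
#' @param r_range Radius range (um) for uniform sampling.
#' @param radii Optional explicit radii (overrides `n` and `r_range`).
#' @param c_a Aggregate-to-droplet radius ratio.
#' @param seed Integer seed (mandatory).
#' @return A data.frame `{droplet_id, R, d, u}` of class `symmetry_table`
#'   with truth metadata (`transition_R`, `sharpness`, `polar` assignment)
#'   in `attr(, "truth")`.
#' @export
gen_population <- function(n = 200, transition_R = 35, sharpness = Inf,
                           r_range = c(15, 60), radii = NULL, c_a = 0.2,
                           seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  R <- radii %||% stats::runif(n, r_range[1], r_range[2])
  n <- length(R)
  if (n < 30L) stop("need at least 30 droplets", call. = FALSE)
  if (transition_R < min(R) || transition_R > max(R)) {
    warning("transition_R lies outside the sampled radius range")
  }
  p_polar <- if (is.infinite(sharpness)) {
    as.numeric(R < transition_R)
  } else {
    stats::plogis(-(R - transition_R) * sharpness)
  }
  polar <- stats::runif(n) < p_polar
  u <- ifelse(polar,
              stats::runif(n, 0.8, 1 - c_a),
              stats::runif(n, 0, 0.15))
  out <- data.frame(droplet_id = seq_len(n), R = R, d = u * R, u = u)
  attr(out, "truth") <- list(transition_R = transition_R,
                             sharpness = sharpness, polar = polar,
                             seed = seed)
  class(out) <- c("symmetry_table", "data.frame")
  out
}
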