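# Independent oracles and shared fixtures for the test suite.

# Closed-form centred-state density profile: the spherically symmetric
# steady state of d(r^2 rho v)/dr = r^2 (k_a - k_d rho) with
# v(r) = -gamma (r - a) and zero flux at r = R integrates (integrating
# factor (r-a)^(-beta), beta = k_d / gamma) to
#   rho(r) = k_a / (gamma r^2) * (r-a)^(beta-1) * Int_r^R s^2 (s-a)^-beta ds
# with the integral in closed form by expanding s^2 about a.
rho_oracle_1d <- function(r, R, a, gamma, k_a, k_d) {
  beta <- k_d / gamma
  stopifnot(!any(abs(beta - c(1, 2, 3)) < 1e-9))
  G <- function(s) {
    x <- s - a
    x^(3 - beta) / (3 - beta) + 2 * a * x^(2 - beta) / (2 - beta) +
      a^2 * x^(1 - beta) / (1 - beta)
  }
  k_a / (gamma * r^2) * (r - a)^(beta - 1) * (G(R) - G(r))
}

# Analytic MSD of a 3D OU process with per-axis variance s2 and relaxation
# rate theta: MSD(t) = 6 s2 (1 - exp(-theta t))
msd_ou <- function(t, D, Rc) {
  s2 <- Rc^2 / 3
  6 * s2 * (1 - exp(-t * D / s2))
}

# volume-weighted L2 relative error of the solved centred density against
# the 1D oracle, at grid spacing h
centered_density_l2 <- function(h, R = 50, a = 10, gamma = 0.2,
                                k_a = 1, k_d = 1) {
  geom <- droplet_geometry(R, a, 0)
  grid <- build_geometry(geom, h)
  vel <- network_velocity_field(grid, geom, gamma)
  ns <- steady_state_density(grid, vel, k_a, k_d)
  cy <- grid$cyto
  r <- sqrt(grid$sc^2 + grid$zc^2)[cy]
  ro <- rho_oracle_1d(pmin(pmax(r, a + 1e-9), R - 1e-9), R, a, gamma, k_a, k_d)
  sqrt(sum(grid$vol[cy] * (ns$rho[cy] - ro)^2) / sum(grid$vol[cy] * ro^2))
}

# ensemble MSD exponent of the directed segments of synthetic breaking
# tracks (the quantity behind the alpha = 1.5 comparison)
breaking_segment_alpha <- function(n_tracks, seed0, v = 1, D = 0.32,
                                   dt = 0.5, T = 60, t_break = 20, R = 40) {
  segs <- lapply(seq_len(n_tracks), function(i) {
    tr <- gen_breaking_track(v = v, D = D, t_break = t_break, dt = dt, T = T,
                             R = R, seed = seed0 + i, droplet_id = i)
    tru <- attr(tr, "truth")
    tend <- if (is.na(tru$t_reach)) max(tr$times) else tru$t_reach
    sel <- tr$times >= tru$t_break & tr$times <= tend
    track(i, tr$times[sel], tr$pos[sel, , drop = FALSE], tr$R, tr$a)
  })
  compute_msd(segs, fit_window = 10, max_lag = 10)$alpha
}

# small steady solve used by several force tests
solve_force <- function(params, R, a, d, h = a / 5) {
  hydro_steady_state(params, droplet_geometry(R, a, d), h = h)
}

# radial displacement of a track (public mirror of the internal helper)
track_displacement_pub <- function(tr) sqrt(rowSums(tr$pos^2))
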