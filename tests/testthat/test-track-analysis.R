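# MSD, VACF, symmetry-breaking detection, classification, curve alignment.

make_linear_track <- function(v = 1, dt = 0.5, T = 30, R = 100, a = 10,
                              id = "lin") {
  times <- seq(0, T, by = dt)
  track(id, times, cbind(v * times, 0, 0), R, a)
}

test_that("MSD: exact ballistic closed form and degenerate static input", {
  tr <- make_linear_track()
  m <- compute_msd(tr, fit_window = 10)
  expect_equal(m$alpha, 2, tolerance = 1e-10)
  expect_equal(m$msd, m$lags^2, tolerance = 1e-12)

  static <- track("s", seq(0, 10, 0.5), matrix(1, 21, 3), 50, 10)
  ms <- compute_msd(static)
  expect_true(ms$degenerate)
  expect_true(is.na(ms$alpha))

  expect_error(compute_msd(list()), "empty")
  jitter <- track("j", c(0, 0.5, 1.13, 1.5), matrix(rnorm(12), 4, 3), 50, 10)
  expect_error(compute_msd(jitter), "jitter")
})

test_that("MSD: gaps are tolerated, pairs across long gaps excluded", {
  tr <- make_linear_track()
  keep <- -c(10:14)                   # a 5-frame hole
  gap <- track("g", tr$times[keep], tr$pos[keep, ], tr$R, tr$a)
  m <- compute_msd(gap, fit_window = 10)
  expect_equal(m$alpha, 2, tolerance = 1e-10)   # ballistic closed form holds
})

test_that("MSD estimator is consistent on Brownian and confined tracks", {
  # near-free Brownian motion: OU with a confinement far larger than the
  # excursion over T
  br <- lapply(1:12, function(i) gen_confined_track(
    D = 0.32, Rc = 60, dt = 0.5, T = 60, R = 100, a = 10,
    seed = 300 + i, droplet_id = i))
  m <- compute_msd(br, fit_window = 5)
  expect_gt(m$alpha, 0.9); expect_lt(m$alpha, 1.1)
  expect_equal(m$D_fit, 0.32, tolerance = 0.2)

  # confined ensemble at the measured motility parameters
  cf <- lapply(1:12, function(i) gen_confined_track(
    D = 0.32, Rc = 3.4, dt = 0.5, T = 60, seed = 400 + i, droplet_id = i))
  mc <- compute_msd(cf, fit_window = 5)
  expect_lt(abs(mc$alpha - 0.93), 0.10)
  expect_equal(mc$Rc, 3.4, tolerance = 0.1)
})

test_that("VACF: normalisation, decorrelation and persistence", {
  tr <- make_linear_track()
  v <- compute_vacf(tr)
  expect_equal(v$c[1], 1)
  expect_true(all(abs(v$c - 1) < 1e-9))   # constant velocity

  # i.i.d. displacement steps decorrelate beyond lag zero
  set.seed(5)
  n <- 400
  wn <- track("w", seq(0, by = 0.5, length.out = n),
              apply(matrix(rnorm(3 * n, sd = 0.3), n, 3), 2, cumsum), 100, 10)
  vw <- compute_vacf(wn, max_lag = 5)
  expect_true(all(abs(vw$c[-1]) < 3 / sqrt(n)))

  # directed runs stay positively correlated for several minutes
  segs <- lapply(1:10, function(i) {
    tr <- gen_breaking_track(v = 1, D = 0.32, t_break = 5, dt = 0.5, T = 40,
                             R = 40, seed = 500 + i, droplet_id = i)
    tru <- attr(tr, "truth")
    tend <- if (is.na(tru$t_reach)) max(tr$times) else tru$t_reach
    sel <- tr$times >= tru$t_break & tr$times <= tend
    track(i, tr$times[sel], tr$pos[sel, ], tr$R, tr$a)
  })
  vs <- compute_vacf(segs, max_lag = 5)
  expect_true(all(vs$c[v_lags <- vs$lags <= 4] > 0))
  expect_false(any(is.na(vs$sd[-1])))     # ensemble STD is reported

  static <- track("s", seq(0, 10, 0.5), matrix(0, 21, 3), 50, 10)
  expect_error(compute_vacf(static), "zero-variance")
})

test_that("symmetry-breaking detection: qualification threshold is sharp", {
  # deterministic radial excursion to a controllable maximum u
  mk <- function(umax, R = 40) {
    times <- seq(0, 40, 0.5)
    d <- pmin(umax * R, pmax(times - 10, 0) * 1)
    track("q", times, cbind(d, 0, 0), R, 0.2 * R)
  }
  expect_null(detect_symmetry_breaking(mk(0.29)))
  expect_s3_class(detect_symmetry_breaking(mk(0.31)), "break_event")
  # centred synthetic track never qualifies
  cf <- gen_confined_track(D = 0.32, Rc = 3.4, seed = 9)
  expect_null(detect_symmetry_breaking(cf))
})

test_that("detection recovers construction truth and is idempotent", {
  durs <- numeric(0); starts <- numeric(0)
  for (s in 1:6) {
    tr <- gen_breaking_track(v = 1, D = 0.32, D_break = 0, t_break = 20,
                             dt = 0.5, T = 60, R = 40, seed = s)
    ev <- detect_symmetry_breaking(tr)
    starts <- c(starts, ev$t_start)
    durs <- c(durs, ev$duration)
    expect_gt(ev$V, 0.8); expect_lt(ev$V, 1.2)
  }
  # the A/B/C algorithm cannot see the onset before displacement crosses
  # 0.05 R = 2 um, which takes (2 - |x0|)/v ~ 1-2 min from the confined
  # state: recovered starts sit just above t_break
  expect_true(all(starts >= 19.5 & starts <= 22.5))
  # duration ~ 0.97 d_max / v, shortened by the starting offset |x0|
  expect_true(all(abs(durs - 0.97 * 32 / 1) < 3))

  # idempotence: rerunning on the event-cropped track reproduces the
  # duration within one sample interval
  tr <- gen_breaking_track(v = 1, D = 0.32, D_break = 0, t_break = 20,
                           dt = 0.5, T = 60, R = 40, seed = 3)
  ev <- detect_symmetry_breaking(tr)
  sel <- tr$times >= ev$t_start & tr$times <= ev$t_end
  cropped <- track("c", tr$times[sel], tr$pos[sel, ], tr$R, tr$a)
  ev2 <- detect_symmetry_breaking(cropped)
  expect_lt(abs(ev2$duration - ev$duration), 0.5 + 1e-9)
})

test_that("symmetry classification: threshold, borders, invariances", {
  # threshold semantics on a hand-built table
  tab <- data.frame(droplet_id = 1:12, R = rep(40, 12),
                    d = 40 * c(0.5, 0.39, 0, 0.41, rep(c(0.1, 0.9), 4)))
  cl <- classify_symmetry(tab)
  expect_equal(cl$table$class[1:4], c(1L, 0L, 0L, 1L))

  # step-transition population: borders bracket the construction truth
  pop <- gen_population(n = 200, transition_R = 35, sharpness = Inf, seed = 42)
  cl2 <- classify_symmetry(pop)
  sr <- cl2$size_ranges
  expect_lt(abs(sr$border_small - 35), 4)
  expect_lt(abs(sr$border_large - 35), 4)
  expect_lte(sr$border_large, 35 + 4)
  expect_gte(sr$border_small, 35 - 4)

  # a graded transition yields a proper intermediate zone with ordered borders
  pop3 <- gen_population(n = 300, transition_R = 35, sharpness = 0.25,
                         seed = 43)
  sr3 <- classify_symmetry(pop3)$size_ranges
  expect_lte(sr3$border_small, sr3$border_large)

  # diameter-shift equivariance: shifting all radii moves both borders
  shifted <- pop
  shifted$R <- pop$R + 5
  shifted$d <- shifted$d * (shifted$R / pop$R)   # keep u identical
  sr_s <- classify_symmetry(shifted)$size_ranges
  expect_equal(sr_s$border_small - sr$border_small, 5, tolerance = 0.75)
  expect_equal(sr_s$border_large - sr$border_large, 5, tolerance = 0.75)

  # degenerate single-class input
  allc <- data.frame(R = seq(20, 60, length.out = 20), d = 0)
  expect_warning(cld <- classify_symmetry(allc), "degenerate")
  expect_true(cld$size_ranges$degenerate)

  expect_error(classify_symmetry(data.frame(R = 1:5, d = 0)), "at least 10")
})

test_that("recentering curves: alignment, exclusions, monotone concave v(d)", {
  # single exponential-relaxation track: aligned t = 0 at the speed peak,
  # mean curve equals the track
  times <- seq(0, 20, 0.25)
  d <- ifelse(times < 2, 18 + times, 20 * exp(-(times - 2) / 3))
  tr1 <- track("e", times, cbind(d, 0, 0), 50, 10)
  rc1 <- recentering_curves(tr1)
  a1 <- rc1$aligned[[1]]
  expect_equal(a1$t_rel[which.min(a1$v)] >= 0, TRUE)
  expect_equal(min(abs(a1$t_rel)), 0)
  expect_equal(rc1$d_curve$d_mean, a1$d[order(a1$t_rel)],
               tolerance = 1e-9)

  # zero-velocity track excluded with a warning
  flat <- track("f", times, matrix(3, length(times), 3), 50, 10)
  expect_warning(rc2 <- recentering_curves(list(tr1, flat)), "excluded")
  expect_identical(rc2$excluded, "f")

  # ensemble of simulated recentering runs: inward speed grows with
  # displacement over the recentering phase
  p <- hydro_params()
  trjs <- lapply(c(14, 18, 22), function(d0) {
    simulate_recentering(p, droplet_geometry(50, 10), d0, T = 8, dt = 0.1)
  })
  rc3 <- recentering_curves(trjs, n_dbin = 6)
  vv <- rc3$v_of_d$v_inward
  ok <- is.finite(vv) & rc3$v_of_d$n > 3
  expect_true(all(diff(vv[ok]) > -0.5))      # non-decreasing up to bin noise
  expect_gt(stats::cor(rc3$v_of_d$d_mid[ok], vv[ok]), 0.9)
})

test_that("track CSV schema round-trips losslessly", {
  trks <- list(gen_confined_track(0.32, 3.4, seed = 1, droplet_id = 1),
               gen_confined_track(0.32, 3.4, seed = 2, droplet_id = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(trks, path)
  hdr <- readLines(path, n = 1)
  expect_identical(hdr, "droplet_id,t_min,x_um,y_um,z_um,R_um,a_um")
  back <- read_tracks(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$pos, trks[[1]]$pos, tolerance = 1e-12)
  expect_equal(back[[2]]$times, trks[[2]]$times)
})
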