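# Aggregate-track statistics: MSD, VACF, symmetry-breaking detection,
# population symmetry classification, recentering-curve alignment.

# place track samples on the nominal time grid; returns positions with NA
# rows for missing frames, the gap-group label per grid index, and dt
track_on_grid <- function(tr, jitter_tol = 0.1) {
  dts <- diff(tr$times)
  dt <- stats::median(dts)
  k <- round(dts / dt)
  if (any(abs(dts - k * dt) / dt > jitter_tol)) {
    stop(sprintf("track %s: non-uniform sampling beyond %.0f%% jitter",
                 as.character(tr$droplet_id), 100 * jitter_tol), call. = FALSE)
  }
  idx <- c(0L, cumsum(k)) + 1L
  n <- idx[length(idx)]
  P <- matrix(NA_real_, n, 3L)
  P[idx, ] <- tr$pos
  # pairs spanning gaps longer than 2 nominal intervals are excluded:
  # label contiguous stretches between such gaps
  grp_samples <- c(0L, cumsum(k > 2L))
  grp <- rep(NA_integer_, n)
  grp[idx] <- grp_samples
  list(P = P, grp = grp, dt = dt, idx = idx)
}

# time-averaged MSD over all ordered same-group pairs, per lag multiple
msd_single <- function(g, max_lag_n) {
  n <- nrow(g$P)
  K <- min(n - 1L, max_lag_n)
  msd <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    i <- seq_len(n - k)
    dP <- g$P[i + k, , drop = FALSE] - g$P[i, , drop = FALSE]
    ok <- !is.na(dP[, 1]) & !is.na(g$grp[i]) & !is.na(g$grp[i + k]) &
      g$grp[i] == g$grp[i + k]
    if (any(ok)) msd[k] <- mean(rowSums(dP[ok, , drop = FALSE]^2))
  }
  msd
}

#' Ensemble mean squared displacement and power-law fit
#'
#' Computes the time-averaged MSD of each track over all ordered sample
#' pairs (lags from the actual timestamps; pairs spanning gaps longer than
#' two nominal intervals are excluded), then the unweighted ensemble mean
#' across tracks, and fits `MSD = 6 D t^alpha` by least squares on log-log
#' axes restricted to lags up to `fit_window`.
#'
#' @param tracks A track or list of tracks with a common nominal sampling
#'   interval.
#' @param fit_window Largest lag (min) used in the fit (default 5).
#' @param max_lag Largest lag (min) at which the MSD is reported (default
#'   half the shortest track duration).
#' @return An object of class `msd_result`: `lags` (min), `msd` (um^2,
#'   ensemble mean), `per_track` (matrix, one row per track), `alpha`,
#'   `D_fit` (um^2/min), `fit_window`, `Rc` (um, RMS distance from the
#'   droplet centre over all samples) and `n_tracks`. For degenerate input
#'   (zero MSD) `alpha` and `D_fit` are `NA` and `degenerate` is `TRUE`.
#' @export
compute_msd <- function(tracks, fit_window = 5, max_lag = NULL) {
  tracks <- as_track_list(tracks)
  if (length(tracks) == 0L) stop("empty track ensemble", call. = FALSE)
  if (any(vapply(tracks, function(tr) length(tr$times), integer(1)) < 2L)) {
    stop("every track needs at least 2 samples", call. = FALSE)
  }
  grids <- lapply(tracks, track_on_grid)
  dt <- grids[[1]]$dt
  if (any(abs(vapply(grids, `[[`, numeric(1), "dt") - dt) > 1e-9)) {
    stop("tracks have different nominal sampling intervals", call. = FALSE)
  }
  max_lag <- max_lag %||% (min(vapply(tracks, function(tr) diff(range(tr$times)),
                                      numeric(1))) / 2)
  K <- max(1L, floor(max_lag / dt))
  per <- t(vapply(grids, msd_single, numeric(K), max_lag_n = K))
  if (is.null(dim(per))) per <- matrix(per, nrow = length(grids))
  lags <- dt * seq_len(K)
  msd <- colMeans(per, na.rm = TRUE)
  msd[!is.finite(msd)] <- NA_real_

  rall <- unlist(lapply(tracks, track_displacement))
  Rc <- sqrt(mean(rall^2))

  sel <- which(lags <= fit_window + 1e-9 & is.finite(msd) & msd > 0)
  degenerate <- length(sel) < 2L
  if (degenerate) {
    alpha <- NA_real_; D_fit <- NA_real_
  } else {
    fit <- stats::lm(log(msd[sel]) ~ log(lags[sel]))
    alpha <- unname(stats::coef(fit)[2])
    D_fit <- exp(unname(stats::coef(fit)[1])) / 6
  }
  structure(list(lags = lags, msd = msd, per_track = per, alpha = alpha,
                 D_fit = D_fit, fit_window = fit_window, Rc = Rc,
                 n_tracks = length(tracks), degenerate = degenerate),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> %d tracks, alpha = %.3f, D = %.3g um^2/min (lags <= %g min), Rc = %.2f um\n",
              x$n_tracks, x$alpha, x$D_fit, x$fit_window, x$Rc))
  invisible(x)
}

#' Normalised velocity autocorrelation function
#'
#' Velocities by forward differences at interval `dt_v`; per-track
#' autocorrelation `c(tau) = <v(t) . v(t + tau)> / <v(t) . v(t)>` averaged
#' over `t`, then ensemble mean and standard deviation across tracks.
#' `c(0) = 1` by construction.
#'
#' @param tracks A track or list of tracks.
#' @param dt_v Velocity differencing interval (min); default the native
#'   sampling interval.
#' @param max_lag Largest lag (min) reported (default a quarter of the
#'   shortest track).
#' @return An object of class `vacf_result`: `lags`, `c` (ensemble mean),
#'   `sd` (ensemble STD), `per_track`, `n_tracks`.
#' @export
compute_vacf <- function(tracks, dt_v = NULL, max_lag = NULL) {
  tracks <- as_track_list(tracks)
  if (length(tracks) == 0L) stop("empty track ensemble", call. = FALSE)
  grids <- lapply(tracks, track_on_grid)
  dt <- grids[[1]]$dt
  dt_v <- dt_v %||% dt
  stride <- max(1L, round(dt_v / dt))
  dt_v <- stride * dt
  max_lag <- max_lag %||% (min(vapply(tracks, function(tr) diff(range(tr$times)),
                                      numeric(1))) / 4)
  K <- max(1L, floor(max_lag / dt_v))

  per <- t(vapply(grids, function(g) {
    n <- nrow(g$P)
    if (n <= stride) stop("track too short for velocity differencing", call. = FALSE)
    i <- seq_len(n - stride)
    Vm <- (g$P[i + stride, , drop = FALSE] - g$P[i, , drop = FALSE]) / dt_v
    ok_v <- !is.na(Vm[, 1]) & !is.na(g$grp[i]) & !is.na(g$grp[i + stride]) &
      g$grp[i] == g$grp[i + stride]
    Vm[!ok_v, ] <- NA_real_
    denom <- mean(rowSums(Vm^2), na.rm = TRUE)
    if (!is.finite(denom) || denom == 0) {
      stop("zero-variance velocity: VACF normalisation undefined", call. = FALSE)
    }
    cv <- numeric(K + 1L)
    cv[1] <- 1
    nv <- nrow(Vm)
    for (k in seq_len(K)) {
      j <- seq_len(max(nv - k * stride, 0L))
      cv[k + 1L] <- if (length(j) == 0L) NA_real_ else {
        mean(rowSums(Vm[j, , drop = FALSE] *
                       Vm[j + k * stride, , drop = FALSE]), na.rm = TRUE) / denom
      }
    }
    cv
  }, numeric(K + 1L)))
  if (is.null(dim(per))) per <- matrix(per, nrow = length(grids))

  structure(list(lags = dt_v * (0:K), c = colMeans(per, na.rm = TRUE),
                 sd = apply(per, 2, stats::sd, na.rm = TRUE),
                 per_track = per, dt_v = dt_v, n_tracks = length(tracks)),
            class = "vacf_result")
}

#' @export
print.vacf_result <- function(x, ...) {
  cat(sprintf("<vacf_result> %d tracks, %d lags at dt_v = %g min, c(0) = %g\n",
              x$n_tracks, length(x$lags), x$dt_v, x$c[1]))
  invisible(x)
}

#' Detect a symmetry-breaking event in a track
#'
#' Implements the A/B/C point algorithm. A track qualifies if its normalised
#' displacement `u = d / R` ever reaches `qualify` (default 0.3). Point A is
#' the last time `u` was at most `thresh_A` (default 0.05) of the radius;
#' point C the first time the displacement reached `thresh_C` (default 0.97)
#' of its maximum; point B the time of highest velocity-velocity correlation
#' (dot product of consecutive velocity vectors at the differencing interval
#' `dt_B`, default native) between A and C. The event starts at the last
#' point between A and B with negative radial velocity (A if none) and ends
#' at C.
#'
#' @param tr A [track].
#' @param qualify Qualification threshold on `max(u)`.
#' @param thresh_A Displacement fraction of `R` defining point A.
#' @param thresh_C Fraction of the maximum displacement defining point C.
#' @param dt_B Velocity interval (min) for the point-B correlation; default
#'   the native sampling interval.
#' @return A `break_event` (fields `t_start`, `t_end`, `duration`, `V`
#'   (mean signed radial velocity, positive outward), `A`, `B`, `C`) or
#'   `NULL` for tracks that never qualify.
#' @export
detect_symmetry_breaking <- function(tr, qualify = 0.3, thresh_A = 0.05,
                                     thresh_C = 0.97, dt_B = NULL) {
  stopifnot(inherits(tr, "track"))
  d <- track_displacement(tr)
  u <- d / tr$R
  if (max(u) < qualify) return(NULL)

  iA <- which(u <= thresh_A)
  iA <- if (length(iA) > 0L) iA[length(iA)] else 1L
  iC <- which(d >= thresh_C * max(d))[1]

  # velocity-velocity correlation of consecutive velocity vectors
  dtn <- stats::median(diff(tr$times))
  stride <- max(1L, round((dt_B %||% dtn) / dtn))
  n <- nrow(tr$pos)
  iv <- seq_len(n - stride)
  Vm <- (tr$pos[iv + stride, , drop = FALSE] - tr$pos[iv, , drop = FALSE]) /
    (tr$times[iv + stride] - tr$times[iv])
  nv <- nrow(Vm)
  corr <- rowSums(Vm[seq_len(nv - stride), , drop = FALSE] *
                    Vm[seq_len(nv - stride) + stride, , drop = FALSE])
  lo <- min(iA, length(corr)); hi <- min(iC, length(corr))
  iB <- if (hi >= lo) (lo:hi)[which.max(corr[lo:hi])] else iA

  v_rad <- diff(d) / diff(tr$times)
  win <- iA:max(iA, min(iB, length(v_rad)))
  neg <- win[v_rad[win] < 0]
  i_start <- if (length(neg) > 0L) neg[length(neg)] else iA

  t_start <- tr$times[i_start]; t_end <- tr$times[iC]
  seg <- i_start:max(i_start, iC - 1L)
  V <- mean(v_rad[seg])
  structure(list(t_start = t_start, t_end = t_end,
                 duration = t_end - t_start, V = V,
                 A = tr$times[iA], B = tr$times[iB], C = tr$times[iC]),
            class = "break_event")
}

#' @export
print.break_event <- function(x, ...) {
  cat(sprintf("<break_event> start %.2f -> end %.2f min (duration %.2f min), V = %.2f um/min\n",
              x$t_start, x$t_end, x$duration, x$V))
  invisible(x)
}

#' Classify population symmetry and find size-range borders
#'
#' Binary classification of droplets as centred (`u <= threshold`) or polar
#' (`u > threshold`) with `u = d / R`, followed by a Gaussian-kernel moving
#' mean of the binary states over droplet *diameter* (kernel variance
#' `kernel_var`, um^2), evaluated at each droplet. The border between the
#' small (polar) and intermediate ranges is where the cumulative mean of the
#' smoothed curve first drops below `cum_drop` of its max-min range; the
#' border between the large (centred) and intermediate ranges is found
#' analogously from the reverse cumulative mean of one minus the curve.
#'
#' @param table A data.frame with columns `R` and `d` (or `R_um` and `d_um`),
#'   one row per droplet; at least 10 droplets.
#' @param threshold Normalised-displacement threshold (default 0.4).
#' @param kernel_var Variance of the Gaussian window in diameter space
#'   (um^2, default 5).
#' @param cum_drop Cumulative-mean drop fraction (default 0.95).
#' @return An object of class `symmetry_classification`: `table` (with `u`
#'   and `class` columns, original order), `curve` (diameter-sorted smoothed
#'   symmetry-breaking curve), and `size_ranges` with `border_small` and
#'   `border_large` (um, radius units; `NA` and `degenerate = TRUE` when all
#'   droplets are one class).
#' @export
classify_symmetry <- function(table, threshold = 0.4, kernel_var = 5,
                              cum_drop = 0.95) {
  R <- table$R %||% table$R_um
  d <- table$d %||% table$d_um
  if (is.null(R) || is.null(d)) {
    stop("table needs columns R and d (or R_um and d_um)", call. = FALSE)
  }
  if (length(R) < 10L) stop("need at least 10 droplets", call. = FALSE)
  u <- d / R
  cls <- as.integer(u > threshold)

  ord <- order(2 * R)
  x <- (2 * R)[ord]                 # diameters, ascending
  y <- cls[ord]
  W <- exp(-outer(x, x, "-")^2 / (2 * kernel_var))
  curve <- as.numeric(W %*% y) / rowSums(W)

  degenerate <- all(cls == 0L) || all(cls == 1L)
  if (degenerate) {
    warning("all droplets in one class; size-range borders are degenerate")
    border_small <- NA_real_; border_large <- NA_real_
  } else {
    cm <- cumsum(curve) / seq_along(curve)
    rng <- max(cm) - min(cm)
    thr <- min(cm) + cum_drop * rng
    i <- which(cm < thr)[1]
    border_small <- if (is.na(i)) NA_real_ else x[i] / 2

    g <- rev(1 - curve)
    rcm <- cumsum(g) / seq_along(g)
    rng2 <- max(rcm) - min(rcm)
    thr2 <- min(rcm) + cum_drop * rng2
    j <- which(rcm < thr2)[1]
    border_large <- if (is.na(j)) NA_real_ else rev(x)[j] / 2
  }

  out <- table
  out$u <- u
  out$class <- cls
  structure(list(table = out,
                 curve = data.frame(diameter_um = x, curve = curve),
                 size_ranges = list(border_small = border_small,
                                    border_large = border_large,
                                    degenerate = degenerate),
                 config = list(threshold = threshold, kernel_var = kernel_var,
                               cum_drop = cum_drop)),
            class = "symmetry_classification")
}

#' @export
print.symmetry_classification <- function(x, ...) {
  sr <- x$size_ranges
  cat(sprintf("<symmetry_classification> %d droplets, %.0f%% polar; borders small/large = %.1f / %.1f um\n",
              nrow(x$table), 100 * mean(x$table$class),
              sr$border_small, sr$border_large))
  invisible(x)
}

# extract (t, d) pairs from a track or recenter_trajectory
displacement_series <- function(x) {
  if (inherits(x, "track")) {
    list(t = x$times, d = track_displacement(x), id = x$droplet_id)
  } else if (inherits(x, "recenter_trajectory")) {
    list(t = x$times, d = x$d, id = "sim")
  } else stop("expected a track or recenter_trajectory", call. = FALSE)
}

#' Align recentering curves at the onset of recentering
#'
#' Each trajectory is shifted so that t = 0 is the time at which the
#' aggregate moved with zero radial velocity (the last outward-to-inward
#' sign change before the speed maximum) or, if the velocity never changes
#' sign, the time of its minimal recorded (most negative) velocity. Tracks
#' with monotone velocity and no interior minimum are excluded with a
#' warning. Returns the aligned ensemble mean and standard deviation of the
#' displacement over time and of the inward speed binned by displacement.
#'
#' @param tracks List of [track] and/or [simulate_recentering()] objects.
#' @param n_dbin Number of displacement bins for the velocity-displacement
#'   curve.
#' @return An object of class `recentering_curves`: `aligned` (per-track
#'   data.frames with `t_rel`, `d`, `v`), `d_curve` (ensemble mean/sd of
#'   `d(t)`), `v_of_d` (ensemble inward speed vs displacement bin) and
#'   `excluded` (ids).
#' @export
recentering_curves <- function(tracks, n_dbin = 10L) {
  if (inherits(tracks, "track") || inherits(tracks, "recenter_trajectory")) {
    tracks <- list(tracks)
  }
  aligned <- list()
  excluded <- character(0)
  for (x in tracks) {
    s <- displacement_series(x)
    if (length(s$t) < 3L) { excluded <- c(excluded, as.character(s$id)); next }
    v <- diff(s$d) / diff(s$t)       # signed, positive = outward
    tv <- s$t[-length(s$t)]
    if (all(v == 0)) {
      warning(sprintf("track %s has zero velocity throughout; excluded",
                      as.character(s$id)))
      excluded <- c(excluded, as.character(s$id)); next
    }
    imin <- which.min(v)
    sgn <- sign(v)
    cross <- which(sgn[-1] < 0 & sgn[-length(sgn)] >= 0) + 1L
    cross <- cross[cross <= imin]
    if (length(cross) > 0L) {
      i0 <- cross[length(cross)]
    } else if (imin > 1L && imin < length(v)) {
      i0 <- imin
    } else {
      warning(sprintf("track %s has monotone velocity with no interior minimum; excluded",
                      as.character(s$id)))
      excluded <- c(excluded, as.character(s$id)); next
    }
    t0 <- tv[i0]
    aligned[[length(aligned) + 1L]] <-
      data.frame(id = as.character(s$id), t_rel = tv - t0,
                 d = s$d[-length(s$d)], v = v)
  }
  if (length(aligned) == 0L) {
    stop("no usable tracks for recentering alignment", call. = FALSE)
  }
  all_df <- do.call(rbind, aligned)

  # ensemble d(t): bin on the common relative-time grid
  dtn <- stats::median(unlist(lapply(aligned, function(a) diff(a$t_rel))))
  tb <- round(all_df$t_rel / dtn) * dtn
  d_curve <- do.call(rbind, lapply(split(all_df$d, tb), function(z) {
    data.frame(d_mean = mean(z), d_sd = stats::sd(z), n = length(z))
  }))
  d_curve <- data.frame(t_rel = as.numeric(rownames(d_curve)), d_curve,
                        row.names = NULL)
  d_curve <- d_curve[order(d_curve$t_rel), ]

  # inward speed vs displacement, recentering phase only (t_rel >= 0)
  rec <- all_df[all_df$t_rel >= 0, ]
  brk <- seq(0, max(rec$d) + 1e-9, length.out = n_dbin + 1L)
  db <- cut(rec$d, brk, include.lowest = TRUE)
  v_of_d <- data.frame(
    d_mid = (brk[-1] + brk[-length(brk)]) / 2,
    v_inward = as.numeric(tapply(-rec$v, db, mean)),
    v_sd = as.numeric(tapply(rec$v, db, stats::sd)),
    n = as.integer(table(db)))
  structure(list(aligned = aligned, d_curve = d_curve, v_of_d = v_of_d,
                 excluded = excluded),
            class = "recentering_curves")
}
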