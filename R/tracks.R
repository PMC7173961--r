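#' Aggregate position track
#'
#' Time-stamped 3D positions of an aggregate centroid relative to the droplet
#' centre, with droplet metadata. The unit of the analysis pipeline.
#'
#' @param droplet_id Identifier (scalar).
#' @param times Times (min), strictly increasing; gaps allowed.
#' @param pos Numeric matrix `n x 3` of positions (um) relative to the
#'   droplet centre.
#' @param R Droplet radius (um).
#' @param a Aggregate radius (um).
#' @param tol Tolerance for the confinement check `|pos| <= R - a + tol`.
#' @return An object of class `track`.
#' @export
track <- function(droplet_id, times, pos, R, a, tol = 1e-6) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L) stop("`pos` must have 3 columns", call. = FALSE)
  if (length(times) != nrow(pos)) stop("times/pos length mismatch", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  assert_scalar_num(R, "R", positive = TRUE)
  assert_scalar_num(a, "a", positive = TRUE)
  r <- sqrt(rowSums(pos^2))
  if (any(r > R - a + tol)) {
    stop(sprintf("track leaves the droplet: max |pos| = %.3g > R - a = %.3g",
                 max(r), R - a), call. = FALSE)
  }
  structure(list(droplet_id = droplet_id, times = as.numeric(times),
                 pos = unname(pos), R = R, a = a),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> droplet %s: %d samples over %.1f min (R = %g um)\n",
              as.character(x$droplet_id), length(x$times),
              diff(range(x$times)), x$R))
  invisible(x)
}

# radial distance from the droplet centre at each sample
track_displacement <- function(tr) sqrt(rowSums(tr$pos^2))

as_track_list <- function(tracks) {
  if (inherits(tracks, "track")) return(list(tracks))
  if (!is.list(tracks) || !all(vapply(tracks, inherits, logical(1), "track"))) {
    stop("expected a track or a list of tracks", call. = FALSE)
  }
  tracks
}

#' Write tracks to CSV
#'
#' Header is exactly
#' `droplet_id, t_min, x_um, y_um, z_um, R_um, a_um`; positions are relative
#' to the droplet centre. Multiple tracks are stacked and distinguished by
#' `droplet_id`.
#'
#' @param tracks A track or list of tracks.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- as_track_list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(droplet_id = tr$droplet_id, t_min = tr$times,
               x_um = tr$pos[, 1], y_um = tr$pos[, 2], z_um = tr$pos[, 3],
               R_um = tr$R, a_um = tr$a)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' @param path Path to a CSV written in the [write_tracks()] schema.
#' @return A list of `track` objects, one per `droplet_id`.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("droplet_id", "t_min", "x_um", "y_um", "z_um", "R_um", "a_um")
  if (!all(need %in% names(df))) {
    stop("track CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$droplet_id), function(g) {
    g <- g[order(g$t_min), ]
    track(g$droplet_id[1], g$t_min,
          cbind(g$x_um, g$y_um, g$z_um), g$R_um[1], g$a_um[1])
  })
}
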