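#' Discretise the droplet on an axisymmetric finite-volume grid
#'
#' The droplet has exact rotational symmetry about the axis through the
#' droplet centre and the aggregate centre, so the 3D problem reduces to the
#' cylindrical half-plane (s, z) with `s >= 0` the distance from the symmetry
#' axis and `z` the axial coordinate (droplet centre at the origin, aggregate
#' centre at `(0, d)`). Cells are squares of side `h`; the volume of cell
#' `(i, j)` carries the axisymmetric weight `2 * pi * s_i * h^2`. Cells are
#' labelled `cytoplasm`, `aggregate` or `exterior` by the signed distance of
#' their centres to the two spheres.
#'
#' @param geom A [droplet_geometry].
#' @param h Grid spacing (um); must satisfy `h < a / 4` so that the aggregate
#'   is resolved.
#' @return An object of class `axi_grid` holding the cell lattice, the
#'   cytoplasm mask, cell volumes, the interior face list with areas and
#'   upwind-stencil neighbours, and prebuilt sparse scatter/average operators.
#' @export
build_geometry <- function(geom, h) {
  stopifnot(inherits(geom, "droplet_geometry"))
  assert_scalar_num(h, "h", positive = TRUE)
  if (h >= geom$a / 4) {
    stop(sprintf("grid spacing h = %.3g does not resolve the aggregate (need h < a/4 = %.3g)",
                 h, geom$a / 4), call. = FALSE)
  }
  R <- geom$R; a <- geom$a; d <- geom$d

  Ns <- as.integer(ceiling(R / h)) + 1L
  Nzh <- as.integer(ceiling(R / h)) + 1L
  Nz <- 2L * Nzh
  s <- (seq_len(Ns) - 0.5) * h
  z <- (seq_len(Nz) - Nzh - 0.5) * h

  ij <- expand.grid(i = seq_len(Ns), j = seq_len(Nz))
  sc <- s[ij$i]; zc <- z[ij$j]
  r_drop <- sqrt(sc^2 + zc^2)
  r_agg <- sqrt(sc^2 + (zc - d)^2)
  mask <- integer(Ns * Nz)           # 0 exterior, 1 cytoplasm, 2 aggregate
  mask[r_drop < R & r_agg > a] <- 1L
  mask[r_drop < R & r_agg <= a] <- 2L
  cyto <- mask == 1L

  # cut-cell fluid volumes: 5x5 subsampling with the axisymmetric 2*pi*s
  # weight; fluid slivers of excluded boundary cells are credited to their
  # cytoplasm neighbours so that the total discrete volume matches the true
  # cytoplasm volume (fluxes are untouched: mass stays exactly conserved)
  off <- (seq_len(5L) - 3L) / 5
  volw <- numeric(Ns * Nz)
  for (os in off) {
    ss <- sc + os * h
    sw <- pmax(ss, 0)
    for (oz in off) {
      zz <- zc + oz * h
      fluid <- (ss^2 + zz^2 < R^2) & (ss^2 + (zz - d)^2 > a^2)
      volw <- volw + sw * fluid
    }
  }
  vol_fluid <- 2 * pi * h^2 * volw / 25
  vol <- ifelse(cyto, pmax(vol_fluid, pi * sc * h^2), 2 * pi * sc * h^2)
  sliver <- which(!cyto & vol_fluid > 0)
  if (length(sliver) > 0L) {
    nb <- cbind(sliver - 1L, sliver + 1L, sliver - Ns, sliver + Ns)
    nb[nb < 1L | nb > Ns * Nz] <- NA
    nb_ok <- !is.na(nb) & matrix(cyto[ifelse(is.na(nb), 1L, nb)], nrow(nb))
    nn <- rowSums(nb_ok)
    for (k in seq_along(sliver)) {
      if (nn[k] > 0L) {
        tgt <- nb[k, nb_ok[k, ]]
        vol[tgt] <- vol[tgt] + vol_fluid[sliver[k]] / nn[k]
      }
    }
  }

  # interior faces: s-direction (between (i,j) and (i+1,j)) and z-direction
  f_s <- which(ij$i < Ns)
  fs_p <- f_s; fs_q <- f_s + 1L
  keep <- cyto[fs_p] & cyto[fs_q]
  fs_p <- fs_p[keep]; fs_q <- fs_q[keep]

  f_z <- which(ij$j < Nz)
  fz_p <- f_z; fz_q <- f_z + Ns
  keep <- cyto[fz_p] & cyto[fz_q]
  fz_p <- fz_p[keep]; fz_q <- fz_q[keep]

  n_fs <- length(fs_p); n_fz <- length(fz_p)
  fp <- c(fs_p, fz_p); fq <- c(fs_q, fz_q)
  fdir <- rep(c(1L, 2L), c(n_fs, n_fz))

  # face centres and areas (s-face sits at s = i*h; z-face at cell s)
  face_s <- c(s[ij$i[fs_p]] + h / 2, sc[fz_p])
  face_z <- c(zc[fs_p], zc[fz_p] + h / 2)
  area <- 2 * pi * face_s * h

  # second-upwind neighbours for the MUSCL reconstruction
  pp <- integer(length(fp)); qq <- integer(length(fp))
  pp[seq_len(n_fs)] <- fs_p - 1L
  qq[seq_len(n_fs)] <- fs_q + 1L
  pp_ok_s <- ij$i[fs_p] > 1L
  qq_ok_s <- ij$i[fs_q] < Ns
  pp[n_fs + seq_len(n_fz)] <- fz_p - Ns
  qq[n_fs + seq_len(n_fz)] <- fz_q + Ns
  pp_ok_z <- ij$j[fz_p] > 1L
  qq_ok_z <- ij$j[fz_q] < Nz
  pp_ok <- c(pp_ok_s, pp_ok_z)
  qq_ok <- c(qq_ok_s, qq_ok_z)
  pp[!pp_ok] <- 1L; qq[!qq_ok] <- 1L   # dummy, guarded by validity flags
  pp_ok <- pp_ok & cyto[pp]
  qq_ok <- qq_ok & cyto[qq]

  nf <- length(fp)
  ncell <- Ns * Nz
  S <- Matrix::sparseMatrix(i = c(fp, fq), j = c(seq_len(nf), seq_len(nf)),
                            x = c(rep(-1, nf), rep(1, nf)),
                            dims = c(ncell, nf))

  # face -> cell averaging operators per direction (for cell-centred gradients)
  avg_op <- function(sel) {
    f <- which(sel)
    W <- Matrix::sparseMatrix(i = c(fp[f], fq[f]),
                              j = c(seq_along(f), seq_along(f)),
                              x = rep(1, 2 * length(f)),
                              dims = c(ncell, length(f)))
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    Matrix::Diagonal(x = 1 / rs) %*% W
  }
  Ws <- avg_op(fdir == 1L)
  Wz <- avg_op(fdir == 2L)

  structure(list(geom = geom, h = h, Ns = Ns, Nz = Nz, s = s, z = z,
                 sc = sc, zc = zc, mask = mask, cyto = cyto, vol = vol,
                 fp = fp, fq = fq, fdir = fdir, face_s = face_s,
                 face_z = face_z, area = area,
                 pp = pp, qq = qq, pp_ok = pp_ok, qq_ok = qq_ok,
                 S = S, Ws = Ws, Wz = Wz),
            class = "axi_grid")
}

#' @export
print.axi_grid <- function(x, ...) {
  cat(sprintf("<axi_grid> %d x %d cells (h = %g um), %d cytoplasm cells, %d faces\n",
              x$Ns, x$Nz, x$h, sum(x$cyto), length(x$fp)))
  invisible(x)
}

#' Total cytoplasm volume represented by the grid (um^3)
#' @param grid An [build_geometry()] grid.
#' @return Numeric scalar.
#' @export
cytoplasm_volume <- function(grid) sum(grid$vol[grid$cyto])

#' Prescribed network velocity field
#'
#' The contracting network moves centripetally toward the aggregate with a
#' speed that grows linearly with distance from the aggregate surface and
#' vanishes on it: `V(x) = -gamma * max(|x - x_agg| - a, 0) * u(x)` with
#' `u` the unit vector pointing from the aggregate centre to `x`. The field
#' is evaluated analytically at face centres (normal components, used by the
#' finite-volume fluxes) and at cell centres.
#'
#' @param grid An `axi_grid`.
#' @param geom The [droplet_geometry] the grid was built for.
#' @param gamma Contraction rate (1/min), `>= 0`.
#' @return An object of class `network_velocity` with face-normal velocities
#'   `vn`, cell-centred components `Vs`, `Vz`, and the upwind stencil.
#' @export
network_velocity_field <- function(grid, geom, gamma) {
  assert_scalar_num(gamma, "gamma", nonneg = TRUE)
  d <- geom$d; a <- geom$a

  vcomp <- function(sx, zx) {
    r <- sqrt(sx^2 + (zx - d)^2)
    mag <- gamma * pmax(r - a, 0)
    r[r == 0] <- 1
    list(vs = -mag * sx / r, vz = -mag * (zx - d) / r)
  }

  vf <- vcomp(grid$face_s, grid$face_z)
  vn <- ifelse(grid$fdir == 1L, vf$vs, vf$vz)
  vc <- vcomp(grid$sc, grid$zc)
  Vs <- ifelse(grid$cyto, vc$vs, 0)
  Vz <- ifelse(grid$cyto, vc$vz, 0)

  # static upwind stencil (face velocities do not change during relaxation)
  up <- ifelse(vn >= 0, grid$fp, grid$fq)
  dn <- ifelse(vn >= 0, grid$fq, grid$fp)
  uu <- ifelse(vn >= 0, grid$pp, grid$qq)
  uu_ok <- ifelse(vn >= 0, grid$pp_ok, grid$qq_ok)

  structure(list(gamma = gamma, vn = vn, Vs = Vs, Vz = Vz,
                 up = up, dn = dn, uu = uu, uu_ok = uu_ok),
            class = "network_velocity")
}
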