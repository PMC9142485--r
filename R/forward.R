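#' Scalp potential of a current dipole in a homogeneous sphere
#'
#' Closed-form surface potential of a current dipole inside a homogeneous
#' conducting sphere with an insulating exterior. The classical spherical
#' harmonic expansion of the boundary-value problem,
#' \deqn{V = \frac{1}{4\pi\sigma R^2}\sum_{n\ge 1} x^{n-1}
#'   \left[(2n+1)\,q_r P_n(\cos\gamma) +
#'   \frac{2n+1}{n}\, q_t P^1_n(\cos\gamma)\cos\phi\right],}
#' with \eqn{x = f/R} the dipole eccentricity, is summed analytically via
#' Legendre generating-function identities, giving an exact expression in
#' terms of the electrode-dipole geometry. Potentials are returned
#' average-referenced (mean over electrodes subtracted), matching the
#' reference of the recorded data.
#'
#' @param position dipole location, 3-vector, meters, head (MNI-aligned)
#'   frame. Must be strictly inside the model sphere.
#' @param moment dipole moment, 3-vector, nAm.
#' @param montage an [build_montage()] montage (electrodes on the sphere).
#' @return numeric vector of per-electrode potentials in microvolts,
#'   average-referenced (sums to zero), named by channel label.
#' @export
dipole_potential <- function(position, moment, montage) {
  sph <- montage$sphere
  r0 <- as.numeric(position) - sph$center
  f <- sqrt(sum(r0^2))
  R <- sph$radius
  if (f >= R) stop("dipole position must lie strictly inside the sphere")
  q <- as.numeric(moment) * 1e-9          # nAm -> A m
  k <- 1 / (4 * pi * sph$sigma * R^2)     # volts per (A m / m^2)
  e <- sweep(montage$pos, 2, sph$center, "-") / R   # unit electrode dirs
  if (f < 1e-9) {
    # central dipole: only the n = 1 term survives
    v <- 3 * k * drop(e %*% q)
  } else {
    rhat <- r0 / f
    x <- f / R
    cth <- pmin(1, pmax(-1, drop(e %*% rhat)))
    A <- sqrt(pmax(0, 1 - 2 * x * cth + x^2))
    qr <- sum(q * rhat)
    # radial series:  sum_n (2n+1) x^(n-1) P_n(c)
    Fr <- (2 * x * (cth - x) / A^3 + 1 / A - 1) / x
    # tangential series with sin(gamma) absorbed into q.(e - c rhat)
    Tt <- 2 / A^3 + (A + 1) / (A * (1 - x * cth + A))
    qe <- drop(e %*% q) - cth * qr
    v <- k * (qr * Fr + qe * Tt)
  }
  v <- (v - mean(v)) * 1e6                # average reference, uV
  names(v) <- montage$labels
  v
}

#' Beamformer source grid in MNI space
#'
#' Regular isotropic grid of voxel centers covering the model brain: the
#' sphere shrunk by 10% intersected with an MNI-like bounding box. Voxel
#' centers sit on multiples of the spacing.
#'
#' @param spacing grid step in mm (default 10)
#' @param sphere model sphere, see [head_sphere()]
#' @return object of class `source_grid`: list with `pos` (V x 3 matrix of
#'   voxel centers, mm, MNI), `spacing` (mm), and `sphere`.
#' @export
source_grid <- function(spacing = 10, sphere = head_sphere()) {
  box <- list(x = c(-70, 70), y = c(-95, 70), z = c(-45, 85))
  ax <- lapply(box, function(r) seq(ceiling(r[1] / spacing) * spacing,
                                    floor(r[2] / spacing) * spacing,
                                    by = spacing))
  g <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  ctr <- sphere$center * 1000
  rad <- 0.9 * sphere$radius * 1000
  keep <- sqrt(rowSums(sweep(g, 2, ctr, "-")^2)) <= rad
  structure(list(pos = g[keep, , drop = FALSE], spacing = spacing,
                 sphere = sphere), class = "source_grid")
}

#' Lead field for a source grid
#'
#' Gain matrix of the spherical forward model: scalp potential pattern of
#' a unit (1 nAm) dipole along each coordinate axis at every grid voxel.
#' Each gain vector is average-referenced by construction. Voxels that
#' fall on or outside the model sphere are dropped with a warning.
#'
#' @param grid a [source_grid()]
#' @param montage an [build_montage()] montage
#' @return object of class `leadfield`: list with `gain` (array
#'   n_channels x 3 x n_voxels, uV per nAm), `grid` (possibly reduced),
#'   and `montage` labels.
#' @export
build_leadfield <- function(grid, montage) {
  sph <- montage$sphere
  posm <- grid$pos / 1000
  d <- sqrt(rowSums(sweep(posm, 2, sph$center, "-")^2))
  ok <- d < sph$radius - 1e-9
  if (!all(ok)) {
    warning(sum(!ok), " voxel(s) outside the model sphere excluded")
    grid$pos <- grid$pos[ok, , drop = FALSE]
    posm <- posm[ok, , drop = FALSE]
  }
  nv <- nrow(posm)
  gain <- array(NA_real_, c(length(montage$labels), 3L, nv),
                dimnames = list(montage$labels, c("x", "y", "z"), NULL))
  eye <- diag(3)
  for (v in seq_len(nv)) {
    for (a in 1:3) {
      gain[, a, v] <- dipole_potential(posm[v, ], eye[a, ], montage)
    }
  }
  structure(list(gain = gain, grid = grid, labels = montage$labels),
            class = "leadfield")
}

#' Face-adjacency neighbor table for a source grid
#'
#' 6-connectivity (face-adjacent voxels one spacing apart along an axis),
#' used by the spatial cluster correction in source space.
#' @param grid a [source_grid()]
#' @return integer matrix V x 6; `NA` where no neighbor exists.
#' @export
grid_neighbors <- function(grid) {
  key <- function(p) paste(p[, 1], p[, 2], p[, 3])
  idx <- stats::setNames(seq_len(nrow(grid$pos)), key(grid$pos))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * grid$spacing
  nb <- matrix(NA_integer_, nrow(grid$pos), 6L)
  for (k in 1:6) {
    shifted <- sweep(grid$pos, 2, offs[k, ], "+")
    m <- idx[key(shifted)]
    nb[, k] <- unname(m)
  }
  nb
}
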