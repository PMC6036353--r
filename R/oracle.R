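# Analytic aperture-fluence references for end-to-end checks.
#
# For a point source, an ideal absorbing collimator and a kerma-level
# water phantom, the expected dose per source history at a voxel center is
# a closed form: the in-cone fluence 1 / (Omega r^2) times the rectangular
# aperture coverage of the voxel footprint, attenuated along the water
# path, times E * mu_en/rho summed over spectrum bins. This integrates the
# same physics the simulation samples, but directly -- no phase space, no
# collimator ray-trace, no voxel walk -- so it serves as an independent
# reference for the full pipeline on open fields.

#' Analytic open-field dose for a point source and absorbing jaws
#'
#' @param phantom a [voxel_phantom()] (uniform water assumed for the
#'   attenuation path; densities are read for the path integral but the
#'   phantom is expected to be the water cube).
#' @param jaws numeric (X1, X2, Y1, Y2), cm at isocenter.
#' @param spectrum data.frame (`energy_MeV`, `probability`).
#' @param atten an [attenuation_model()].
#' @param cone_half_angle source cone half-angle, radians (sets the
#'   solid-angle normalization Omega of one history).
#' @param sad source-to-axis distance, cm.
#' @param focal_spot_sigma Gaussian focal-spot spread (cm) of the source at
#'   the target plane. A finite spot blurs the geometric field edge: a
#'   source point offset by x0 shifts the projected edge at depth z by
#'   `x0 (1 - z / z_top)`, so the edge indicator is convolved with a
#'   Gaussian of width `sigma |z / z_top - 1|` before the voxel-footprint
#'   integration (closed form, per jaw pair).
#' @param geom a [collimator_geometry()] supplying the per-axis jaw plane
#'   heights for the penumbra width (defaults to the standard fixture).
#' @return a [dose_grid()] in Gy per source history (zero variance).
#' @export
analytic_aperture_dose <- function(phantom, jaws, spectrum,
                                   atten = attenuation_model(),
                                   cone_half_angle = 0.25, sad = 100,
                                   focal_spot_sigma = 0,
                                   geom = collimator_geometry()) {
  d <- phantom$dims
  vs <- phantom$voxel_size
  xc <- phantom$origin[1] + (seq_len(d[1]) - 0.5) * vs[1]
  yc <- phantom$origin[2] + (seq_len(d[2]) - 0.5) * vs[2]
  zc <- phantom$origin[3] + (seq_len(d[3]) - 0.5) * vs[3]
  omega <- 2 * pi * (1 - cos(cone_half_angle))
  z_top <- c(X = NA_real_, Y = NA_real_)
  for (p in geom$jaw_pairs) z_top[[p$axis]] <- p$z_top

  # mean coverage of a voxel footprint [c-h, c+h] by the projected field
  # interval whose edges are blurred by a Gaussian of width sig
  # (integral of Phi has the closed form G(x) = x Phi(x) + phi(x))
  cover <- function(centers, half, lo_iso, hi_iso, z, sig) {
    lo <- lo_iso * z / sad
    hi <- hi_iso * z / sad
    if (sig < 1e-9) {
      return(pmax(0, pmin(centers + half, hi) - pmax(centers - half, lo)) /
               (2 * half))
    }
    G <- function(x) x * stats::pnorm(x) + stats::dnorm(x)
    a <- centers - half
    b <- centers + half
    f <- (sig / (2 * half)) *
      ((G((hi - a) / sig) - G((hi - b) / sig)) -
         (G((lo - a) / sig) - G((lo - b) / sig)))
    pmin(pmax(f, 0), 1) # clamp floating cancellation at the tails
  }

  dose <- array(0, dim = d)
  probs <- spectrum$probability / sum(spectrum$probability)
  mu <- atten$mu_rho(spectrum$energy_MeV)
  muen <- atten$muen_rho(spectrum$energy_MeV)
  e <- spectrum$energy_MeV
  for (k in seq_len(d[3])) {
    z <- zc[k]
    sig_x <- if (focal_spot_sigma > 0) {
      focal_spot_sigma * abs(z / z_top[["X"]] - 1)
    } else 0
    sig_y <- if (focal_spot_sigma > 0) {
      focal_spot_sigma * abs(z / z_top[["Y"]] - 1)
    } else 0
    fx <- cover(xc, vs[1] / 2, jaws[1], jaws[2], z, sig_x)
    fy <- cover(yc, vs[2] / 2, jaws[3], jaws[4], z, sig_y)
    covxy <- outer(fx, fy)
    r2 <- outer(xc^2, yc^2, `+`) + z^2
    r <- sqrt(r2)
    wpath <- pmax(0, r * (1 - phantom$ssd / z)) # water depth along the ray
    plane <- matrix(0, d[1], d[2])
    for (b in seq_along(e)) {
      plane <- plane + probs[b] * e[b] * muen[b] * exp(-mu[b] * wpath)
    }
    dose[, , k] <- MEV_PER_G_TO_GY * plane * covxy / (omega * r2)
  }
  dose_grid(dose, array(0, dim = d), phantom, n_histories_equivalent = 1)
}

#' Bin a phase space into a 2D fluence map at a plane
#'
#' Particles are projected in vacuum to `z_plane` and their weights binned
#' on a regular lateral grid.
#'
#' @param store a `phsp_store` with downward particles.
#' @param z_plane projection plane, cm.
#' @param xlim,ylim lateral extents, cm.
#' @param nbins bins per axis (scalar or length 2).
#' @return list: `counts` (matrix, weight-summed), `x_centers`,
#'   `y_centers`, `bin_width`.
#' @export
fluence_map <- function(store, z_plane, xlim = c(-10, 10), ylim = c(-10, 10),
                        nbins = 80) {
  nbins <- rep(as.integer(nbins), length.out = 2)
  t <- (z_plane - store$z) / store$w
  x <- store$x + store$u * t
  y <- store$y + store$v * t
  bw <- c(diff(xlim) / nbins[1], diff(ylim) / nbins[2])
  ix <- floor((x - xlim[1]) / bw[1]) + 1
  iy <- floor((y - ylim[1]) / bw[2]) + 1
  ok <- ix >= 1 & ix <= nbins[1] & iy >= 1 & iy <= nbins[2]
  counts <- matrix(0, nbins[1], nbins[2])
  tab <- tapply(store$weight[ok], list(factor(ix[ok], levels = 1:nbins[1]),
                                       factor(iy[ok], levels = 1:nbins[2])),
                sum)
  tab[is.na(tab)] <- 0
  counts[] <- tab
  list(counts = counts,
       x_centers = xlim[1] + (seq_len(nbins[1]) - 0.5) * bw[1],
       y_centers = ylim[1] + (seq_len(nbins[2]) - 0.5) * bw[2],
       bin_width = bw)
}

#' Locate the 50% edges of a 1D fluence profile
#'
#' The plateau level is the mean over the central half of the profile's
#' support; the two 50% crossings are found by linear interpolation
#' between bin centers.
#'
#' @param centers bin-center coordinates.
#' @param profile fluence values.
#' @return numeric (left, right) edge positions.
#' @export
edge_50 <- function(centers, profile) {
  peak_idx <- which(profile > 0.5 * max(profile))
  core <- seq(quantile(peak_idx, 0.25), quantile(peak_idx, 0.75))
  plateau <- mean(profile[round(core)])
  half <- plateau / 2
  above <- profile >= half
  i_left <- which(above)[1]
  i_right <- rev(which(above))[1]
  interp_cross <- function(i0, i1) {
    if (i0 < 1 || i1 > length(profile) || profile[i1] == profile[i0]) {
      return(centers[max(min(i1, length(centers)), 1)])
    }
    centers[i0] + (half - profile[i0]) / (profile[i1] - profile[i0]) *
      (centers[i1] - centers[i0])
  }
  c(left = interp_cross(i_left - 1, i_left),
    right = interp_cross(i_right, i_right + 1))
}
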