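# Voxel dose calculation: the kerma ray-trace engine, per-voxel statistical
# uncertainty, required-history estimation, and dose summation.
#
# The engine is deliberately kerma-level: photon energy fluence attenuates
# along the exact voxel traversal and deposits collision kerma locally; no
# secondary electron transport, no scatter dose. This is the documented
# accuracy envelope -- the package's claims concern collimation, not
# transport physics.

#' Construct a dose grid
#'
#' @param dose 3D array, Gy per primary-history-equivalent.
#' @param variance 3D array, variance of the per-voxel mean dose.
#' @param phantom the [voxel_phantom()] the grid lives on.
#' @param n_histories_equivalent normalization denominator.
#' @param n_missed particles that never touched the phantom.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(dose, variance, phantom, n_histories_equivalent,
                      n_missed = 0) {
  stopifnot(all(dose >= 0), all(variance >= 0))
  structure(list(dose = dose, variance = variance,
                 dims = phantom$dims, voxel_size = phantom$voxel_size,
                 origin = phantom$origin,
                 n_histories_equivalent = n_histories_equivalent,
                 n_missed = n_missed),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Dose grid:", paste(x$dims, collapse = " x "), "voxels\n")
  cat("  max dose:", format(max(x$dose), digits = 6),
      "Gy/history-equivalent\n")
  cat("  histories equivalent:", format(x$n_histories_equivalent), "\n")
  if (max(x$dose) > 0) {
    hot <- x$dose > 0.5 * max(x$dose)
    rel <- sqrt(x$variance[hot]) / x$dose[hot]
    cat("  median rel. sigma (>50% voxels):",
        format(100 * median(rel), digits = 3), "%\n")
  }
  invisible(x)
}

# Rotate machine-frame coordinates into the phantom frame for a gantry
# angle (degrees): rotation about the couch (y) axis through the isocenter.
rotate_gantry <- function(x, y, z, u, v, w, gantry_deg, sad) {
  g <- -gantry_deg * pi / 180
  cg <- cos(g); sg <- sin(g)
  zc <- z - sad
  list(x = cg * x + sg * zc, y = y, z = -sg * x + cg * zc + sad,
       u = cg * u + sg * w, v = v, w = -sg * u + cg * w)
}

#' Deposit a phase space into a voxel phantom
#'
#' Particles are rotated by the gantry angle about the isocenter into the
#' phantom frame, ray-traced through the voxel grid with the exact
#' grid-crossing walk, and deposit kerma along their path; dose is
#' normalized by voxel mass and by the store's history-equivalent count.
#' Variance is accumulated history by history (recycled copies of one
#' source particle share a history).
#'
#' @param phsp a [phsp_store()]; a `gantry_deg` column (written by
#'   [collimate_dynamic()]) is honored per particle when `gantry_deg` is
#'   `NULL`.
#' @param phantom a [voxel_phantom()].
#' @param atten an [attenuation_model()].
#' @param gantry_deg gantry angle in degrees (scalar), or `NULL` to use the
#'   store's per-particle annotation (0 if absent).
#' @param sad source-to-axis distance, cm (rotation center at (0, 0, sad)).
#' @return a [dose_grid()] in Gy per primary-history-equivalent.
#' @export
deposit <- function(phsp, phantom, atten, gantry_deg = NULL, sad = 100) {
  n <- nrow(phsp)
  if (!n) stop("empty phase space")
  g <- if (!is.null(gantry_deg)) {
    rep(as.numeric(gantry_deg), n)
  } else if (!is.null(phsp$gantry_deg)) {
    phsp$gantry_deg
  } else {
    rep(0, n)
  }
  if (all(g == 0)) {
    rc <- list(x = phsp$x, y = phsp$y, z = phsp$z,
               u = phsp$u, v = phsp$v, w = phsp$w)
  } else {
    rc <- rotate_gantry(phsp$x, phsp$y, phsp$z, phsp$u, phsp$v, phsp$w,
                        g, sad)
  }
  hist <- cumsum(phsp$new_history)
  if (hist[1] == 0) hist <- hist + 1L
  mu <- atten$mu_rho(phsp$energy)
  muen <- atten$muen_rho(phsp$energy)
  res <- deposit_cpp(rc$x, rc$y, rc$z, rc$u, rc$v, rc$w,
                     phsp$energy, phsp$weight, as.integer(phsp$kind),
                     as.integer(hist), mu, muen,
                     phantom$dims, phantom$voxel_size, phantom$origin,
                     as.numeric(phantom$density))
  N <- attr(phsp, "n_original_histories")
  if (is.null(N) || !is.finite(N) || N <= 0) N <- n
  conv <- MEV_PER_G_TO_GY
  s <- array(res$sum, dim = phantom$dims)
  s2 <- array(res$sum2, dim = phantom$dims)
  dose <- conv * s / N
  variance <- if (N > 1) {
    array(pmax(0, conv^2 * (s2 - s^2 / N) / (N * (N - 1))),
          dim = phantom$dims)
  } else {
    array(0, dim = phantom$dims)
  }
  dose_grid(dose, variance, phantom, N, n_missed = res$n_missed)
}

#' Radiological path through a phantom
#'
#' Integral of density along a ray, using the same exact voxel traversal as
#' the dose engine.
#'
#' @param phantom a [voxel_phantom()].
#' @param origin ray origin (cm, length 3).
#' @param direction ray direction (need not be normalized).
#' @return path integral in g/cm^2.
#' @export
radiological_path <- function(phantom, origin, direction) {
  rad_path_cpp(as.numeric(origin), as.numeric(direction), phantom$dims,
               phantom$voxel_size, phantom$origin,
               as.numeric(phantom$density))
}

#' Estimate histories needed for a target uncertainty
#'
#' Scales the pilot run's median relative sigma (over voxels above
#' `threshold_frac` of the maximum dose) by the inverse-square-root law.
#'
#' @param pilot a [dose_grid()] from a pilot run.
#' @param target_rel_sigma target relative sigma (fraction, e.g. 0.01).
#' @param threshold_frac dose threshold as a fraction of the maximum
#'   (default 0.1: the conventional "voxels above 10% of the maximum").
#' @return recommended history count.
#' @export
estimate_required_histories <- function(pilot, target_rel_sigma,
                                        threshold_frac = 0.1) {
  dmax <- max(pilot$dose)
  if (dmax <= 0) stop("pilot dose grid is all zero")
  sel <- pilot$dose > threshold_frac * dmax
  rel <- sqrt(pilot$variance[sel]) / pilot$dose[sel]
  med <- median(rel)
  pilot$n_histories_equivalent * (med / target_rel_sigma)^2
}

#' Sum dose grids
#'
#' Weighted voxelwise sum; variances combine assuming independent runs.
#' `weights = "histories"` pools grids by their history-equivalent counts
#' (the parallel-splitting contract: partitioned runs recombine to exactly
#' the single-run grid); a numeric vector applies, e.g., per-field MU
#' weights.
#'
#' @param grids list of [dose_grid()]s on identical lattices.
#' @param weights numeric vector, or `"histories"`.
#' @return a [dose_grid()].
#' @export
sum_dose <- function(grids, weights = 1) {
  stopifnot(length(grids) >= 1)
  d0 <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(g$dims, d0$dims)) stop("dose grid shape mismatch")
  }
  ns <- vapply(grids, `[[`, numeric(1), "n_histories_equivalent")
  if (identical(weights, "histories")) {
    w <- ns / sum(ns)
    n_out <- sum(ns)
  } else {
    w <- rep(weights, length.out = length(grids))
    n_out <- sum(w * ns)
  }
  dose <- array(0, dim = d0$dims)
  variance <- array(0, dim = d0$dims)
  miss <- 0
  for (i in seq_along(grids)) {
    dose <- dose + w[i] * grids[[i]]$dose
    variance <- variance + w[i]^2 * grids[[i]]$variance
    miss <- miss + grids[[i]]$n_missed
  }
  structure(list(dose = dose, variance = variance, dims = d0$dims,
                 voxel_size = d0$voxel_size, origin = d0$origin,
                 n_histories_equivalent = n_out, n_missed = miss),
            class = "dose_grid")
}

#' Write a dose grid as a plain-text dump plus JSON metadata
#'
#' One value per line in column-major order -- a diffable export.
#'
#' @param grid a [dose_grid()].
#' @param path base path; writes `<path>.dose.txt` and `<path>.json`.
#' @return invisibly, the text path.
#' @export
write_dose_text <- function(grid, path) {
  meta <- list(format = "fajtrace-dose-v1", dims = grid$dims,
               voxel_size = grid$voxel_size, origin = grid$origin,
               n_histories_equivalent = grid$n_histories_equivalent)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  txt <- paste0(path, ".dose.txt")
  writeLines(format(as.vector(grid$dose), digits = 10, trim = TRUE,
                    scientific = TRUE), txt)
  invisible(txt)
}
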