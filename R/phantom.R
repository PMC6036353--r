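# Voxel phantoms. Machine frame at gantry 0: beam axis +z from the target
# at z = 0, isocenter on the axis at z = SAD; the couch (patient) axis is y.

#' Construct a voxel phantom
#'
#' @param dims integer (nx, ny, nz) voxel counts.
#' @param voxel_size numeric voxel edge lengths in cm (scalar or length 3).
#' @param origin corner of the grid (minimum x, y, z) in the machine frame
#'   at gantry 0, cm.
#' @param density 3D array of mass densities, g/cm^3 (defaults to water).
#' @param ssd source-to-surface distance: z of the upstream phantom face.
#' @return an object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(dims, voxel_size, origin, density = NULL,
                          ssd = origin[3]) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (is.null(density)) density <- array(1, dim = dims)
  stopifnot(all(dim(density) == dims), all(density >= 0))
  structure(list(dims = dims, voxel_size = voxel_size,
                 origin = as.numeric(origin), density = density,
                 ssd = as.numeric(ssd)),
            class = "voxel_phantom")
}

#' Make a cubic water phantom
#'
#' Uniform unit-density cube, laterally centered on the beam axis, surface
#' plane at `z = ssd`.
#'
#' @param n voxels per axis.
#' @param voxel voxel edge length, cm.
#' @param ssd source-to-surface distance, cm.
#' @return a [voxel_phantom()].
#' @export
make_water_cube <- function(n = 82, voxel = 0.5, ssd = 90) {
  stopifnot(n >= 1)
  half <- n * voxel / 2
  voxel_phantom(dims = c(n, n, n), voxel_size = voxel,
                origin = c(-half, -half, ssd), ssd = ssd)
}

#' Make a cylindrical water phantom
#'
#' A water cylinder with its axis along the couch (y) axis, centered on
#' the isocenter; voxels outside the cylinder hold air density.
#'
#' @param diameter cylinder diameter, cm.
#' @param length cylinder length along the couch axis, cm.
#' @param voxel voxel edge length, cm.
#' @param sad isocenter distance (cylinder center), cm.
#' @param air_density density outside the cylinder, g/cm^3.
#' @return a [voxel_phantom()].
#' @export
make_water_cylinder <- function(diameter = 20.4, length = 20.4,
                                voxel = 0.25, sad = 100,
                                air_density = 0.0012) {
  stopifnot(diameter > 0)
  r <- diameter / 2
  nx <- nz <- ceiling(diameter / voxel)
  ny <- ceiling(length / voxel)
  origin <- c(-nx * voxel / 2, -ny * voxel / 2, sad - nz * voxel / 2)
  xc <- origin[1] + (seq_len(nx) - 0.5) * voxel
  zc <- origin[3] + (seq_len(nz) - 0.5) * voxel
  in_cyl <- outer(xc^2, (zc - sad)^2, `+`) <= r^2 # nx x nz mask
  density <- array(air_density, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    density[, , k][in_cyl[, k], ] <- 1
  }
  voxel_phantom(dims = c(nx, ny, nz), voxel_size = voxel, origin = origin,
                density = density, ssd = sad - r)
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("Voxel phantom:", paste(x$dims, collapse = " x "), "voxels,",
      paste(format(x$voxel_size), collapse = " x "), "cm\n")
  cat("  origin (cm):", paste(format(x$origin), collapse = ", "),
      "| SSD:", x$ssd, "cm\n")
  cat("  density range:", paste(format(range(x$density)), collapse = " .. "),
      "g/cm^3\n")
  invisible(x)
}
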