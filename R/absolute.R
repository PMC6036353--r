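# Absolute dose conversion: from relative Monte Carlo dose (Gy per initial
# history) to Gy, using the clinic-style calibration chain
#
#   D' = Do * TMR(dref, 10x10) * Dcal(dmax, 10x10) / DMC(dref, 10x10)
#             * MU * Sb
#
# where Sb corrects for radiation backscattered from the secondary
# collimators into the monitor chamber -- an effect a collimator model
# without jaw scatter cannot simulate, hence the measurement-style lookup
# table indexed by jaw opening.

#' Load a tissue-maximum-ratio table
#'
#' @param path CSV: first column `depth_cm`, remaining columns named
#'   `S<side>` for equivalent-square side lengths (e.g. `S10`); defaults to
#'   the packaged fixture table.
#' @return an object of class `tmr_table`.
#' @export
read_tmr <- function(path = system.file("extdata", "tmr_table.csv",
                                        package = "fajtrace")) {
  tab <- read.csv(path, check.names = FALSE)
  depths <- tab[[1]]
  squares <- as.numeric(sub("^S", "", names(tab)[-1]))
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (any(values <= 0) || any(values > 1.2)) {
    stop("TMR values must lie in (0, 1.2]")
  }
  structure(list(depths = depths, squares = squares, values = values),
            class = "tmr_table")
}

bilinear <- function(xs, ys, grid, x, y, clamp_warn = NULL) {
  clamp <- function(v, lim) pmin(pmax(v, lim[1]), lim[2])
  if (!is.null(clamp_warn) &&
      (x < min(xs) || x > max(xs) || y < min(ys) || y > max(ys))) {
    warning(clamp_warn, call. = FALSE)
  }
  x <- clamp(x, range(xs)); y <- clamp(y, range(ys))
  i <- findInterval(x, xs, rightmost.closed = TRUE, all.inside = TRUE)
  j <- findInterval(y, ys, rightmost.closed = TRUE, all.inside = TRUE)
  fx <- (x - xs[i]) / (xs[i + 1] - xs[i])
  fy <- (y - ys[j]) / (ys[j + 1] - ys[j])
  unname((1 - fx) * (1 - fy) * grid[i, j] + fx * (1 - fy) * grid[i + 1, j] +
           (1 - fx) * fy * grid[i, j + 1] + fx * fy * grid[i + 1, j + 1])
}

#' Look up a TMR value
#'
#' Bilinear interpolation in depth and equivalent-square side.
#'
#' @param table a [read_tmr()] table.
#' @param depth depth in cm.
#' @param square equivalent-square side in cm.
#' @return the TMR value.
#' @export
tmr_lookup <- function(table, depth, square) {
  bilinear(table$depths, table$squares, table$values, depth, square)
}

#' Load a monitor-backscatter (Sb) lookup table
#'
#' The packaged fixture is a smooth synthetic surface close to 1
#' (larger openings backscatter less into the monitor chamber), normalized
#' so Sb(10, 10) = 1; measured tables are supplied in the same CSV layout.
#'
#' @param path CSV: first column `X` (X field sizes, cm), remaining columns
#'   named `Y<size>`.
#' @return an object of class `sb_table`.
#' @export
read_sb <- function(path = system.file("extdata", "sb_table.csv",
                                       package = "fajtrace")) {
  tab <- read.csv(path, check.names = FALSE)
  x_sizes <- tab[[1]]
  y_sizes <- as.numeric(sub("^Y", "", names(tab)[-1]))
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (any(values <= 0)) stop("Sb values must be positive")
  structure(list(x_sizes = x_sizes, y_sizes = y_sizes, values = values),
            class = "sb_table")
}

#' Monitor-backscatter factor for a static jaw opening
#'
#' Bilinear interpolation on the (X size, Y size) grid; queries outside the
#' table hull are clamped with a warning.
#'
#' @param table a [read_sb()] table.
#' @param x_size,y_size jaw opening at isocenter, cm (> 0).
#' @return the Sb factor.
#' @export
sb_lookup <- function(table, x_size, y_size) {
  if (x_size <= 0 || y_size <= 0) stop("field sizes must be positive")
  bilinear(table$x_sizes, table$y_sizes, table$values, x_size, y_size,
           clamp_warn = "Sb query outside table hull; clamped to edge")
}

jaw_sizes_at <- function(beam, mu) {
  st <- delivery_state(beam, mu)
  c(x = unname(st$jaws[, 2] - st$jaws[, 1]),
    y = unname(st$jaws[, 4] - st$jaws[, 3]))
}

#' MU-weighted monitor-backscatter factor for a dynamic field
#'
#' One Sb per control-point segment (jaw opening at the segment midpoint,
#' consistent with linear-in-MU interpolation; `mode = "node"` uses the
#' segment's starting control point instead), weighted by the segment's
#' share of the delivered MU.
#'
#' @param beam a dynamic [beam()] (>= 2 control points).
#' @param table a [read_sb()] table.
#' @param mode `"midpoint"` (default) or `"node"`.
#' @return the weighted Sb factor.
#' @export
sb_weighted_imrt <- function(beam, table, mode = c("midpoint", "node")) {
  mode <- match.arg(mode)
  if (beam$n_cp < 2) stop("need at least 2 control points")
  dmu <- diff(beam$mu_cum)
  if (sum(dmu) <= 0) stop("zero total MU across control points")
  mus <- if (mode == "midpoint") {
    (beam$mu_cum[-1] + beam$mu_cum[-beam$n_cp]) / 2
  } else {
    beam$mu_cum[-beam$n_cp]
  }
  sbs <- vapply(mus, function(m) {
    sz <- jaw_sizes_at(beam, m)
    sb_lookup(table, sz[["x"]], sz[["y"]])
  }, numeric(1))
  sum(dmu * sbs) / sum(dmu)
}

#' Per-sub-field monitor-backscatter factors for a VMAT arc
#'
#' One Sb per sub-field (from [split_vmat_subfields()]), each via its own
#' narrow MU-weighted aperture; applied separately when converting each
#' sub-field to absolute dose.
#'
#' @param subfields list of sub-[beam()]s.
#' @param table a [read_sb()] table.
#' @return numeric vector of Sb factors.
#' @export
sb_per_subfield <- function(subfields, table) {
  vapply(subfields, function(b) sb_weighted_imrt(b, table), numeric(1))
}

#' Calibration configuration for absolute dose
#'
#' Calibration in SAD conditions: 10 x 10 cm^2 field, 90 cm SSD in water,
#' reference depth 10 cm; `dcal` is the calibration dose per MU at dmax and
#' `dmc_ref` the Monte Carlo dose per history-equivalent at the reference
#' point of the 10 x 10 reference simulation.
#'
#' @param dcal calibration dose at dmax for 10x10, Gy/MU.
#' @param dref reference depth, cm.
#' @param dmc_ref reference-simulation dose at dref, Gy per
#'   history-equivalent (> 0).
#' @param tmr_table a [read_tmr()] table.
#' @return an object of class `calibration_config`.
#' @export
calibration_config <- function(dcal = 0.01, dref = 10, dmc_ref,
                               tmr_table = read_tmr()) {
  if (dcal <= 0) stop("dcal must be positive")
  if (missing(dmc_ref) || dmc_ref <= 0) stop("dmc_ref must be positive")
  structure(list(dcal = dcal, dref = dref, dmc_ref = dmc_ref,
                 tmr_table = tmr_table),
            class = "calibration_config")
}

#' Load a calibration configuration from JSON
#'
#' @param path JSON with `dcal`, `dref`, `dmc_ref`, and optional
#'   `tmr_csv` / `sb_csv` paths (resolved relative to the config file).
#' @return `list(calib = calibration_config, sb = sb_table)`.
#' @export
read_calibration <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p, default) {
    if (is.null(p)) return(default)
    if (file.exists(p)) p else file.path(base, p)
  }
  tmr <- read_tmr(resolve(cfg$tmr_csv,
                          system.file("extdata", "tmr_table.csv",
                                      package = "fajtrace")))
  sb <- read_sb(resolve(cfg$sb_csv,
                        system.file("extdata", "sb_table.csv",
                                    package = "fajtrace")))
  list(calib = calibration_config(cfg$dcal, cfg$dref, cfg$dmc_ref, tmr),
       sb = sb)
}

#' Convert a relative dose grid to absolute dose in Gy
#'
#' Applies the calibration chain voxelwise; the variance scales by the
#' square of the constant, so relative uncertainties are untouched. Linear
#' in the input dose, in MU, and in Sb.
#'
#' @param do a [dose_grid()] in Gy per history-equivalent.
#' @param calib a [calibration_config()].
#' @param mu delivered monitor units (> 0).
#' @param sb monitor-backscatter factor (see [sb_lookup()],
#'   [sb_weighted_imrt()], [sb_per_subfield()]).
#' @return a [dose_grid()] in Gy.
#' @export
to_gray <- function(do, calib, mu, sb = 1) {
  if (mu <= 0) stop("MU must be positive")
  if (calib$dmc_ref <= 0) stop("dmc_ref must be positive")
  tmr <- tmr_lookup(calib$tmr_table, calib$dref, 10)
  k <- tmr * calib$dcal / calib$dmc_ref * mu * sb
  out <- do
  out$dose <- do$dose * k
  out$variance <- do$variance * k^2
  out
}
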