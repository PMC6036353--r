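# Treatment-plan model: cumulative-MU-indexed control points, aperture
# interpolation, delivery sampling, VMAT sub-field splitting and IMRT
# parallel splitting.
#
# Conventions follow DICOM RT Plan: jaw and MLC positions are stored
# projected to the isocenter plane; leaves travel along X, leaf boundaries
# partition Y. Conversion to physical collimator-plane coordinates happens
# only inside the collimation module.

#' Construct a control point
#'
#' @param index ordinal position within the beam (1-based).
#' @param mu_cum cumulative fractional monitor units in \[0, 1\].
#' @param jaws numeric (X1, X2, Y1, Y2), cm projected to isocenter.
#' @param mlc `NULL`, or `list(boundaries, bankA, bankB)`: `boundaries` are
#'   the `n_leaf + 1` leaf-edge positions on the Y axis, `bankA`/`bankB`
#'   the left/right leaf-tip X positions, all cm at isocenter.
#' @param gantry_deg gantry angle in degrees.
#' @return a `control_point` list.
#' @export
control_point <- function(index, mu_cum, jaws, mlc = NULL, gantry_deg = 0) {
  structure(list(index = index, mu_cum = mu_cum,
                 jaws = as.numeric(jaws), mlc = mlc,
                 gantry_deg = gantry_deg),
            class = "control_point")
}

#' Construct a beam from control points
#'
#' Raw cumulative metersets are normalized by their final value so that
#' `mu_cum` runs from 0 to 1. All control-point invariants are checked:
#' X1 < X2, Y1 < Y2, non-decreasing meterset, bankA <= bankB per leaf pair.
#'
#' @param control_points list of [control_point()]s (their `mu_cum` may be
#'   raw metersets).
#' @param total_mu absolute monitor units delivered by the beam.
#' @param modality one of `"static"`, `"imrt_dynamic"`, `"vmat_arc"`.
#' @param jaw_tracking do the jaws follow the MLC aperture dynamically? If
#'   `FALSE`, collimation holds the jaws at the widest opening the beam
#'   reaches.
#' @param interp aperture interpolation between control points:
#'   `"linear"` in cumulative MU (dynamic-delivery semantics, the default)
#'   or `"nearest"` (snap to the closer control point).
#' @return an object of class `fajt_beam`.
#' @export
beam <- function(control_points, total_mu, modality = "static",
                 jaw_tracking = FALSE, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  modality <- match.arg(modality, c("static", "imrt_dynamic", "vmat_arc"))
  ncp <- length(control_points)
  if (modality != "static" && ncp < 2) {
    stop("dynamic modalities need at least 2 control points")
  }
  if (ncp < 1) stop("a beam needs at least one control point")
  mu_raw <- vapply(control_points, `[[`, numeric(1), "mu_cum")
  if (any(diff(mu_raw) < 0)) {
    bad <- which(diff(mu_raw) < 0)[1] + 1L
    stop("non-monotone cumulative meterset at control point ", bad)
  }
  mu <- if (ncp == 1) 0 else {
    if (mu_raw[ncp] <= 0) stop("final cumulative meterset must be positive")
    (mu_raw - mu_raw[1]) / (mu_raw[ncp] - mu_raw[1])
  }
  jaws <- t(vapply(control_points, `[[`, numeric(4), "jaws"))
  colnames(jaws) <- c("X1", "X2", "Y1", "Y2")
  for (i in seq_len(ncp)) {
    if (jaws[i, 1] >= jaws[i, 2] || jaws[i, 3] >= jaws[i, 4]) {
      stop("invalid jaw opening at control point ", i,
           " (need X1 < X2 and Y1 < Y2)")
    }
  }
  gantry <- vapply(control_points, `[[`, numeric(1), "gantry_deg")
  mlc0 <- control_points[[1]]$mlc
  boundaries <- bankA <- bankB <- NULL
  if (!is.null(mlc0)) {
    boundaries <- as.numeric(mlc0$boundaries)
    if (is.unsorted(boundaries, strictly = TRUE)) {
      stop("MLC leaf boundaries must be strictly increasing")
    }
    n_leaf <- length(boundaries) - 1L
    bankA <- matrix(NA_real_, ncp, n_leaf)
    bankB <- matrix(NA_real_, ncp, n_leaf)
    for (i in seq_len(ncp)) {
      m <- control_points[[i]]$mlc
      if (is.null(m) || length(m$bankA) != n_leaf ||
          length(m$bankB) != n_leaf) {
        stop("control point ", i, " has inconsistent MLC banks")
      }
      if (any(m$bankA > m$bankB)) {
        leaf <- which(m$bankA > m$bankB)[1]
        stop("overlapping leaf pair ", leaf, " at control point ", i)
      }
      bankA[i, ] <- m$bankA
      bankB[i, ] <- m$bankB
    }
  }
  structure(list(modality = modality, total_mu = total_mu,
                 jaw_tracking = isTRUE(jaw_tracking), interp = interp,
                 n_cp = ncp, mu_cum = mu, mu_cum_raw = mu_raw,
                 jaws = jaws, gantry = gantry,
                 mlc_boundaries = boundaries, bankA = bankA, bankB = bankB),
            class = "fajt_beam")
}

#' @export
print.fajt_beam <- function(x, ...) {
  cat("Beam:", x$modality, "|", x$n_cp, "control points |",
      x$total_mu, "MU | jaw tracking:", x$jaw_tracking, "\n")
  cat("  jaws at CP1 [cm at iso]:",
      paste(colnames(x$jaws), format(x$jaws[1, ]), sep = "=",
            collapse = " "), "\n")
  if (!is.null(x$mlc_boundaries)) {
    cat("  MLC:", ncol(x$bankA), "leaf pairs\n")
  }
  invisible(x)
}

#' Load a treatment plan from the JSON plan dialect
#'
#' @param path JSON file: `{"beams": [{"modality", "total_mu",
#'   "jaw_tracking", "control_points": [{"mu_cum_raw", "jaws":
#'   {"X1","X2","Y1","Y2"}, "mlc": {"boundaries","bankA","bankB"},
#'   "gantry_deg"}, ...]}, ...]}`.
#' @return a `fajt_plan`: list of [beam()]s.
#' @export
load_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$beams)) stop("plan file has no 'beams' array")
  beams <- lapply(raw$beams, function(b) {
    cps <- lapply(seq_along(b$control_points), function(i) {
      cp <- b$control_points[[i]]
      j <- cp$jaws
      mlc <- if (!is.null(cp$mlc)) {
        list(boundaries = as.numeric(unlist(cp$mlc$boundaries)),
             bankA = as.numeric(unlist(cp$mlc$bankA)),
             bankB = as.numeric(unlist(cp$mlc$bankB)))
      }
      control_point(i, cp$mu_cum_raw,
                    c(j$X1, j$X2, j$Y1, j$Y2), mlc,
                    if (is.null(cp$gantry_deg)) 0 else cp$gantry_deg)
    })
    beam(cps, total_mu = b$total_mu,
         modality = if (is.null(b$modality)) "static" else b$modality,
         jaw_tracking = isTRUE(b$jaw_tracking),
         interp = if (is.null(b$interp)) "linear" else b$interp)
  })
  structure(list(beams = beams), class = "fajt_plan")
}

#' Save a plan in the JSON plan dialect
#'
#' @param plan a `fajt_plan` or list of [beam()]s.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
save_plan <- function(plan, path) {
  beams <- if (inherits(plan, "fajt_plan")) plan$beams else plan
  out <- list(beams = lapply(beams, function(b) {
    cps <- lapply(seq_len(b$n_cp), function(i) {
      cp <- list(
        mu_cum_raw = b$mu_cum_raw[i],
        jaws = as.list(setNames(b$jaws[i, ], colnames(b$jaws))),
        gantry_deg = b$gantry[i]
      )
      if (!is.null(b$mlc_boundaries)) {
        cp$mlc <- list(boundaries = b$mlc_boundaries,
                       bankA = b$bankA[i, ], bankB = b$bankB[i, ])
      }
      cp
    })
    list(modality = b$modality, total_mu = b$total_mu,
         jaw_tracking = b$jaw_tracking, interp = b$interp,
         control_points = cps)
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Vectorized delivery state: for fractional MU values `mu` return the
# enclosing segment, within-segment fraction, interpolated jaws (n x 4) and
# gantry angles. MLC banks are interpolated lazily per leaf (see
# mlc_banks_at) because the collimator only needs the leaf each particle
# crosses.
delivery_state <- function(beam, mu) {
  ncp <- beam$n_cp
  seg <- findInterval(mu, beam$mu_cum, rightmost.closed = TRUE,
                      all.inside = TRUE)
  dmu <- beam$mu_cum[seg + 1L] - beam$mu_cum[seg]
  frac <- ifelse(dmu > 0, (mu - beam$mu_cum[seg]) / dmu, 0)
  if (beam$interp == "nearest") frac <- round(frac)
  jaws <- beam$jaws[seg, , drop = FALSE] +
    frac * (beam$jaws[seg + 1L, , drop = FALSE] -
              beam$jaws[seg, , drop = FALSE])
  gantry <- beam$gantry[seg] + frac * (beam$gantry[seg + 1L] -
                                         beam$gantry[seg])
  list(mu_frac = mu, segment = seg, frac = frac, jaws = jaws,
       gantry = gantry)
}

# Interpolated bank positions for specified (sample, leaf) pairs.
mlc_banks_at <- function(beam, seg, frac, leaf) {
  iA0 <- cbind(seg, leaf)
  iA1 <- cbind(seg + 1L, leaf)
  a <- beam$bankA[iA0] + frac * (beam$bankA[iA1] - beam$bankA[iA0])
  b <- beam$bankB[iA0] + frac * (beam$bankB[iA1] - beam$bankB[iA0])
  list(a = a, b = b)
}

#' Sample the delivery state of a dynamic beam
#'
#' Maps a uniform draw on \[0, 1) to a fractional MU, locates the
#' enclosing control-point pair, and interpolates jaws, MLC banks, and
#' gantry angle (linearly in cumulative MU by default).
#'
#' @param beam a dynamic [beam()] (>= 2 control points).
#' @param rng_draw a uniform draw in \[0, 1); `mu_frac = rng_draw`.
#' @return a `delivery_sample`: `mu_frac`, `segment`, `jaws_t`, `mlc_t`
#'   (full interpolated banks, or `NULL`), `gantry_t`.
#' @export
sample_delivery <- function(beam, rng_draw) {
  stopifnot(beam$n_cp >= 2, rng_draw >= 0, rng_draw <= 1)
  st <- delivery_state(beam, rng_draw)
  mlc_t <- NULL
  if (!is.null(beam$mlc_boundaries)) {
    n_leaf <- ncol(beam$bankA)
    banks <- mlc_banks_at(beam, rep(st$segment, n_leaf),
                          rep(st$frac, n_leaf), seq_len(n_leaf))
    mlc_t <- list(boundaries = beam$mlc_boundaries,
                  bankA = banks$a, bankB = banks$b)
  }
  structure(list(mu_frac = st$mu_frac, segment = st$segment,
                 jaws_t = drop(st$jaws), mlc_t = mlc_t,
                 gantry_t = st$gantry),
            class = "delivery_sample")
}

#' Split a VMAT arc into per-segment sub-fields
#'
#' One sub-beam per adjacent control-point pair. Each sub-beam's `mu_cum`
#' is re-normalized to \[0, 1\] and it carries its MU share
#' (`total_mu * delta_MU`, forced to sum exactly to the parent total) and
#' its own gantry span, so that pooled sampling over sub-beams weighted by
#' MU share is statistically identical to sampling the parent.
#'
#' @param beam a `vmat_arc` [beam()].
#' @return list of 2-control-point [beam()]s with an `mu_share` field.
#' @export
split_vmat_subfields <- function(beam) {
  if (beam$modality != "vmat_arc") stop("beam is not a VMAT arc")
  if (beam$n_cp < 2) stop("cannot split a beam with fewer than 2 control points")
  n_seg <- beam$n_cp - 1L
  shares <- beam$total_mu * diff(beam$mu_cum)
  shares[n_seg] <- beam$total_mu - sum(shares[-n_seg])
  lapply(seq_len(n_seg), function(i) {
    cps <- lapply(c(i, i + 1L), function(k) {
      mlc <- if (!is.null(beam$mlc_boundaries)) {
        list(boundaries = beam$mlc_boundaries,
             bankA = beam$bankA[k, ], bankB = beam$bankB[k, ])
      }
      control_point(k - i + 1L, beam$mu_cum[k], beam$jaws[k, ], mlc,
                    beam$gantry[k])
    })
    sub <- beam(cps, total_mu = shares[i], modality = "vmat_arc",
                jaw_tracking = beam$jaw_tracking, interp = beam$interp)
    sub$mu_share <- shares[i]
    sub$parent_segment <- i
    sub
  })
}

#' Split an IMRT field into identical parallel sub-fields
#'
#' Returns `nsplit` copies of the beam, each with a distinct child seed
#' derived from `base_seed` (see [derive_seed()]); running each copy with
#' `n_requested / nsplit` particles and summing the resulting dose grids is
#' the parallelization contract.
#'
#' @param beam a [beam()].
#' @param nsplit number of sub-fields (>= 1).
#' @param base_seed master seed.
#' @return list of `list(beam =, seed =)` pairs.
#' @export
split_imrt_nsplit <- function(beam, nsplit, base_seed) {
  stopifnot(nsplit >= 1)
  lapply(seq_len(nsplit), function(i) {
    list(beam = beam, seed = derive_seed(base_seed, i))
  })
}

#' Import a DICOM RT Plan (not yet supported)
#'
#' Placeholder for the DICOM adapter: converts
#' BeamSequence/ControlPointSequence into the JSON plan dialect. Not
#' implemented in this version; export the plan to the JSON dialect (see
#' [load_plan()] for the schema) instead.
#'
#' @param path DICOM RT Plan file.
#' @export
read_dicom_plan <- function(path) {
  stop("DICOM RT Plan import is not implemented; convert the plan to the ",
       "JSON dialect documented in ?load_plan")
}

# Widest jaw opening the beam ever reaches (componentwise envelope over
# control points; linear interpolation cannot exceed it).
beam_max_opening <- function(beam) {
  c(X1 = min(beam$jaws[, 1]), X2 = max(beam$jaws[, 2]),
    Y1 = min(beam$jaws[, 3]), Y2 = max(beam$jaws[, 4]))
}
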