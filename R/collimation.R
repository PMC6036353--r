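# The flat-absorbing jaw-tracking (FAJT) collimator.
#
# Each source particle drawn from the cyclic reader is recycled n_recycle
# times; every copy is azimuthally redistributed (rotated by an independent
# uniform angle about the beam axis), then ray-traced in vacuum to the top
# surface of each jaw pair in beam order. A copy that strikes a jaw top
# surface is absorbed outright -- no transmission, no scatter. Survivors
# pass a single-plane MLC stage (projected aperture, bulk transmission
# factor, leaf-tip offset) and are scored on the PhspB plane below the MLC,
# until the scored store holds exactly n_requested particles.
#
# In dynamic mode every copy first samples a fractional MU, which fixes the
# jaw edges AND the MLC banks for that copy -- the synchronization that
# makes jaw-tracking work. Azimuth angles and MU draws come from two
# independent RNG streams derived from the master seed; phi is consumed
# first for each chunk of copies, then the MU draws.

#' Define the collimator geometry
#'
#' All planes in cm from the target, increasing toward the isocenter.
#' Projected jaw edges always scale with `z_top / sad` (point-source
#' projection); the absorbing plane sits at the top (target-side) surface
#' of each jaw pair, which rejects both diverging and downward-aimed
#' particles most effectively.
#'
#' @param jaw_pairs ordered list (beam direction) of `list(axis, z_top)`
#'   with `axis` `"X"` or `"Y"`.
#' @param mlc_plane_z single MLC modeling plane, cm.
#' @param sad source-to-axis distance, cm.
#' @param phspB_z scoring plane of the collimated store, below the MLC.
#' @return an object of class `collimator_geometry`.
#' @export
collimator_geometry <- function(jaw_pairs = list(list(axis = "Y", z_top = 28),
                                                 list(axis = "X", z_top = 36)),
                                mlc_plane_z = 50, sad = 100, phspB_z = 55) {
  z_tops <- vapply(jaw_pairs, `[[`, numeric(1), "z_top")
  if (is.unsorted(z_tops, strictly = TRUE) || any(z_tops <= 0)) {
    stop("jaw planes must be strictly ordered along the beam and positive")
  }
  if (!(max(z_tops) < mlc_plane_z && mlc_plane_z < phspB_z &&
        phspB_z <= sad)) {
    stop("need z_top < mlc_plane_z < phspB_z <= sad")
  }
  structure(list(jaw_pairs = jaw_pairs, mlc_plane_z = mlc_plane_z,
                 sad = sad, phspB_z = phspB_z),
            class = "collimator_geometry")
}

#' Load a collimator geometry from a JSON config
#'
#' @param path JSON with fields `jaw_pairs` (list of `{axis, z_top}`),
#'   `mlc_plane_z`, `sad`, `phspB_z`.
#' @return a [collimator_geometry()].
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  collimator_geometry(
    jaw_pairs = lapply(g$jaw_pairs, function(p) {
      list(axis = p$axis, z_top = p$z_top)
    }),
    mlc_plane_z = g$mlc_plane_z, sad = g$sad, phspB_z = g$phspB_z)
}

#' Collimation run configuration
#'
#' @param n_requested exact number of particles the collimated store
#'   (PhspB) must contain.
#' @param n_recycle azimuthal-redistribution copies per source particle
#'   (default 20: large enough that one pass over a typically sized source
#'   store feeds the whole run, small enough to bound latent variance).
#' @param seed master seed; azimuth and MU streams are derived from it.
#' @param mlc_transmission bulk weight factor in \[0, 1\] applied to
#'   particles crossing under a leaf (0 = absorbing MLC).
#' @param leaf_tip_offset widening of each leaf opening, cm at isocenter.
#' @return an object of class `collimation_config`.
#' @export
collimation_config <- function(n_requested, n_recycle = 20, seed = 1L,
                               mlc_transmission = 0, leaf_tip_offset = 0) {
  stopifnot(n_requested >= 1, n_recycle >= 1,
            mlc_transmission >= 0, mlc_transmission <= 1)
  structure(list(n_requested = as.integer(n_requested),
                 n_recycle = as.integer(n_recycle), seed = as.integer(seed),
                 mlc_transmission = mlc_transmission,
                 leaf_tip_offset = leaf_tip_offset),
            class = "collimation_config")
}

#' Azimuthally rotate particles about the beam axis
#'
#' Rotates position (x, y) and direction (u, v) by the same angle, leaving
#' z, w, energy, weight, and kind untouched, so radius, polar angle, and
#' energy are preserved exactly.
#'
#' @param p a `phsp_store` (any number of rows).
#' @param phi rotation angle(s), radians (recycled to the row count).
#' @return the rotated store.
#' @export
apr_rotate <- function(p, phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  x <- p$x * c_ - p$y * s_
  y <- p$x * s_ + p$y * c_
  u <- p$u * c_ - p$v * s_
  v <- p$u * s_ + p$v * c_
  p$x <- x; p$y <- y; p$u <- u; p$v <- v
  p
}

#' Project particles to a downstream plane
#'
#' Straight-line vacuum transport: `x' = x + u (z_plane - z) / w`, likewise
#' for y; direction, energy, and weight unchanged.
#'
#' @param p a `phsp_store`; all rows must travel toward increasing z
#'   (`w > 0`).
#' @param z_plane target plane, cm, at or beyond the particles' z.
#' @return the projected store.
#' @export
project_to_plane <- function(p, z_plane) {
  if (any(p$w <= 0)) {
    stop("cannot project particle(s) with w <= 0 (not travelling downstream)")
  }
  if (any(z_plane < p$z - 1e-12)) stop("z_plane lies upstream of particle z")
  t <- (z_plane - p$z) / p$w
  p$x <- p$x + p$u * t
  p$y <- p$y + p$v * t
  p$z <- rep(z_plane, nrow(p))
  if (inherits(p, "phsp_store")) attr(p, "z_plane") <- z_plane
  p
}

#' Test particles against one absorbing jaw pair
#'
#' The particle is projected to the pair's top surface; the physical edges
#' there are the isocenter-plane edges scaled by `z_top / sad`. It passes
#' iff its coordinate along the pair's axis lies strictly inside the
#' opening -- a particle exactly on an edge is absorbed (closed-edge
#' tie-break: never over-doses out of field).
#'
#' @param p a `phsp_store` with `w > 0`.
#' @param pair `list(axis = "X"|"Y", z_top, e_neg, e_pos)` with edges in cm
#'   at isocenter.
#' @param sad source-to-axis distance, cm.
#' @return logical vector: `TRUE` = pass, `FALSE` = absorbed.
#' @export
jaw_transmit <- function(p, pair, sad = 100) {
  scale <- pair$z_top / sad
  t <- (pair$z_top - p$z) / p$w
  coord <- if (identical(pair$axis, "X")) p$x + p$u * t else p$y + p$v * t
  coord > pair$e_neg * scale & coord < pair$e_pos * scale
}

#' Transport particles through the single-plane MLC stage
#'
#' Particles are projected to the MLC plane; the leaf pair is located by
#' the Y coordinate against the projected boundaries. Inside the
#' (tip-offset-widened) opening the particle passes unchanged; under a leaf
#' its weight is multiplied by `transmission` (absorbed outright when
#' `transmission = 0`); outside the leaf-boundary span it is absorbed.
#'
#' @param p a `phsp_store` with `w > 0`.
#' @param mlc_plane_z MLC modeling plane, cm.
#' @param boundaries,bankA,bankB leaf geometry/tips, cm at isocenter
#'   (`bankA`/`bankB` may be matrices indexed per particle via `banks_at`
#'   internally; here plain vectors, one value per leaf).
#' @param sad source-to-axis distance, cm.
#' @param transmission bulk under-leaf weight factor.
#' @param tip_offset opening widening, cm at isocenter.
#' @return list with `status` (`"pass"`, `"pass_attenuated"`, `"absorb"`
#'   per particle) and `particle` (the projected store, weights updated,
#'   absorbed rows removed).
#' @export
mlc_transmit <- function(p, mlc_plane_z, boundaries, bankA, bankB,
                         sad = 100, transmission = 0, tip_offset = 0) {
  proj <- project_to_plane(p, mlc_plane_z)
  scale <- mlc_plane_z / sad
  y_iso <- proj$y / scale
  x_iso <- proj$x / scale
  leaf <- findInterval(y_iso, boundaries)
  in_span <- leaf >= 1L & leaf <= length(boundaries) - 1L
  leaf_safe <- pmax(1L, pmin(leaf, length(boundaries) - 1L))
  open <- x_iso > (bankA[leaf_safe] - tip_offset) &
    x_iso < (bankB[leaf_safe] + tip_offset)
  status <- rep("absorb", nrow(p))
  status[in_span & open] <- "pass"
  under <- in_span & !open
  if (transmission > 0) {
    status[under] <- "pass_attenuated"
    proj$weight[under] <- proj$weight[under] * transmission
  }
  keep <- status != "absorb"
  list(status = status, particle = phsp_subset(proj, keep))
}

#' @export
print.collimation_report <- function(x, ...) {
  cat("FAJT collimation report\n")
  cat("  source particles read (n_read):", x$n_read, "\n")
  cat("  APR copies examined:           ", x$n_examined, "\n")
  cat("    rejected upward (w <= 0):    ", x$n_upward, "\n")
  cat("    absorbed by jaws:            ", x$n_absorbed_jaws, "\n")
  cat("    absorbed by MLC:             ", x$n_absorbed_mlc, "\n")
  cat("    scored to PhspB:             ", x$n_scored, "\n")
  cat("  reader wrapped:", x$wrapped, "\n")
  invisible(x)
}

# Shared chunked driver for static and dynamic collimation. aperture_fn
# maps a chunk of copies (after APR) to per-copy jaw edge matrix and MLC
# state; it receives the copy count and the MU stream.
collimate_engine <- function(reader, geom, cfg, state_fn, annotate_gantry) {
  phi_stream <- rng_stream(derive_seed(cfg$seed, 1L))
  mu_stream <- rng_stream(derive_seed(cfg$seed, 2L))
  # chunk sized from the request (with headroom for rejections) so small
  # runs do not spuriously wrap the reader; depends only on the config, so
  # results stay reproducible
  nrec <- cfg$n_recycle
  chunk_src <- min(8192L, max(64L, 4L * as.integer(ceiling(
    cfg$n_requested / nrec))))

  scored <- list()
  n_scored_total <- 0L
  tally <- c(upward = 0L, jaws = 0L, mlc = 0L, scored = 0L, examined = 0L)
  src_global <- 0L # global source-delivery counter (for history grouping)
  zero_rounds <- 0L

  repeat {
    taken <- reader_take(reader, chunk_src)
    src <- reader$store[taken$idx, , drop = FALSE]
    n_src <- chunk_src
    copy_src <- rep(seq_len(n_src), each = nrec) # local source index per copy
    n_copy <- n_src * nrec

    idx <- rep(seq_len(n_src), each = nrec)
    px <- src$x[idx]; py <- src$y[idx]; pz <- src$z[idx]
    pu <- src$u[idx]; pv <- src$v[idx]; pw <- src$w[idx]
    pe <- src$energy[idx]; pwt <- src$weight[idx]; pk <- src$kind[idx]

    phi <- stream_runif(phi_stream, n_copy, 0, 2 * pi)
    c_ <- cos(phi); s_ <- sin(phi)
    x <- px * c_ - py * s_; y <- px * s_ + py * c_
    u <- pu * c_ - pv * s_; v <- pu * s_ + pv * c_

    st <- state_fn(n_copy, mu_stream)
    jaws <- st$jaws # n_copy x 4 matrix or 4-vector

    down <- pw > 0
    alive <- down
    absorbed_jaws <- rep(FALSE, n_copy)
    for (pair in geom$jaw_pairs) {
      scale <- pair$z_top / geom$sad
      t <- (pair$z_top - pz) / pw
      coord <- if (identical(pair$axis, "X")) x + u * t else y + v * t
      if (identical(pair$axis, "X")) {
        e_lo <- if (is.matrix(jaws)) jaws[, 1] else jaws[1]
        e_hi <- if (is.matrix(jaws)) jaws[, 2] else jaws[2]
      } else {
        e_lo <- if (is.matrix(jaws)) jaws[, 3] else jaws[3]
        e_hi <- if (is.matrix(jaws)) jaws[, 4] else jaws[4]
      }
      pass <- coord > e_lo * scale & coord < e_hi * scale
      absorbed_jaws <- absorbed_jaws | (alive & !pass)
      alive <- alive & pass
    }

    absorbed_mlc <- rep(FALSE, n_copy)
    wt_mult <- rep(1, n_copy)
    if (!is.null(st$mlc)) {
      scale <- geom$mlc_plane_z / geom$sad
      t <- (geom$mlc_plane_z - pz) / pw
      y_iso <- (y + v * t) / scale
      x_iso <- (x + u * t) / scale
      bnd <- st$mlc$boundaries
      leaf <- findInterval(y_iso, bnd)
      in_span <- leaf >= 1L & leaf <= length(bnd) - 1L
      leaf_safe <- pmax(1L, pmin(leaf, length(bnd) - 1L))
      ab <- st$mlc$banks_at(leaf_safe)
      open <- x_iso > (ab$a - cfg$leaf_tip_offset) &
        x_iso < (ab$b + cfg$leaf_tip_offset)
      under <- in_span & !open
      dead <- !in_span | (under & cfg$mlc_transmission == 0)
      if (cfg$mlc_transmission > 0) {
        wt_mult[under] <- cfg$mlc_transmission
      }
      absorbed_mlc <- alive & dead
      alive <- alive & !dead
    }

    pass_idx <- which(alive)
    n_need <- cfg$n_requested - n_scored_total
    cut_copy <- n_copy
    if (length(pass_idx) >= n_need) {
      cut_copy <- pass_idx[n_need]
      pass_idx <- pass_idx[seq_len(n_need)]
    }
    in_cut <- seq_len(n_copy) <= cut_copy
    tally["upward"] <- tally["upward"] + sum(!down & in_cut)
    tally["jaws"] <- tally["jaws"] + sum(absorbed_jaws & in_cut)
    tally["mlc"] <- tally["mlc"] + sum(absorbed_mlc & in_cut)
    tally["scored"] <- tally["scored"] + length(pass_idx)
    tally["examined"] <- tally["examined"] + cut_copy

    if (length(pass_idx)) {
      t_out <- (geom$phspB_z - pz[pass_idx]) / pw[pass_idx]
      src_ids <- src_global + copy_src[pass_idx]
      out <- data.frame(
        kind = pk[pass_idx], energy = pe[pass_idx],
        x = x[pass_idx] + u[pass_idx] * t_out,
        y = y[pass_idx] + v[pass_idx] * t_out,
        z = rep(geom$phspB_z, length(pass_idx)),
        u = u[pass_idx], v = v[pass_idx], w = pw[pass_idx],
        weight = pwt[pass_idx] * wt_mult[pass_idx],
        new_history = c(TRUE, diff(src_ids) != 0)
      )
      if (annotate_gantry) out$gantry_deg <- st$gantry[pass_idx]
      scored[[length(scored) + 1L]] <- out
      n_scored_total <- n_scored_total + nrow(out)
      zero_rounds <- 0L
    } else {
      zero_rounds <- zero_rounds + 1L
      if (zero_rounds * chunk_src > 3L * max(reader$m, reader$n)) {
        stop("collimation made no progress after re-reading the source ",
             "several times: the aperture admits no particles")
      }
    }

    if (n_scored_total >= cfg$n_requested) {
      # Return unused source particles to the reader so n_read reflects
      # exactly the records needed to fill PhspB.
      src_used <- ceiling(cut_copy / nrec)
      reader_seek(reader, reader$t - (chunk_src - src_used))
      src_global <- src_global + src_used
      break
    }
    src_global <- src_global + n_src
  }

  particles <- do.call(rbind, scored)
  rownames(particles) <- NULL
  hist_equiv <- reader$n_read * cfg$n_recycle *
    (attr(reader$store, "n_original_histories") / reader$n)
  store <- phsp_store(particles, z_plane = geom$phspB_z,
                      n_original_histories = hist_equiv, validate = FALSE)
  report <- structure(list(
    n_read = reader$n_read,
    n_examined = as.integer(tally["examined"]),
    n_upward = as.integer(tally["upward"]),
    n_absorbed_jaws = as.integer(tally["jaws"]),
    n_absorbed_mlc = as.integer(tally["mlc"]),
    n_scored = as.integer(tally["scored"]),
    wrapped = reader$wrapped
  ), class = "collimation_report")
  list(store = store, report = report)
}

#' Collimate a static aperture to an exact-count PhspB
#'
#' Runs the FAJT loop -- read, recycle with APR, absorb at jaw top
#' surfaces, MLC stage, score on the PhspB plane -- until the output store
#' holds exactly `n_requested` particles. The number of source records
#' consumed (`n_read`) is determined on the fly from the rejection rate.
#'
#' @param reader a [cyclic_reader()] over the incident store (PhspA).
#' @param geom a [collimator_geometry()].
#' @param cfg a [collimation_config()].
#' @param aperture `list(jaws = c(X1, X2, Y1, Y2), mlc = NULL |
#'   list(boundaries, bankA, bankB))`, cm at isocenter.
#' @return `list(store = phsp_store, report = collimation_report)`. The
#'   store's `n_original_histories` is the history-equivalent count
#'   `n_read * n_recycle * (source histories / source size)`, the
#'   normalization that keeps dose-per-initial-history semantics under
#'   recycling and radius rejection.
#' @export
collimate_static <- function(reader, geom, cfg, aperture) {
  jaws <- as.numeric(aperture$jaws)
  mlc <- aperture$mlc
  state_fn <- function(n_copy, mu_stream) {
    st <- list(jaws = jaws)
    if (!is.null(mlc)) {
      st$mlc <- list(
        boundaries = mlc$boundaries,
        banks_at = function(leaf) {
          list(a = mlc$bankA[leaf], b = mlc$bankB[leaf])
        })
    }
    st
  }
  collimate_engine(reader, geom, cfg, state_fn, annotate_gantry = FALSE)
}

#' Collimate a dynamic beam with synchronized jaw and MLC motion
#'
#' As [collimate_static()], but every APR copy first samples a fractional
#' MU (an independent uniform draw); the jaw edges and MLC banks applied to
#' that copy are interpolated from the plan at the sampled MU, which
#' synchronizes collimator and leaf motion. With `jaw_tracking = FALSE` the
#' jaws are held at the beam's widest opening while the MLC still moves.
#' Scored particles carry the sampled gantry angle in a `gantry_deg`
#' column.
#'
#' @param reader a [cyclic_reader()] over PhspA.
#' @param geom a [collimator_geometry()].
#' @param cfg a [collimation_config()].
#' @param beam a dynamic [beam()].
#' @return `list(store, report)` as for [collimate_static()].
#' @export
collimate_dynamic <- function(reader, geom, cfg, beam) {
  if (beam$n_cp < 2) stop("dynamic collimation needs >= 2 control points")
  fixed_jaws <- if (!beam$jaw_tracking) beam_max_opening(beam)
  state_fn <- function(n_copy, mu_stream) {
    mu <- stream_runif(mu_stream, n_copy)
    st <- delivery_state(beam, mu)
    out <- list(
      jaws = if (is.null(fixed_jaws)) st$jaws else as.numeric(fixed_jaws),
      gantry = st$gantry
    )
    if (!is.null(beam$mlc_boundaries)) {
      out$mlc <- list(
        boundaries = beam$mlc_boundaries,
        banks_at = function(leaf) mlc_banks_at(beam, st$segment, st$frac, leaf)
      )
    }
    out
  }
  collimate_engine(reader, geom, cfg, state_fn, annotate_gantry = TRUE)
}
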