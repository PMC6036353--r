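# Cyclic in-RAM phase-space reader with recycling bookkeeping.
#
# The reader starts at a uniformly random record (so parallel runs with
# different seeds consume independent stretches of the file), then reads
# sequentially with wraparound. An optional radius pre-filter discards
# particles that could never reach the collimator opening; discarded records
# still count toward n_read, because they correspond to source histories
# that were examined and rejected.
#
# Implementation: the delivery order for one full cycle is precomputed at
# construction (rotated store order restricted to in-radius records), along
# with the cumulative number of records examined at each delivery. take()
# is then O(particles delivered) regardless of how sparse the filter is.

#' Create a cyclic reader over a phase-space store
#'
#' @param store a [phsp_store()].
#' @param seed integer seed fixing the random start record. Two readers
#'   with the same seed deliver identical sequences.
#' @param r_max optional radius pre-filter in cm: records with
#'   sqrt(x^2+y^2) > r_max are skipped (but counted as read). See
#'   [default_r_max()] for the conventional choice.
#' @return an object of class `cyclic_reader` (mutable environment).
#' @export
cyclic_reader <- function(store, seed, r_max = NULL) {
  n <- nrow(store)
  if (n == 0) stop("cannot read from an empty store")
  rd <- new.env(parent = emptyenv())
  rd$store <- store
  rd$n <- n
  rd$seed <- as.integer(seed)
  rd$r_max <- r_max
  start_stream <- rng_stream(derive_seed(seed, 0L))
  rd$start_index <- stream_sample_int(start_stream, n, 1L)
  order_idx <- ((rd$start_index - 1L) + 0:(n - 1L)) %% n + 1L
  keep <- if (is.null(r_max)) {
    rep(TRUE, n)
  } else {
    sqrt(store$x^2 + store$y^2) <= r_max
  }
  rd$elig_pos <- which(keep[order_idx])     # position within the rotated cycle
  rd$elig_idx <- order_idx[rd$elig_pos]     # store row index
  rd$m <- length(rd$elig_pos)
  rd$t <- 0L            # deliveries so far
  rd$n_read <- 0L       # records examined (incl. filtered-out)
  rd$n_delivered <- 0L
  rd$wrapped <- FALSE
  class(rd) <- "cyclic_reader"
  rd
}

#' Default radius pre-filter for a jaw aperture
#'
#' The diagonal half-width of the largest jaw opening (projected from the
#' isocenter plane back to the store's scoring plane through the point
#' source) plus a 10% margin, so that one store can serve any field up to
#' that opening.
#'
#' @param jaws numeric (X1, X2, Y1, Y2) in cm at isocenter (the widest
#'   opening the delivery reaches, for dynamic beams).
#' @param z_plane scoring-plane z of the store, cm.
#' @param sad source-to-axis distance, cm.
#' @param margin fractional safety margin (default 0.1).
#' @return radius in cm.
#' @export
default_r_max <- function(jaws, z_plane, sad = 100, margin = 0.1) {
  half_diag <- sqrt(max(abs(jaws[1]), abs(jaws[2]))^2 +
                    max(abs(jaws[3]), abs(jaws[4]))^2)
  half_diag * (z_plane / sad) * (1 + margin)
}

# Deliver k particles. Returns store row indices and, per delivery, the
# cumulative n_read. Mutates the reader.
reader_take <- function(rd, k) {
  if (rd$m == 0L) {
    rd$n_read <- rd$n
    stop("cyclic reader exhausted: no particle passes the radius pre-filter ",
         "(r_max = ", format(rd$r_max), " cm) after a full cycle")
  }
  ts <- rd$t + seq_len(k)
  cycle <- (ts - 1L) %/% rd$m
  within <- (ts - 1L) %% rd$m + 1L
  idx <- rd$elig_idx[within]
  n_read_cum <- as.numeric(cycle) * rd$n + rd$elig_pos[within]
  if (cycle[k] > 0L && !rd$wrapped) {
    rd$wrapped <- TRUE
    warning("cyclic reader wrapped: the phase space is being re-read; ",
            "latent variance will grow", call. = FALSE)
  }
  rd$t <- rd$t + as.integer(k)
  rd$n_delivered <- rd$n_delivered + as.integer(k)
  rd$n_read <- n_read_cum[k]
  list(idx = idx, n_read_cum = n_read_cum)
}

# Rewind/advance the reader to a total delivery count t (used by the
# collimator to return over-consumed particles after hitting the exact
# requested count).
reader_seek <- function(rd, t) {
  t <- as.integer(t)
  rd$t <- t
  rd$n_delivered <- t
  if (t == 0L) {
    rd$n_read <- 0L
  } else {
    cycle <- (t - 1L) %/% rd$m
    within <- (t - 1L) %% rd$m + 1L
    rd$n_read <- as.numeric(cycle) * rd$n + rd$elig_pos[within]
    rd$wrapped <- cycle > 0L
  }
  invisible(rd)
}

#' Read the next particle from a cyclic reader
#'
#' Sequential delivery with wraparound, honoring the radius pre-filter.
#' `n_read` advances by the number of records examined (including
#' filtered-out ones); `n_delivered` by one.
#'
#' @param reader a [cyclic_reader()].
#' @return a one-row `phsp_store` with the next particle.
#' @export
next_particle <- function(reader) {
  taken <- reader_take(reader, 1L)
  phsp_subset(reader$store, taken$idx)
}

#' @export
print.cyclic_reader <- function(x, ...) {
  cat("Cyclic phase-space reader over", x$n, "particles\n")
  cat("  start index:", x$start_index,
      " r_max:", if (is.null(x$r_max)) "none" else format(x$r_max), "\n")
  cat("  eligible:", x$m, " read:", x$n_read,
      " delivered:", x$n_delivered,
      " wrapped:", x$wrapped, "\n")
  invisible(x)
}
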