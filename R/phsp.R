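# Phase-space particle containers.
#
# A phase-space store holds the state of every particle crossing a scoring
# plane: kind, energy (MeV), position (cm), direction cosines, statistical
# weight, and a flag marking the first particle of each primary history.
# Stores are columnar (a data.frame) so the collimator can operate on whole
# chunks with vectorized arithmetic.

PHSP_COLUMNS <- c("kind", "energy", "x", "y", "z", "u", "v", "w",
                  "weight", "new_history")

#' Construct a phase-space store
#'
#' @param particles a data.frame with columns `kind` (integer codes
#'   1 = photon, 2 = electron, 3 = positron, or character names), `energy`
#'   (MeV), `x`, `y`, `z` (cm), `u`, `v`, `w` (direction cosines), `weight`
#'   and logical `new_history`. Missing `z` is filled from `z_plane`;
#'   missing `weight` defaults to 1 and missing `new_history` to `TRUE`
#'   (every particle its own primary history).
#' @param z_plane scoring-plane position in cm from the target. Defaults to
#'   the common `z` of the particles.
#' @param n_original_histories number of primary histories the store
#'   represents (may be non-integer for recycled stores, where it is a
#'   history-equivalent count).
#' @param validate run invariant checks (unit direction norm, positive
#'   energy and weight, particles on the scoring plane).
#' @return an object of class `phsp_store`.
#' @export
phsp_store <- function(particles, z_plane = NULL,
                       n_original_histories = nrow(particles),
                       validate = TRUE) {
  stopifnot(is.data.frame(particles))
  if (is.character(particles$kind)) {
    particles$kind <- unname(PARTICLE_KINDS[particles$kind])
  }
  particles$kind <- as.integer(particles$kind)
  if (is.null(particles$weight)) particles$weight <- rep(1, nrow(particles))
  if (is.null(particles$new_history)) {
    particles$new_history <- rep(TRUE, nrow(particles))
  }
  if (is.null(particles$z)) {
    if (is.null(z_plane)) stop("either particles$z or z_plane must be given")
    particles$z <- rep(as.numeric(z_plane), nrow(particles))
  }
  if (is.null(z_plane)) {
    z_plane <- if (nrow(particles)) particles$z[[1]] else NA_real_
  }
  missing_cols <- setdiff(PHSP_COLUMNS, names(particles))
  if (length(missing_cols)) {
    stop("missing phase-space columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(particles), PHSP_COLUMNS)
  particles <- particles[, c(PHSP_COLUMNS, extra), drop = FALSE]
  out <- structure(particles,
                   z_plane = as.numeric(z_plane),
                   n_original_histories = as.numeric(n_original_histories),
                   class = c("phsp_store", "data.frame"))
  if (validate) validate_phsp(out)
  out
}

#' Validate phase-space store invariants
#'
#' Checks unit direction norms (|u^2+v^2+w^2 - 1| <= 1e-6), strictly
#' positive energies and weights, and that every particle lies on the
#' declared scoring plane within 1e-4 cm.
#'
#' @param store a `phsp_store`.
#' @return the store, invisibly; stops on violation.
#' @export
validate_phsp <- function(store) {
  if (!nrow(store)) return(invisible(store))
  norm2 <- store$u^2 + store$v^2 + store$w^2
  if (any(abs(norm2 - 1) > 1e-6)) {
    stop("direction cosines are not unit norm (tolerance 1e-6)")
  }
  if (any(store$energy <= 0)) stop("non-positive particle energy")
  if (any(store$weight <= 0)) stop("non-positive particle weight")
  if (!all(store$kind %in% PARTICLE_KINDS)) stop("unknown particle kind code")
  zp <- attr(store, "z_plane")
  if (is.finite(zp) && any(abs(store$z - zp) > 1e-4)) {
    stop("particles off the declared scoring plane z = ", zp,
         " (tolerance 1e-4 cm)")
  }
  invisible(store)
}

#' Particle counts per kind
#'
#' @param store a `phsp_store`.
#' @return named integer vector with photon/electron/positron totals.
#' @export
counts_by_kind <- function(store) {
  counts <- tabulate(store$kind, nbins = 3L)
  setNames(as.integer(counts), names(PARTICLE_KINDS))
}

#' @export
print.phsp_store <- function(x, ...) {
  counts <- counts_by_kind(x)
  cat("Phase-space store:", nrow(x), "particles on z =",
      format(attr(x, "z_plane")), "cm\n")
  cat("  histories represented:",
      format(attr(x, "n_original_histories")), "\n")
  cat("  by kind:", paste(names(counts), counts, sep = " = ",
                          collapse = ", "), "\n")
  if (nrow(x)) {
    cat("  energy range [MeV]:",
        paste(format(range(x$energy), digits = 4), collapse = " .. "), "\n")
  }
  invisible(x)
}

#' @export
summary.phsp_store <- function(object, ...) {
  print(object)
  if (nrow(object)) {
    r <- sqrt(object$x^2 + object$y^2)
    cat("  radius [cm]: mean", format(mean(r), digits = 4),
        "max", format(max(r), digits = 4), "\n")
    cat("  mean weight:", format(mean(object$weight), digits = 6), "\n")
  }
  invisible(object)
}

# Subset rows of a store, keeping metadata.
phsp_subset <- function(store, idx) {
  out <- store[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            z_plane = attr(store, "z_plane"),
            n_original_histories = attr(store, "n_original_histories"),
            class = c("phsp_store", "data.frame"))
}
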