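# Synthetic photon source emulating a linac phase space scored above the
# jaws (PhspA). A Gaussian focal spot at the target plane (z = 0) emits
# photons uniformly in solid angle within a cone about +z, with energies
# drawn from a binned spectrum, transported in vacuum to the scoring plane.
#
# The defaults are declared fixtures, not beam-data fits: a 1.2 mm-FWHM
# focal spot, a 0.25 rad cone (wide enough to cover a 30 x 30 cm^2 field
# corner at isocenter), and a coarse 10-bin 6 MV-like bremsstrahlung
# spectrum shipped with the package.

#' Load the packaged 6 MV-like spectrum fixture
#'
#' A coarse 10-bin approximation of a 6 MV bremsstrahlung spectrum (peak
#' probability near 0.5--2 MeV, maximum 6 MeV). A plausibility fixture for
#' testing, not a physics claim about any particular machine.
#'
#' @param path CSV with columns `energy_MeV`, `probability`; defaults to
#'   the packaged fixture.
#' @return data.frame with normalized probabilities.
#' @export
default_spectrum <- function(path = system.file("extdata", "spectrum_6mv.csv",
                                                package = "fajtrace")) {
  spec <- read.csv(path)
  stopifnot(all(c("energy_MeV", "probability") %in% names(spec)))
  spec$probability <- spec$probability / sum(spec$probability)
  spec
}

#' Define a synthetic photon source model
#'
#' @param focal_spot_sigma Gaussian lateral spread (cm) of the emission
#'   point at the target plane z = 0.
#' @param spectrum data.frame (`energy_MeV`, `probability`); probabilities
#'   are normalized and must be non-negative.
#' @param cone_half_angle maximum polar angle (radians), in (0, pi/2).
#' @param z_score scoring-plane position (cm from target) of the generated
#'   store; must sit above the first jaw plane.
#' @param seed integer seed.
#' @return an object of class `source_model`.
#' @export
source_model <- function(focal_spot_sigma = 0.05,
                         spectrum = default_spectrum(),
                         cone_half_angle = 0.25,
                         z_score = 20,
                         seed = 1L) {
  if (any(spectrum$probability < 0)) stop("negative spectrum probability")
  p <- spectrum$probability / sum(spectrum$probability)
  if (abs(sum(p) - 1) > 1e-9) stop("spectrum probabilities fail to normalize")
  if (cone_half_angle <= 0 || cone_half_angle >= pi / 2) {
    stop("cone_half_angle must lie in (0, pi/2)")
  }
  spectrum$probability <- p
  structure(list(focal_spot_sigma = focal_spot_sigma, spectrum = spectrum,
                 cone_half_angle = cone_half_angle, z_score = z_score,
                 seed = as.integer(seed)),
            class = "source_model")
}

#' Generate a synthetic incident phase space (PhspA)
#'
#' Directions are sampled uniformly in solid angle within the cone
#' (cos(theta) uniform on \[cos(theta_max), 1\], azimuth uniform), origins
#' from the focal spot, energies from the spectrum; particles are
#' transported in vacuum to `z_score`. All weights are 1 and every particle
#' starts a new primary history.
#'
#' @param model a [source_model()].
#' @param n number of photons (> 0).
#' @return a [phsp_store()] with `n_original_histories = n`.
#' @export
generate_phspA <- function(model, n) {
  stopifnot(inherits(model, "source_model"), n > 0)
  s <- rng_stream(model$seed)
  n <- as.integer(n)
  cos_max <- cos(model$cone_half_angle)
  cos_t <- 1 - stream_runif(s, n) * (1 - cos_max)
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  phi <- stream_runif(s, n, 0, 2 * pi)
  u <- sin_t * cos(phi)
  v <- sin_t * sin(phi)
  w <- cos_t
  x0 <- if (model$focal_spot_sigma > 0) {
    stream_rnorm(s, n, 0, model$focal_spot_sigma)
  } else rep(0, n)
  y0 <- if (model$focal_spot_sigma > 0) {
    stream_rnorm(s, n, 0, model$focal_spot_sigma)
  } else rep(0, n)
  bins <- stream_sample_int(s, nrow(model$spectrum), n, replace = TRUE,
                            prob = model$spectrum$probability)
  energy <- model$spectrum$energy_MeV[bins]
  t <- model$z_score / w
  particles <- data.frame(
    kind = rep(PARTICLE_KINDS[["photon"]], n),
    energy = energy,
    x = x0 + u * t, y = y0 + v * t, z = rep(model$z_score, n),
    u = u, v = v, w = w,
    weight = rep(1, n), new_history = rep(TRUE, n)
  )
  phsp_store(particles, z_plane = model$z_score, n_original_histories = n,
             validate = FALSE)
}

#' Generate a monoenergetic parallel beam
#'
#' An idealized test beam: all particles travel along +z, lateral positions
#' uniform within a square of the given half-width. Useful for probing the
#' top-surface absorbing-plane semantics, where a parallel beam is the
#' extreme case that separates the top-of-jaw choice from mid-jaw variants.
#'
#' @param n number of photons.
#' @param half_width half-width (cm) of the square footprint.
#' @param energy photon energy, MeV.
#' @param z_score scoring plane, cm.
#' @param seed integer seed.
#' @return a [phsp_store()].
#' @export
parallel_beam <- function(n, half_width, energy = 6, z_score = 20, seed = 1L) {
  stopifnot(n > 0, half_width > 0)
  s <- rng_stream(seed)
  n <- as.integer(n)
  particles <- data.frame(
    kind = rep(PARTICLE_KINDS[["photon"]], n),
    energy = rep(energy, n),
    x = stream_runif(s, n, -half_width, half_width),
    y = stream_runif(s, n, -half_width, half_width),
    z = rep(z_score, n),
    u = rep(0, n), v = rep(0, n), w = rep(1, n),
    weight = rep(1, n), new_history = rep(TRUE, n)
  )
  phsp_store(particles, z_plane = z_score, n_original_histories = n,
             validate = FALSE)
}
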