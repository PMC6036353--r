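# Shared fixtures: tiny hand-built stores and plans, constructed in code.

tiny_store <- function(x, y, z = 20, u = 0, v = 0, w = 1, energy = 6,
                       weight = 1, kind = 1L) {
  n <- if (length(x) == 0) 0L else
    max(lengths(list(x, y, u, v, w, energy, weight)))
  phsp_store(data.frame(
    kind = rep(kind, length.out = n), energy = rep(energy, length.out = n),
    x = rep(x, length.out = n), y = rep(y, length.out = n),
    z = rep(z, length.out = n),
    u = rep(u, length.out = n), v = rep(v, length.out = n),
    w = rep(w, length.out = n),
    weight = rep(weight, length.out = n),
    new_history = rep(TRUE, n)
  ), z_plane = z)
}

square_cp <- function(i, mu, half, gantry = 0, mlc = NULL) {
  control_point(i, mu, c(-half, half, -half, half), mlc, gantry)
}

# dynamic beam stepping between two square apertures at mu = 0.5
two_segment_beam <- function(half1 = 2, half2 = 5, jaw_tracking = TRUE) {
  beam(list(square_cp(1, 0, half1), square_cp(2, 0.5, half1),
            square_cp(3, 0.5, half2), square_cp(4, 1, half2)),
       total_mu = 100, modality = "imrt_dynamic",
       jaw_tracking = jaw_tracking)
}

test_mlc <- function(n_leaf = 10, open_half = 5, pitch = 1) {
  bnd <- seq(-n_leaf / 2 * pitch, n_leaf / 2 * pitch, by = pitch)
  list(boundaries = bnd, bankA = rep(-open_half, n_leaf),
       bankB = rep(open_half, n_leaf))
}
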