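# Exhaustive brute-force gamma oracle, independent of the package's
# search-limited implementation: for every reference voxel above threshold,
# minimize over ALL evaluation voxels. The candidate argmin is located with
# a BLAS-backed bilinear expansion of the squared gamma surface, then the
# value is recomputed with the direct formula at that voxel, so the result
# carries no cancellation error.
brute_gamma <- function(ref, eval, spacing_mm, dose_tol_pct, dta_mm,
                        threshold_pct) {
  d <- dim(ref)
  dmax <- max(ref)
  tolD <- dose_tol_pct / 100 * dmax
  thr <- threshold_pct / 100 * dmax
  gx <- (seq_len(d[1]) - 1) * spacing_mm[1]
  gy <- (seq_len(d[2]) - 1) * spacing_mm[2]
  gz <- (seq_len(d[3]) - 1) * spacing_mm[3]
  coords <- cbind(
    x = rep(gx, times = d[2] * d[3]),
    y = rep(rep(gy, each = d[1]), times = d[3]),
    z = rep(gz, each = d[1] * d[2])
  )
  rv <- as.numeric(ref)
  ev <- as.numeric(eval)
  sel <- which(rv >= thr)
  # squared-term expansion: T[v, j] = a_v + b_j - 2 * A[v, ] %*% B[j, ]
  A <- cbind(rv[sel] / tolD^2, coords[sel, , drop = FALSE] / dta_mm^2)
  B <- cbind(ev, coords)
  a <- rv[sel]^2 / tolD^2 + rowSums(coords[sel, , drop = FALSE]^2) / dta_mm^2
  b <- ev^2 / tolD^2 + rowSums(coords^2) / dta_mm^2
  tB <- t(B)
  jmin <- integer(length(sel))
  for (start in seq(1, length(sel), by = 2000L)) {
    rows <- start:min(start + 1999L, length(sel))
    TT <- a[rows] + outer(rep(0, length(rows)), b, `+`) -
      2 * (A[rows, , drop = FALSE] %*% tB)
    jmin[rows] <- max.col(-TT, ties.method = "first")
  }
  # exact recomputation at the located argmin
  dd <- (ev[jmin] - rv[sel]) / tolD
  dist2 <- rowSums((coords[jmin, , drop = FALSE] -
                      coords[sel, , drop = FALSE])^2)
  gamma <- rep(NA_real_, length(rv))
  gamma[sel] <- sqrt(dd^2 + dist2 / dta_mm^2)
  list(gamma = array(gamma, dim = d),
       pass_rate = 100 * mean(gamma[sel] <= 1),
       n_evaluated = length(sel))
}

# smooth positive random field on an n^3 lattice: separable smooth modes
# plus a little smoothed noise
smooth_field <- function(n, seed) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  f1 <- function() {
    a <- runif(3, -1, 1)
    a[1] * sin(pi * t * runif(1, 0.5, 2)) +
      a[2] * cos(pi * t * runif(1, 0.5, 2)) + a[3] * t
  }
  base <- outer(outer(f1(), f1()), f1())
  noise <- array(rnorm(n^3, 0, 0.05), dim = rep(n, 3))
  sm <- (noise +
           abs(base) / max(abs(base)) + 0.2)
  sm / max(sm) * 100
}
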