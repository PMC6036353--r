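# FAJT core: azimuthal redistribution, plane projection, absorbing jaws,
# the single-plane MLC stage, and exact-count collimation.

test_that("azimuthal rotation preserves everything but the azimuth", {
  p <- tiny_store(x = 3, y = 4, u = 0.1, v = 0, w = sqrt(1 - 0.01))
  r0 <- apr_rotate(p, 0)
  expect_equal(r0, p)
  rq <- apr_rotate(p, pi / 2)
  expect_equal(rq$x, -4)
  expect_equal(rq$y, 3)
  expect_equal(rq$u, 0, tolerance = 1e-15)
  expect_equal(rq$v, 0.1)
  expect_equal(sqrt(rq$x^2 + rq$y^2), 5)
  expect_equal(rq$u^2 + rq$v^2, p$u^2 + p$v^2)
  # distributional: uniform angles give uniform azimuths, radius untouched
  set.seed(41)
  n <- 1e5
  many <- tiny_store(x = rep(3, n), y = rep(4, n), u = 0.1, v = 0,
                     w = sqrt(1 - 0.01))
  phis <- runif(n, 0, 2 * pi)
  rot <- apr_rotate(many, phis)
  expect_equal(sqrt(rot$x^2 + rot$y^2), rep(5, n))
  expect_identical(rot$energy, many$energy)
  expect_identical(rot$weight, many$weight)
  expect_identical(rot$w, many$w)
  az <- atan2(rot$y, rot$x) %% (2 * pi)
  ks <- suppressWarnings(stats::ks.test(az / (2 * pi), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("plane projection is straight-line transport", {
  p <- tiny_store(x = 1.5, y = -2, z = 26)
  q <- project_to_plane(p, 55)
  expect_equal(q$x, 1.5)
  expect_equal(q$y, -2)
  expect_equal(q$z, 55)
  slope <- tiny_store(x = 0, y = 0, z = 0, u = 0.05 / sqrt(1.0025),
                      v = 0, w = 1 / sqrt(1.0025))
  expect_equal(project_to_plane(slope, 100)$x, 5.0)
  # associativity of successive projections
  two_step <- project_to_plane(project_to_plane(slope, 28), 100)
  expect_equal(two_step$x, project_to_plane(slope, 100)$x,
               tolerance = 1e-12)
  up <- tiny_store(0, 0, w = -1)
  expect_error(project_to_plane(up, 30), "w <= 0")
})

test_that("jaw transmission uses top-surface projected edges", {
  pair <- list(axis = "X", z_top = 28, e_neg = -5, e_pos = 5)
  mk <- function(slope) {
    w <- 1 / sqrt(1 + slope^2)
    tiny_store(x = 0, y = 0, z = 0, u = slope * w, w = w)
  }
  # physical half-opening at the plane: 5 * 28/100 = 1.4 cm
  expect_true(jaw_transmit(mk(0.049), pair))   # arrives at 1.372 cm
  expect_false(jaw_transmit(mk(0.051), pair))  # arrives at 1.428 cm
  # a particle exactly on the edge is absorbed (closed-edge tie-break):
  # place it on the jaw plane at exactly the physical edge coordinate
  on_edge <- tiny_store(x = 5 * (28 / 100), y = 0, z = 28)
  expect_false(jaw_transmit(on_edge, pair))
  # open edges pass every downward particle
  open_pair <- list(axis = "X", z_top = 28, e_neg = -Inf, e_pos = Inf)
  expect_true(all(jaw_transmit(mk(c(0, 0.3, -0.5)), open_pair)))
})

test_that("a parallel beam passes exactly the in-opening fraction", {
  # uniform grid of parallel rays, half-width 3 cm; edges chosen so the
  # physical opening at the top surface is +-1.4 cm
  g <- seq(-2.95, 2.95, by = 0.1)
  st <- tiny_store(x = rep(g, each = length(g)),
                   y = rep(g, times = length(g)), z = 0)
  pairY <- list(axis = "Y", z_top = 28, e_neg = -5, e_pos = 5)
  pairX <- list(axis = "X", z_top = 36, e_neg = -1.4 * 100 / 36,
                e_pos = 1.4 * 100 / 36)
  passY <- jaw_transmit(st, pairY)
  passX <- jaw_transmit(st, pairX)
  # counting oracle on the grid
  expect_equal(sum(passY & passX),
               sum(abs(st$y) < 1.4 & abs(st$x) < 1.4))
  expect_equal(mean(passX), mean(abs(g) < 1.4))
})

test_that("the top-surface plane differs measurably from a mid-jaw plane", {
  # same isocenter edges, absorbing plane moved from the top surface to a
  # mid-jaw height: for a parallel beam the projected opening scales with
  # the plane height, so the passing sets differ
  st <- parallel_beam(5000, half_width = 2, z_score = 10, seed = 3)
  top <- list(axis = "X", z_top = 28, e_neg = -5, e_pos = 5)
  mid <- list(axis = "X", z_top = 33, e_neg = -5, e_pos = 5)
  n_top <- sum(jaw_transmit(st, top)) # opening 1.4 cm
  n_mid <- sum(jaw_transmit(st, mid)) # opening 1.65 cm
  expect_gt(n_mid, n_top * 1.1)
})

test_that("the MLC stage attenuates under-leaf particles and absorbs outside", {
  mlc <- test_mlc(n_leaf = 10, open_half = 1, pitch = 1) # 2 cm opening in X
  mk <- function(x_iso, y_iso) {
    # aim a ray from the target at (x_iso, y_iso) projected coordinates
    w <- 1 / sqrt(1 + (x_iso / 100)^2 + (y_iso / 100)^2)
    tiny_store(x = 0, y = 0, z = 0, u = x_iso / 100 * w,
               v = y_iso / 100 * w, w = w)
  }
  hit <- function(x_iso, y_iso, transmission = 0, tip = 0) {
    mlc_transmit(mk(x_iso, y_iso), 50, mlc$boundaries, mlc$bankA,
                 mlc$bankB, transmission = transmission, tip_offset = tip)
  }
  expect_equal(hit(0, 0)$status, "pass")
  expect_equal(hit(2, 0)$status, "absorb")         # under leaf, trans = 0
  expect_equal(hit(2, 0, 0.015)$status, "pass_attenuated")
  expect_equal(hit(2, 0, 0.015)$particle$weight, 0.015)
  expect_equal(hit(0, 8, 0.015)$status, "absorb")  # outside leaf span
  # tip offset widens the opening
  expect_equal(hit(1.05, 0, 0, tip = 0.2)$status, "pass")
  expect_equal(hit(1.05, 0, 0, tip = 0)$status, "absorb")
})

test_that("the MLC fluence profile steps at the projected leaf tips", {
  # dense uniform fan across a 2 cm gap, uniform illumination in iso x
  x_iso <- seq(-3, 3, length.out = 6001)
  w <- 1 / sqrt(1 + (x_iso / 100)^2)
  fan <- tiny_store(x = 0, y = 0, z = 0, u = x_iso / 100 * w, w = w)
  mlc <- test_mlc(n_leaf = 10, open_half = 1, pitch = 1)
  res <- mlc_transmit(fan, 50, mlc$boundaries, mlc$bankA, mlc$bankB,
                      transmission = 0.1, tip_offset = 0)
  # weights binned back in iso coordinates
  kept_x <- res$particle$x * 100 / 50
  in_gap <- abs(x_iso) < 0.99
  under <- abs(x_iso) > 1.01
  w_of <- function(xs) {
    vapply(xs, function(x) {
      i <- which.min(abs(kept_x - x))
      res$particle$weight[i]
    }, numeric(1))
  }
  expect_true(all(w_of(x_iso[in_gap][c(1, 500, 1500)]) == 1))
  expect_true(all(w_of(c(-2, 1.5, 2.5)) == 0.1))
})

test_that("wide-open collimation reads exactly the needed source records", {
  A <- generate_phspA(source_model(seed = 51), 5000)
  geom <- collimator_geometry()
  rd <- cyclic_reader(A, 3)
  cfg <- collimation_config(1000, 20, seed = 4)
  res <- collimate_static(rd, geom, cfg,
                          list(jaws = c(-500, 500, -500, 500)))
  expect_equal(nrow(res$store), 1000)
  expect_equal(res$report$n_read, 50) # ceil(1000 / 20), nothing rejected
  expect_equal(res$report$n_scored, 1000)
  expect_equal(res$report$n_absorbed_jaws, 0)
})

test_that("PhspB holds exactly n_requested for arbitrary apertures", {
  A <- generate_phspA(source_model(seed = 52), 3e4)
  geom <- collimator_geometry()
  set.seed(11)
  for (i in 1:10) {
    jaws <- c(-runif(1, 0.5, 8), runif(1, 0.5, 8),
              -runif(1, 0.5, 8), runif(1, 0.5, 8))
    rd <- cyclic_reader(A, 100 + i,
                        r_max = default_r_max(jaws, attr(A, "z_plane")))
    res <- suppressWarnings(collimate_static(
      rd, geom, collimation_config(777, 20, seed = i), list(jaws = jaws)))
    expect_equal(nrow(res$store), 777)
    rep_ <- res$report
    expect_identical(rep_$n_examined,
                     rep_$n_upward + rep_$n_absorbed_jaws +
                       rep_$n_absorbed_mlc + rep_$n_scored)
  }
})

test_that("collimation is bit-identical under a fixed seed", {
  A <- generate_phspA(source_model(seed = 53), 2e4)
  geom <- collimator_geometry()
  run <- function() {
    rd <- cyclic_reader(A, 7, r_max = default_r_max(c(-5, 5, -5, 5), 20))
    collimate_static(rd, geom, collimation_config(5000, 20, seed = 99),
                     list(jaws = c(-5, 5, -5, 5)))
  }
  a <- run()
  b <- run()
  expect_identical(a$store, b$store)
  expect_identical(unclass(a$report), unclass(b$report))
})

test_that("the scored fraction matches the aperture solid angle", {
  # point source, square 10x10 aperture: the fraction of examined copies
  # scored equals the solid angle of the square over the cone solid angle
  m <- source_model(focal_spot_sigma = 0, seed = 54)
  A <- generate_phspA(m, 2e5)
  geom <- collimator_geometry()
  rd <- cyclic_reader(A, 5)
  res <- collimate_static(rd, geom, collimation_config(5e4, 20, seed = 6),
                          list(jaws = c(-5, 5, -5, 5)))
  rep_ <- res$report
  frac <- rep_$n_scored / rep_$n_examined
  # solid angle of a centered 2a x 2b rectangle seen from distance d
  a <- 5; b <- 5; d <- 100
  omega_rect <- 4 * atan(a * b / (d * sqrt(a^2 + b^2 + d^2)))
  omega_cone <- 2 * pi * (1 - cos(m$cone_half_angle))
  p <- omega_rect / omega_cone
  sigma <- sqrt(p * (1 - p) / rep_$n_examined)
  # recycled copies of one source particle are correlated; allow for the
  # variance inflation (up to n_recycle-fold) on top of the binomial bound
  expect_lt(abs(frac - p), 4 * sigma * sqrt(20))
})

test_that("an aperture that admits nothing raises instead of spinning", {
  A <- generate_phspA(source_model(seed = 55), 2000)
  geom <- collimator_geometry()
  rd <- cyclic_reader(A, 2)
  expect_error(
    suppressWarnings(collimate_static(
      rd, geom, collimation_config(100, 20, seed = 1),
      list(jaws = c(40, 41, 40, 41)))),
    "admits no particles")
})

test_that("dynamic collimation synchronizes jaws with the sampled MU", {
  # two equal-MU segments, 4x4 then 10x10: the inner core sees both
  # segments, the annulus only the second; with n_recycle = 1 the scored
  # counts are Poisson and the core/annulus density ratio is 2
  bm <- two_segment_beam(half1 = 2, half2 = 5)
  A <- generate_phspA(source_model(seed = 56), 3e6)
  geom <- collimator_geometry()
  rd <- cyclic_reader(A, 8, r_max = default_r_max(c(-5, 5, -5, 5), 20))
  res <- suppressWarnings(
    collimate_dynamic(rd, geom, collimation_config(6e4, 1, seed = 21), bm))
  st <- res$store
  expect_equal(nrow(st), 6e4)
  expect_false(is.null(st$gantry_deg))
  t <- (100 - st$z) / st$w
  xi <- st$x + st$u * t
  yi <- st$y + st$v * t
  n_core <- sum(abs(xi) < 1.5 & abs(yi) < 1.5)
  n_ann <- sum(abs(xi) < 4.5 & abs(yi) < 4.5 &
                 pmax(abs(xi), abs(yi)) > 2.5)
  dens_ratio <- (n_core / 9) / (n_ann / 56)
  sigma <- dens_ratio * sqrt(1 / n_core + 1 / n_ann)
  expect_lt(abs(dens_ratio - 2), 4 * sigma)

  # with jaw tracking off (no MLC) the jaws sit at the widest opening and
  # the mixture disappears: density ratio ~1
  bm2 <- two_segment_beam(half1 = 2, half2 = 5, jaw_tracking = FALSE)
  rd2 <- cyclic_reader(A, 8, r_max = default_r_max(c(-5, 5, -5, 5), 20))
  res2 <- suppressWarnings(
    collimate_dynamic(rd2, geom, collimation_config(6e4, 1, seed = 21),
                      bm2))
  st2 <- res2$store
  t <- (100 - st2$z) / st2$w
  xi <- st2$x + st2$u * t
  yi <- st2$y + st2$v * t
  n_core2 <- sum(abs(xi) < 1.5 & abs(yi) < 1.5)
  n_ann2 <- sum(abs(xi) < 4.5 & abs(yi) < 4.5 &
                  pmax(abs(xi), abs(yi)) > 2.5)
  ratio2 <- (n_core2 / 9) / (n_ann2 / 56)
  sigma2 <- ratio2 * sqrt(1 / n_core2 + 1 / n_ann2)
  expect_lt(abs(ratio2 - 1), 4 * sigma2)
})
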