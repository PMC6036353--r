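# Kerma ray-trace engine: phantoms, traversal, attenuation, uncertainty
# bookkeeping, and dose summation.

test_that("water phantoms are built to specification", {
  ph <- make_water_cube(82, 0.5, 90)
  expect_equal(ph$dims, c(82L, 82L, 82L))
  expect_equal(ph$origin[3], 90)
  expect_equal(ph$ssd, 90)
  expect_true(all(ph$density == 1))
  expect_equal(prod(ph$dims) * prod(ph$voxel_size), (82 * 0.5)^3)
  expect_equal(make_water_cube(1, 1, 50)$dims, c(1L, 1L, 1L))
})

test_that("the water cylinder holds water inside and air outside", {
  ph <- make_water_cylinder(diameter = 20.4, length = 10, voxel = 0.25)
  vol_water <- sum(ph$density == 1) * 0.25^3
  vol_expect <- pi * 10.2^2 * ph$dims[2] * 0.25
  expect_lt(abs(vol_water - vol_expect) / vol_expect, 0.02)
  # voxel centers beyond the radius are air
  xc <- ph$origin[1] + (seq_len(ph$dims[1]) - 0.5) * 0.25
  zc <- ph$origin[3] + (seq_len(ph$dims[3]) - 0.5) * 0.25
  out <- outer(xc^2, (zc - 100)^2, `+`) > 10.2^2
  mid <- ph$density[, 1, ]
  expect_true(all(mid[out] < 0.01))
  # reflection symmetry through the axis
  expect_equal(ph$density, ph$density[rev(seq_len(ph$dims[1])), , ])
  expect_equal(ph$density, ph$density[, , rev(seq_len(ph$dims[3]))])
})

test_that("zero density deposits nothing", {
  ph <- make_water_cube(10, 1, 90)
  ph$density[] <- 0
  st <- parallel_beam(100, 3, z_score = 20, seed = 1)
  g <- deposit(st, ph, attenuation_model())
  expect_true(all(g$dose == 0))
  expect_equal(g$n_missed, 100)
})

test_that("voxel traversal integrates the radiological path exactly", {
  ph <- make_water_cube(20, 0.5, 90)
  ph$density[] <- 1.23
  # axial ray through the full cube
  expect_equal(radiological_path(ph, c(0.1, 0.1, 0), c(0, 0, 1)),
               1.23 * 10, tolerance = 1e-9)
  # oblique ray: chord length from entry to exit
  d <- c(0.02, -0.01, 1)
  d <- d / sqrt(sum(d^2))
  p0 <- c(-1, 0.5, 0)
  t_in <- (90 - p0[3]) / d[3]
  t_out <- (100 - p0[3]) / d[3]
  expect_equal(radiological_path(ph, p0, d), 1.23 * (t_out - t_in),
               tolerance = 1e-8)
  # a ray that misses the cube integrates zero
  expect_equal(radiological_path(ph, c(50, 0, 0), c(0, 0, 1)), 0)
})

test_that("a broad parallel beam decays exponentially with depth", {
  ph <- make_water_cube(24, 0.5, 90)
  st <- parallel_beam(4e4, half_width = 5.9, energy = 2, z_score = 20,
                      seed = 5)
  att <- attenuation_model()
  g <- deposit(st, ph, att)
  mu <- att$mu_rho(2)
  prof <- apply(g$dose[9:16, 9:16, ], 3, mean)
  ratios <- prof[-1] / prof[-length(prof)]
  expect_equal(ratios, rep(exp(-mu * 0.5), length(ratios)),
               tolerance = 1e-9)
  # energy bookkeeping: deposited energy cannot exceed incident energy
  mass <- ph$density * prod(ph$voxel_size)
  e_dep <- sum(g$dose * g$n_histories_equivalent * mass) /
    fajtrace:::MEV_PER_G_TO_GY
  expect_lt(e_dep, sum(st$weight * st$energy))
})

test_that("deposition matches the closed-form kerma integral per voxel", {
  # single axial pencil ray, one voxel column
  ph <- voxel_phantom(c(1, 1, 4), 1, c(-0.5, -0.5, 90))
  st <- tiny_store(x = 0, y = 0, z = 20, energy = 2)
  att <- attenuation_model()
  g <- deposit(st, ph, att)
  mu <- att$mu_rho(2)
  muen <- att$muen_rho(2)
  k <- seq_len(4)
  expected <- 2 * (muen / mu) * (exp(-mu * (k - 1)) - exp(-mu * k)) /
    (1 * 1) * fajtrace:::MEV_PER_G_TO_GY
  expect_equal(as.numeric(g$dose), expected, tolerance = 1e-12)
})

test_that("charged particles deposit their energy in the entry voxel", {
  ph <- make_water_cube(5, 1, 90)
  st <- tiny_store(x = 0.2, y = 0.2, z = 20, energy = 3, kind = 2L)
  g <- deposit(st, ph, attenuation_model())
  expect_equal(sum(g$dose > 0), 1)
  expect_equal(max(g$dose),
               3 / 1 * fajtrace:::MEV_PER_G_TO_GY / 1,
               tolerance = 1e-12)
  expect_equal(unname(which(g$dose > 0, arr.ind = TRUE)[1, 3]),
               1L) # surface voxel
})

test_that("gantry rotation mirrors the dose for opposed beams", {
  ph <- voxel_phantom(c(21, 5, 21), 1, c(-10.5, -2.5, 89.5))
  st <- generate_phspA(source_model(seed = 61), 1e5)
  geom <- collimator_geometry()
  rd <- cyclic_reader(st, 3, r_max = default_r_max(c(-2, 6, -3, 3), 20))
  res <- collimate_static(rd, geom, collimation_config(2e4, 20, seed = 5),
                          list(jaws = c(-2, 6, -3, 3)))
  att <- attenuation_model()
  g0 <- deposit(res$store, ph, att, gantry_deg = 0)
  g180 <- deposit(res$store, ph, att, gantry_deg = 180)
  mirrored <- g180$dose[rev(seq_len(21)), , rev(seq_len(21))]
  sel <- g0$dose > 0.2 * max(g0$dose)
  rel <- (mirrored[sel] - g0$dose[sel]) /
    sqrt(pmax(g0$variance[sel] + g180$variance[rev(seq_len(21)), ,
                                               rev(seq_len(21))][sel],
              1e-30))
  expect_gt(mean(abs(rel) < 4), 0.99)
})

test_that("history estimation follows the inverse-square law", {
  ph <- make_water_cube(4, 1, 90)
  fake <- dose_grid(array(1, dim = c(4, 4, 4)),
                    array(0.04^2, dim = c(4, 4, 4)), ph,
                    n_histories_equivalent = 1e4)
  expect_equal(estimate_required_histories(fake, 0.01), 1.6e5)
  expect_equal(estimate_required_histories(fake, 0.04), 1e4)
  empty <- dose_grid(array(0, dim = c(4, 4, 4)),
                     array(0, dim = c(4, 4, 4)), ph, 1)
  expect_error(estimate_required_histories(empty, 0.01), "all zero")
})

test_that("the recommended history count reaches the uncertainty target", {
  ph <- make_water_cube(16, 1, 90)
  att <- attenuation_model()
  A <- generate_phspA(source_model(seed = 62), 1e6)
  run <- function(n, seed) {
    rd <- cyclic_reader(A, seed,
                        r_max = default_r_max(c(-5, 5, -5, 5), 20))
    res <- collimate_static(rd, collimator_geometry(),
                            collimation_config(n, 20, seed = seed),
                            list(jaws = c(-5, 5, -5, 5)))
    deposit(res$store, ph, att)
  }
  pilot <- run(3e4, 71)
  target <- 0.02
  Nest <- estimate_required_histories(pilot, target, 0.1)
  scale <- Nest / pilot$n_histories_equivalent
  full <- run(ceiling(3e4 * scale), 72)
  sel <- full$dose > 0.1 * max(full$dose)
  med <- median(sqrt(full$variance[sel]) / full$dose[sel])
  expect_lt(med, 1.1 * target)
})

test_that("dose summation obeys the variance algebra and linearity", {
  ph <- make_water_cube(6, 1, 90)
  st <- parallel_beam(2000, 2.9, z_score = 20, seed = 3)
  att <- attenuation_model()
  g <- deposit(st, ph, att)
  dbl <- sum_dose(list(g, g), c(1, 1))
  expect_equal(dbl$dose, 2 * g$dose)
  expect_equal(dbl$variance, 2 * g$variance)
  ident <- sum_dose(list(g, g), c(1, 0))
  expect_equal(ident$dose, g$dose)
  # partitioning the particle set and pooling by histories is exact
  quarters <- lapply(0:3, function(q) {
    idx <- seq_len(500) + q * 500
    sub <- fajtrace:::phsp_subset(st, idx)
    attr(sub, "n_original_histories") <- 500
    deposit(sub, ph, att)
  })
  pooled <- sum_dose(quarters, "histories")
  expect_equal(pooled$dose, g$dose, tolerance = 1e-12)
  expect_equal(pooled$n_histories_equivalent, 2000)
  g2 <- deposit(st, make_water_cube(5, 1, 90), att)
  expect_error(sum_dose(list(g, g2)), "mismatch")
})
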