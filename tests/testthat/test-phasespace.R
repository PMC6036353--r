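# Phase-space containers, IAEA-dialect I/O, and the cyclic reader.

test_that("IAEA write/read round-trips stores at single precision", {
  dir <- withr::local_tempdir()
  h <- file.path(dir, "two.IAEAheader")

  two <- tiny_store(x = c(1, -0.5), y = c(-2, 0.25), u = c(0, 0.1),
                    v = c(0, -0.2), w = c(1, sqrt(1 - 0.01 - 0.04)),
                    energy = c(6, 1.25))
  two$new_history <- c(TRUE, FALSE)
  write_iaea(two, h)
  back <- read_iaea(h)
  for (col in c("kind", "x", "y", "z", "energy", "weight")) {
    expect_equal(back[[col]], two[[col]], tolerance = 1e-7)
  }
  expect_identical(back$new_history, two$new_history)
  expect_equal(back$w, two$w, tolerance = 1e-6)

  # 1e4 random particles: fields written as float32 must come back exact
  big <- generate_phspA(source_model(seed = 5), 1e4)
  h2 <- file.path(dir, "big.IAEAheader")
  write_iaea(big, h2)
  b2 <- read_iaea(h2)
  snap32 <- function(v) readBin(writeBin(v, raw(), size = 4L), "numeric",
                                n = length(v), size = 4L)
  expect_identical(b2$x, snap32(big$x))
  expect_identical(b2$u, snap32(big$u))
  expect_identical(b2$weight, snap32(big$weight))
  expect_equal(counts_by_kind(b2), counts_by_kind(big))
  expect_equal(attr(b2, "n_original_histories"), 1e4)
  # a second write of the read-back store is byte-identical (fixed point)
  h3 <- file.path(dir, "big2.IAEAheader")
  write_iaea(b2, h3)
  expect_identical(readBin(sub("header", "phsp", h3), "raw", 3e6),
                   readBin(sub("header", "phsp", h2), "raw", 3e6))
})

test_that("a header declaring zero particles yields an empty store", {
  dir <- withr::local_tempdir()
  h <- file.path(dir, "empty.IAEAheader")
  st <- tiny_store(numeric(0), numeric(0))
  attr(st, "n_original_histories") <- 123
  write_iaea(st, h, allow_empty = TRUE)
  back <- read_iaea(h)
  expect_equal(nrow(back), 0)
  expect_equal(attr(back, "n_original_histories"), 123)
})

test_that("a hand-composed record decodes to the exact field values", {
  # bytes assembled independently from the record layout: signed type byte
  # (sign = sign of w), then float32 E (negated for a new history), x, y,
  # u, v, weight; z constant from the header
  dir <- withr::local_tempdir()
  rec <- c(
    writeBin(1L, raw(), size = 1L),                      # photon, w > 0
    writeBin(c(-6.0, 1.0, -2.0, 0, 0, 1.0), raw(), size = 4L,
             endian = "little")                          # new history
  )
  writeBin(rec, file.path(dir, "hand.IAEAphsp"))
  writeLines(c(
    "$RECORD_LENGTH:", "25", "",
    "$RECORD_CONTENTS:",
    "    1     // X", "    1     // Y", "    0     // Z",
    "    1     // U", "    1     // V", "    1     // Weight",
    "    0     // extra floats", "    0     // extra longs", "",
    "$RECORD_CONSTANT:", "    26.7     // Z", "",
    "$ORIG_HISTORIES:", "1", "",
    "$PARTICLES:", "1", ""
  ), file.path(dir, "hand.IAEAheader"))
  st <- read_iaea(file.path(dir, "hand.IAEAheader"))
  expect_equal(st$kind, 1L)
  expect_equal(st$energy, 6.0)
  expect_equal(st$x, 1.0)
  expect_equal(st$y, -2.0)
  expect_equal(st$z, 26.7)
  expect_equal(st$u, 0)
  expect_equal(st$v, 0)
  expect_equal(st$w, 1)
  expect_equal(st$weight, 1)
  expect_true(st$new_history)
})

test_that("an independent byte-level decoder agrees with the writer", {
  dir <- withr::local_tempdir()
  st <- generate_phspA(source_model(seed = 31), 500)
  st$new_history <- rep(c(TRUE, FALSE), length.out = 500)
  h <- file.path(dir, "ind.IAEAheader")
  write_iaea(st, h)
  # independent decoder: raw bytes, no shared code with read_iaea
  raw_all <- readBin(sub("IAEAheader", "IAEAphsp", h), "raw", 1e6)
  expect_equal(length(raw_all) %% 25, 0)
  n <- length(raw_all) / 25
  for (i in c(1, 57, 500)) {
    rec <- raw_all[((i - 1) * 25 + 1):(i * 25)]
    typ <- readBin(rec[1], "integer", size = 1L, signed = TRUE)
    flt <- readBin(rec[-1], "numeric", n = 6, size = 4L, endian = "little")
    expect_equal(abs(typ), st$kind[i])
    expect_equal(abs(flt[1]), st$energy[i], tolerance = 1e-7)
    expect_equal(flt[1] < 0, st$new_history[i])
    expect_equal(flt[2], st$x[i], tolerance = 1e-6)
    expect_equal(flt[3], st$y[i], tolerance = 1e-6)
    expect_equal(flt[4], st$u[i], tolerance = 1e-7)
    expect_equal(flt[5], st$v[i], tolerance = 1e-7)
    expect_equal(flt[6], st$weight[i], tolerance = 1e-7)
    expect_equal(sign(typ), sign(st$w[i]))
  }
})

test_that("malformed and truncated IAEA files raise targeted errors", {
  dir <- withr::local_tempdir()
  st <- tiny_store(1, 1)
  h <- file.path(dir, "bad.IAEAheader")
  write_iaea(st, h)
  # drop a required key
  lines <- readLines(h)
  writeLines(lines[lines != "$ORIG_HISTORIES:"],
             file.path(dir, "nokey.IAEAheader"))
  file.copy(sub("header$", "phsp", h),
            file.path(dir, "nokey.IAEAphsp"))
  expect_error(read_iaea(file.path(dir, "nokey.IAEAheader")),
               "ORIG_HISTORIES")
  # truncate the record file mid-record
  rec <- readBin(sub("header$", "phsp", h), "raw", 100)
  writeBin(rec[1:17], file.path(dir, "trunc.IAEAphsp"))
  file.copy(h, file.path(dir, "trunc.IAEAheader"))
  expect_error(read_iaea(file.path(dir, "trunc.IAEAheader")),
               "truncated.*byte offset")
})

test_that("the native columnar container round-trips exact doubles", {
  dir <- withr::local_tempdir()
  st <- generate_phspA(source_model(seed = 8), 2000)
  p <- file.path(dir, "native")
  write_phsp(st, p)
  back <- read_phsp(p)
  for (col in names(st)) expect_identical(back[[col]], st[[col]])
  expect_identical(attr(back, "z_plane"), attr(st, "z_plane"))
  expect_identical(attr(back, "n_original_histories"),
                   attr(st, "n_original_histories"))
})

test_that("store invariants are enforced", {
  st <- tiny_store(c(1, 2), c(0, 0))
  bad <- st
  bad$u[1] <- 0.5 # breaks unit norm
  expect_error(phsp_store(as.data.frame(bad), z_plane = 20), "unit norm")
  bad2 <- st
  bad2$energy[2] <- -1
  expect_error(phsp_store(as.data.frame(bad2), z_plane = 20), "energy")
  expect_equal(unname(counts_by_kind(st)[["photon"]]), 2L)
})

test_that("cyclic reading is sequential with wraparound from a random start", {
  st <- tiny_store(x = c(0.1, 0.2, 0.3), y = 0)
  rd <- cyclic_reader(st, seed = 4)
  s <- rd$start_index
  got <- suppressWarnings(
    vapply(1:7, function(i) next_particle(rd)$x, numeric(1)))
  want <- st$x[((s - 1) + 0:6) %% 3 + 1]
  expect_equal(got, want)
  expect_true(rd$wrapped)
  expect_equal(rd$n_delivered, 7)
  expect_equal(rd$n_read, 7)
})

test_that("the radius pre-filter delivers exactly the in-radius subset", {
  st <- tiny_store(x = c(1, 2, 3, 4), y = 0) # radii 1..4
  rd <- cyclic_reader(st, seed = 9, r_max = 2.5)
  xs <- suppressWarnings(
    vapply(1:8, function(i) next_particle(rd)$x, numeric(1)))
  expect_setequal(unique(xs), c(1, 2))       # only the two inner particles
  expect_equal(rd$n_delivered, 8)
  expect_equal(rd$n_read, 4 * 4)             # 4 cycles, all records examined
  # one full cycle delivers the in-radius subset in rotated store order
  rd2 <- cyclic_reader(st, seed = 9, r_max = 2.5)
  cyc <- vapply(1:2, function(i) next_particle(rd2)$x, numeric(1))
  expect_setequal(cyc, c(1, 2))
})

test_that("reader exhaustion on an all-excluded store raises after one cycle", {
  st <- tiny_store(x = c(3, 4), y = 0)
  rd <- cyclic_reader(st, seed = 1, r_max = 1)
  expect_error(next_particle(rd), "exhausted")
  expect_equal(rd$n_read, 2) # the full cycle was examined
})

test_that("readers are deterministic in their seed", {
  st <- generate_phspA(source_model(seed = 12), 500)
  r1 <- cyclic_reader(st, seed = 77, r_max = 1)
  r2 <- cyclic_reader(st, seed = 77, r_max = 1)
  x1 <- suppressWarnings(
    vapply(1:50, function(i) next_particle(r1)$x, numeric(1)))
  x2 <- suppressWarnings(
    vapply(1:50, function(i) next_particle(r2)$x, numeric(1)))
  expect_identical(x1, x2)
  expect_identical(r1$n_read, r2$n_read)
  # different seeds almost surely start elsewhere
  starts <- vapply(1:20, function(s) cyclic_reader(st, s)$start_index,
                   integer(1))
  expect_gt(length(unique(starts)), 10)
})
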