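test_that("ENVI roundtrip is bit-exact for all three interleaves", {
  cube <- tiny_cube()
  for (il in c("bil", "bip", "bsq")) {
    hdr <- file.path(withr::local_tempdir(), paste0("cube_", il, ".hdr"))
    write_envi(cube, hdr, interleave = il)
    back <- read_envi(hdr)
    expect_identical(back$data, cube$data, label = il)
    expect_identical(back$wavelengths_nm, cube$wavelengths_nm)
  }
})

test_that("metadata keys survive the header roundtrip", {
  cube <- tiny_cube()
  hdr <- file.path(withr::local_tempdir(), "m.hdr")
  write_envi(cube, hdr)
  back <- read_envi(hdr)
  expect_equal(back$meta$instrument, "synthetic-rig")
  expect_equal(back$meta$scan_speed, "3.4")
})

test_that("BIL and BSQ binaries decode to the same cube as explicit index arithmetic", {
  cube <- tiny_cube()
  td <- withr::local_tempdir()
  L <- 2L; S <- 2L; B <- 3L
  decoded <- list()
  for (il in c("bil", "bsq")) {
    hdr <- file.path(td, paste0(il, ".hdr"))
    write_envi(cube, hdr, interleave = il)
    raw <- readBin(file.path(td, paste0(il, ".dat")), "numeric",
                   n = L * S * B, size = 8, endian = "little")
    # independent scalar decoder from the interleave definition
    arr <- array(NA_real_, c(L, S, B))
    for (l in 1:L) for (s in 1:S) for (b in 1:B) {
      pos <- switch(il,
        bil = (l - 1) * B * S + (b - 1) * S + s,
        bsq = (b - 1) * L * S + (l - 1) * S + s)
      arr[l, s, b] <- raw[pos]
    }
    decoded[[il]] <- arr
    expect_identical(read_envi(hdr)$data, arr, label = il)
  }
  expect_identical(decoded$bil, decoded$bsq)
})

test_that("full 462-band instrument grid roundtrips", {
  wl <- seq(400, 1000, length.out = 462)
  cube <- hypercube(array(runif(462), c(1, 1, 462)), wl)
  hdr <- file.path(withr::local_tempdir(), "grid.hdr")
  write_envi(cube, hdr)
  back <- read_envi(hdr)
  expect_identical(back$data, cube$data)
  expect_equal(back$wavelengths_nm, wl)
})

test_that("malformed inputs are rejected", {
  td <- withr::local_tempdir()
  expect_error(read_envi(file.path(td, "nope.hdr")), "not found")
  # non-monotone wavelength list
  hdr <- file.path(td, "bad.hdr")
  writeLines(c("ENVI", "samples = 1", "lines = 1", "bands = 3",
               "data type = 5", "interleave = bil", "byte order = 0",
               "wavelength = { 700, 500, 900 }"), hdr)
  writeBin(as.numeric(1:3), file.path(td, "bad.dat"), size = 8)
  expect_error(read_envi(hdr), "strictly increasing")
  expect_error(hypercube(array(1, c(1, 1, 2)), c(700, 500)),
               "strictly increasing")
  expect_error(hypercube(array(1, c(1, 1, 2)), c(500)), "match")
})

test_that("calibration satisfies the white/dark/midpoint identities", {
  L <- 3L; S <- 4L; B <- 5L
  white <- 900 + seq_len(B) * 10
  dark <- 90 + seq_len(B)
  refs <- calibration_pair(white, dark)
  wl <- seq(500, 900, length.out = B)
  as_cube <- function(perband)
    hypercube(aperm(array(perband, c(B, L, S)), c(2, 3, 1)), wl)
  expect_equal(calibrate(as_cube(white), refs)$data,
               array(1, c(L, S, B)))
  expect_equal(calibrate(as_cube(dark), refs)$data,
               array(0, c(L, S, B)))
  expect_equal(calibrate(as_cube((white + dark) / 2), refs)$data,
               array(0.5, c(L, S, B)))
})

test_that("calibration is identity in the unit reference frame and unclipped", {
  set.seed(11)
  cube <- hypercube(array(runif(24, 0, 2), c(2, 2, 6)),
                    seq(400, 900, length.out = 6))
  out <- calibrate(cube, calibration_pair(rep(1, 6), rep(0, 6)))
  expect_equal(out$data, cube$data, tolerance = 1e-14)
  expect_true(any(out$data > 1)) # specular values preserved, not clipped
})

test_that("calibration is invariant under a consistent affine re-gauge", {
  set.seed(12)
  raw <- hypercube(array(runif(36, 100, 800), c(3, 2, 6)),
                   seq(400, 900, length.out = 6))
  white <- rep(900, 6); dark <- rep(50, 6)
  a <- 2.5; b <- 40
  raw2 <- hypercube(a * raw$data + b, raw$wavelengths_nm)
  out1 <- calibrate(raw, calibration_pair(white, dark))
  out2 <- calibrate(raw2, calibration_pair(a * white + b, a * dark + b))
  expect_equal(out1$data, out2$data, tolerance = 1e-12)
})

test_that("dead pixels (white <= dark) warn and are epsilon-guarded", {
  raw <- hypercube(array(c(5, 5), c(1, 1, 2)), c(500, 600))
  refs <- calibration_pair(white = c(10, 3), dark = c(2, 3))
  expect_warning(out <- calibrate(raw, refs), "white <= dark")
  expect_true(all(is.finite(out$data)))
  expect_equal(out$data[1, 1, 1], (5 - 2) / (10 - 2))
})

test_that("reference shape mismatches are input errors", {
  raw <- hypercube(array(1, c(2, 2, 3)), c(5, 6, 7) * 100)
  expect_error(calibrate(raw, calibration_pair(rep(1, 4), rep(0, 4))),
               "reference")
})

test_that("nearest_band resolves targets with the lower-index tie rule", {
  cube <- hypercube(array(1, c(1, 1, 3)), c(400, 500, 600))
  expect_equal(nearest_band(cube, 598.71), 3L)
  expect_equal(nearest_band(cube, 500), 2L)
  expect_equal(nearest_band(cube, 450), 1L) # equidistant -> lower index
})
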