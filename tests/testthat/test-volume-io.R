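test_that("scalar_volume enforces its invariants", {
  a <- array(1, dim = c(3, 3, 3))
  expect_s3_class(scalar_volume(a), "scalar_volume")
  expect_error(scalar_volume(array(1, dim = c(1, 3, 3))), "at least 2")
  bad <- a; bad[2, 2, 2] <- NaN
  expect_error(scalar_volume(bad), "non-finite")
  expect_error(scalar_volume(a, spacing = c(1, 0, 1)), "positive")
  expect_error(scalar_volume(matrix(1, 3, 3)), "3D")
})

test_that("analytic fields evaluate at physical grid coordinates", {
  # sphere signed distance: sample at the center is the radius
  v <- generate_volume(field_spec("sphere", radius = 1), dims = c(5, 5, 5),
                       spacing = c(0.5, 0.5, 0.5), origin = c(-1, -1, -1))
  expect_equal(v$samples[3, 3, 3], 1)  # grid (2,2,2) is the physical origin
  expect_equal(v$samples[1, 3, 3], 0)  # on the surface at distance 1

  r <- generate_volume(field_spec("linear_ramp", coef = c(2, -1, 3, 0.5)),
                       dims = c(4, 4, 4), spacing = c(1, 2, 0.5),
                       origin = c(10, 0, -1))
  expect_equal(r$samples[2, 3, 4],
               2 * 11 - 1 * 4 + 3 * 0.5 + 0.5)

  tor <- generate_volume(field_spec("torus", major_radius = 1,
                                    tube_radius = 0.4),
                         dims = c(3, 3, 3), spacing = c(1, 1, 1),
                         origin = c(-1, -1, -1))
  expect_equal(tor$samples[3, 2, 2], 0.4)  # (1,0,0) lies on the spine

  two <- generate_volume(
    field_spec("two_spheres", centers = rbind(c(-1, 0, 0), c(1, 0, 0)),
               radii = c(0.5, 0.75)),
    dims = c(5, 3, 3), spacing = c(0.5, 0.5, 0.5), origin = c(-1, -0.5, -0.5))
  expect_equal(two$samples[1, 2, 2], 0.5)    # center of sphere 1
  expect_equal(two$samples[5, 2, 2], 0.75)   # center of sphere 2
})

test_that("smooth noise is exactly reproducible from its seed", {
  a <- generate_volume(field_spec("smooth_noise", seed = 7), dims = c(8, 8, 8))
  b <- generate_volume(field_spec("smooth_noise", seed = 7), dims = c(8, 8, 8))
  c <- generate_volume(field_spec("smooth_noise", seed = 8), dims = c(8, 8, 8))
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("field specs validate their parameters", {
  expect_error(field_spec("sphere", radius = -1), "> 0")
  expect_error(field_spec("two_spheres"), "centers")
  expect_error(field_spec("smooth_noise"), "seed")
  expect_error(field_spec("linear_ramp", coef = 1:3), "coef")
})

test_that("raw binary grids round-trip through their JSON sidecar", {
  vol <- fix_noise(seed = 3L)
  path <- file.path(withr::local_tempdir(), "vol.raw")
  write_raw_volume(vol, path)
  back <- read_raw_volume(path)
  expect_identical(back$samples, vol$samples)
  expect_identical(back$spacing, vol$spacing)

  # integer dtype rounds
  small <- scalar_volume(array(c(0.2, 1.7, 3.5, 200, 8, 9, 10, 11),
                               dim = c(2, 2, 2)))
  p2 <- file.path(withr::local_tempdir(), "u8.raw")
  write_raw_volume(small, p2, dtype = "uint8")
  expect_equal(read_raw_volume(p2)$samples,
               array(round(small$samples), dim = c(2, 2, 2)))
  expect_error(read_raw_volume(file.path(tempdir(), "nope.raw")), "I/O")
})

test_that("slice-to-raster conversion follows the windowing contract", {
  expect_equal(convert_slice_to_raster(matrix(5, 4, 4)),
               matrix(0L, 4, 4))  # degenerate range rule
  ident <- matrix(0:255, 16, 16)
  expect_equal(convert_slice_to_raster(ident), matrix(as.integer(ident), 16, 16))
  ramp <- matrix(0:1023, 32, 32)
  expect_equal(convert_slice_to_raster(ramp),
               matrix(as.integer(round(255 * (0:1023) / 1023)), 32, 32))
  # explicit window clamps
  w <- convert_slice_to_raster(matrix(c(-10, 0, 50, 100, 110, 200), 2, 3),
                               window = c(50, 100))
  expect_equal(as.vector(w), c(0L, 0L, 128L, 255L, 255L, 255L))
  expect_error(convert_slice_to_raster(matrix(1, 2, 2), window = c(0, 0)),
               "width")
})

test_that("windowing is monotone non-decreasing", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      vals <- sort(stats::rnorm(64, sd = 100))
      for (win in list("full", c(0, 50), c(10, 200))) {
        px <- convert_slice_to_raster(matrix(vals, 8, 8), window = win)
        expect_true(all(diff(as.vector(px)) >= 0))
      }
    }
  })
})

test_that("BMP and PNG codecs round-trip 8-bit rasters exactly", {
  img <- matrix(as.integer((0:255)[(seq_len(12 * 9) %% 256) + 1]), 12, 9)
  d <- withr::local_tempdir()
  write_gray_bmp(img, file.path(d, "a.bmp"))
  expect_identical(read_gray_bmp(file.path(d, "a.bmp")), img)
  write_gray_png(img, file.path(d, "a.png"))
  expect_identical(read_gray_png(file.path(d, "a.png")), img)
  expect_error(write_gray_bmp(matrix(300L, 2, 2), file.path(d, "b.bmp")),
               "0..255")
})

test_that("raster stacks assemble and enforce matching dimensions", {
  d <- withr::local_tempdir()
  img <- matrix(100L, 8, 8)
  for (k in 1:3) write_gray_bmp(img, file.path(d, sprintf("s%d.bmp", k)))
  vol <- load_raster_stack(d, spacing = c(1, 1, 2.5))
  expect_equal(dim(vol), c(8, 8, 3))
  expect_true(all(vol$samples == 100))
  expect_equal(vol$spacing, c(1, 1, 2.5))

  write_gray_bmp(matrix(1L, 4, 4), file.path(d, "t0.bmp"))
  expect_error(load_raster_stack(file.path(d, c("s1.bmp", "t0.bmp"))),
               "dimension mismatch")
  expect_error(load_raster_stack(character(0)), "insufficient")
})

test_that("volume -> raster stack -> volume reproduces 8-bit quantization", {
  vol <- fix_sphere_physical()
  d <- withr::local_tempdir()
  write_raster_stack(vol, d, format = "png")
  back <- load_raster_stack(d, spacing = vol$spacing)
  # oracle: the global full-range window applied slice by slice
  rng <- range(vol$samples)
  win <- c(mean(rng), diff(rng))
  expected <- vol$samples
  for (k in seq_len(dim(vol)[3]))
    expected[, , k] <- convert_slice_to_raster(vol$samples[, , k], win)
  expect_identical(back$samples, expected)
})

test_that("DICOM series assemble with rescale and ordering applied", {
  d <- withr::local_tempdir()
  # constant field survives assembly
  write_dicom_series(file.path(d, "const"),
                     replicate(2, matrix(7L, 6, 5), simplify = FALSE))
  vol <- load_dicom_series(file.path(d, "const"))
  expect_equal(dim(vol), c(6, 5, 2))
  expect_true(all(vol$samples == 7))

  # rescale: stored 5, slope 2, intercept -1 -> 9
  write_dicom_series(file.path(d, "resc"),
                     replicate(2, matrix(5L, 4, 4), simplify = FALSE),
                     rescale_slope = 2, rescale_intercept = -1)
  expect_true(all(load_dicom_series(file.path(d, "resc"))$samples == 9))

  # 4-slice ramp written by this suite: z-profile is 0,1,2,3
  write_dicom_series(file.path(d, "ramp"),
                     lapply(0:3, function(v) matrix(v, 4, 4)),
                     slice_thickness = 2)
  ramp <- load_dicom_series(file.path(d, "ramp"))
  expect_equal(as.vector(ramp$samples[1, 1, ]), c(0, 1, 2, 3))
  expect_equal(ramp$spacing[3], 2)
})

test_that("DICOM slice ordering uses position, then instance number", {
  d <- withr::local_tempdir()
  # file names reversed relative to position: position must win
  write_dicom_series(file.path(d, "pos"),
                     lapply(c(30, 10, 20), function(v) matrix(v, 3, 3)),
                     positions = c(3, 1, 2),
                     names_ = c("a.dcm", "b.dcm", "c.dcm"))
  vol <- load_dicom_series(file.path(d, "pos"))
  expect_equal(as.vector(vol$samples[1, 1, ]), c(10, 20, 30))

  # duplicate positions: instance number decides
  write_dicom_series(file.path(d, "inst"),
                     lapply(c(2, 1), function(v) matrix(v, 3, 3)),
                     positions = c(0, 0), instance_numbers = c(2, 1),
                     names_ = c("a.dcm", "b.dcm"))
  vol2 <- load_dicom_series(file.path(d, "inst"))
  expect_equal(as.vector(vol2$samples[1, 1, ]), c(1, 2))
})

test_that("DICOM loader reports contract violations usefully", {
  d <- withr::local_tempdir()
  write_dicom_series(file.path(d, "mix"), list(matrix(1L, 4, 4)))
  write_dicom_slice(matrix(1L, 5, 5), file.path(d, "mix", "slice004.dcm"),
                    instance_number = 2L, position_z = 1)
  expect_error(load_dicom_series(file.path(d, "mix")), "dimension mismatch")

  write_dicom_series(file.path(d, "one"), list(matrix(1L, 4, 4)))
  expect_error(load_dicom_series(file.path(d, "one")), "insufficient")

  garbled <- file.path(d, "bad.dcm")
  writeBin(as.raw(1:64), garbled)
  expect_error(load_dicom_series(c(garbled, garbled)), "bad.dcm")
})

test_that("loaded DICOM volumes carry no patient metadata", {
  d <- withr::local_tempdir()
  write_dicom_series(file.path(d, "s"),
                     replicate(2, matrix(1L, 4, 4), simplify = FALSE))
  vol <- load_dicom_series(file.path(d, "s"))
  expect_identical(sort(names(vol)), sort(c("samples", "spacing", "origin")))
  expect_null(attributes(vol)$patient)
  # nothing string-valued anywhere in the object
  expect_false(any(vapply(vol, is.character, logical(1L))))
})

test_that("grid_to_physical applies origin and spacing", {
  v <- scalar_volume(array(0, dim = c(3, 3, 3)), spacing = c(1, 2, 3),
                     origin = c(10, 20, 30))
  expect_equal(as.vector(grid_to_physical(v, c(1, 1, 1))), c(11, 22, 33))
  expect_equal(grid_to_physical(v, rbind(c(0, 0, 0), c(2, 2, 2))),
               rbind(c(10, 20, 30), c(12, 24, 36)))
})
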