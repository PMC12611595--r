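test_that("CT series round-trips voxel-identically through DICOM", {
  geo <- grid_geometry(c(12, 10, 10), c(2, 2, 3), c(-10, -8, 5))
  set.seed(1)
  ct <- scalar_volume(array(round(runif(1200, -1000, 1000)), dim = geo$shape),
                      geo, "HU")
  dir <- withr::local_tempdir()
  write_ct_series(ct, dir, seed = 42)
  back <- read_ct_series(dir)
  expect_identical(back$geometry$shape, geo$shape)
  expect_equal(back$geometry$spacing, geo$spacing)
  expect_equal(back$geometry$origin, geo$origin)
  expect_identical(back$values, ct$values)
  # rescale arithmetic: a 0 HU voxel is stored as 1024 with intercept -1024
  ct0 <- scalar_volume(array(0, dim = geo$shape), geo, "HU")
  dir2 <- withr::local_tempdir()
  write_ct_series(ct0, dir2, seed = 1)
  first <- doserings:::dcm_read_file(list.files(dir2, full.names = TRUE)[1])
  stored <- readBin(doserings:::dcm_get(first, "7FE0,0010"), "integer",
                    n = 120, size = 2, endian = "little", signed = FALSE)
  expect_true(all(stored == 1024))
  expect_equal(doserings:::dcm_get(first, "0028,1052"), -1024)
})

test_that("a removed CT slice is reported with the gap position", {
  geo <- grid_geometry(c(6, 6, 8), c(3, 3, 3))
  ct <- scalar_volume(array(0, dim = geo$shape), geo, "HU")
  dir <- withr::local_tempdir()
  paths <- write_ct_series(ct, dir, seed = 2)
  file.remove(paths[4])
  expect_error(read_ct_series(dir), "non-uniform|gap")
})

test_that("dose round-trips within one scaling quantum", {
  geo <- toy_geometry(c(9, 7, 5))
  dose <- random_dose(geo, seed = 3, max_gy = 55,
                      prescriptions = c(PTV45 = 45, PTV50 = 50))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dose(dose, f, seed = 1)
  back <- read_dose(f)
  quantum <- max(dose$values) / (2^31 - 1)
  expect_lte(max(abs(back$values - dose$values)), quantum)
  expect_equal(unname(back$prescriptions), c(45, 50))
  # all-zero dose is a valid file
  z <- dose_grid(array(0, dim = geo$shape), geo)
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_dose(z, f2, seed = 1)
  expect_true(all(read_dose(f2)$values == 0))
})

test_that("dose with geometry different from the CT loads but fails alignment", {
  geo_ct <- toy_geometry(c(8, 8, 4))
  geo_dose <- grid_geometry(c(8, 8, 4), c(3, 3, 3), c(30, 0, 0))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dose(random_dose(geo_dose, 4), f, seed = 9)
  back <- read_dose(f)
  expect_false(doserings:::same_geometry(back$geometry, geo_ct))
})

test_that("structure sets round-trip with perfect overlap", {
  geo <- grid_geometry(c(20, 20, 10), c(3, 3, 3))
  sph <- sphere_mask(geo, c(28, 30, 13), 20)
  two <- binary_mask(pmin(sph$values +
                            sphere_mask(geo, c(10, 10, 5), 6)$values, 1), geo)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_structures(structure_set(list(sphere = sph, blobs = two)), f, seed = 3)
  back <- read_structures(f, geo)
  for (nm in c("sphere", "blobs")) {
    a <- if (nm == "sphere") sph$values else two$values
    b <- back[[nm]]$values
    dice <- 2 * sum(a * b) / (sum(a) + sum(b))
    expect_gte(dice, 0.99)
  }
})

test_that("a 30 mm square contour on a 3 mm grid rasterizes to 100 voxels per slice", {
  geo <- grid_geometry(c(16, 16, 2), c(3, 3, 3))
  # voxel centers at 0, 3, ..., 45 mm; the square [-1.5, 28.5]^2 holds the
  # 10 x 10 block of centers 0..27
  square <- cbind(c(-1.5, 28.5, 28.5, -1.5), c(-1.5, -1.5, 28.5, 28.5))
  loops <- list(list(xy = square, z = 0), list(xy = square, z = 3))
  mask <- rasterize_contours(loops, geo)
  expect_equal(sum(mask$values[, , 1]), 100)
  expect_equal(sum(mask$values[, , 2]), 100)
  # brute-force point-in-polygon agrees voxel by voxel
  for (i in seq_len(16)) for (j in seq_len(16)) {
    expect_equal(mask$values[i, j, 1] == 1,
                 point_in_polygon(axis_coords(geo, 1)[i],
                                  axis_coords(geo, 2)[j], square))
  }
})

test_that("an RTSTRUCT without ROIs yields an empty structure set", {
  geo <- toy_geometry()
  f <- withr::local_tempfile(fileext = ".dcm")
  write_structures(structure_set(list()), f, seed = 1)
  expect_length(read_structures(f, geo)$masks, 0)
})

test_that("resampling honors identity, constants, and the analytic ramp", {
  geo <- grid_geometry(c(8, 8, 8), c(1, 1, 1))
  ramp <- scalar_volume(array(rep(0:7, times = 64), dim = c(8, 8, 8)), geo, "Gy")
  expect_identical(resample(ramp, geo, "linear")$values, ramp$values)
  const <- scalar_volume(array(3.5, dim = c(8, 8, 8)), geo, "HU")
  tg <- grid_geometry(c(5, 5, 5), c(1.3, 1.3, 1.3), c(0.2, 0.2, 0.2))
  expect_true(all(abs(resample(const, tg, "linear")$values - 3.5) < 1e-12))
  # downsample x2: linear interpolation reproduces the ramp at new centers
  tg2 <- grid_geometry(c(4, 4, 4), c(2, 2, 2))
  r <- resample(ramp, tg2, "linear")
  expect_equal(r$values[, 1, 1], c(0, 2, 4, 6), tolerance = 1e-9)
  # masks stay binary under any resampling
  m <- binary_mask((ramp$values > 3) * 1, geo)
  rm <- resample(m, grid_geometry(c(6, 6, 6), c(1.4, 1.4, 1.4)))
  expect_true(all(rm$values %in% c(0, 1)))
  expect_error(grid_geometry(c(4, 4, 4), c(0, 2, 2)), "positive")
})

test_that("structure sets enforce unique names and PTV nesting", {
  geo <- toy_geometry()
  m <- binary_mask(array(1, dim = geo$shape), geo)
  expect_error(structure_set(list(a = m, a = m)), "unique")
  inner <- binary_mask(array(c(1, rep(0, prod(geo$shape) - 1)), dim = geo$shape), geo)
  expect_error(structure_set(list(PTV45 = inner, PTV50 = m)), "subset")
  expect_silent(structure_set(list(PTV45 = m, PTV50 = inner)))
})
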