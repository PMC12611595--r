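test_that("ISO regions code strictly-above voxels 255 and the rest 0", {
  geo <- toy_geometry(c(3, 3, 3))
  vals <- array(0, dim = c(3, 3, 3))
  vals[1, 1, 1] <- 30            # above level 25 -> inside
  vals[2, 1, 1] <- 25            # exactly at the level -> outside (strict >)
  vals[3, 1, 1] <- 24.9
  iso <- make_iso_regions(dose_grid(vals, geo, c(PTV45 = 45)), 45)
  expect_equal(iso$masks[[25]][1, 1, 1], 255)
  expect_equal(iso$masks[[25]][2, 1, 1], 0)
  expect_equal(iso$masks[[25]][3, 1, 1], 0)
  expect_true(all(unlist(iso$masks) %in% c(0, 255)))
  # an all-zero dose has empty regions at every level
  iso0 <- make_iso_regions(dose_grid(array(0, c(3, 3, 3)), geo), 10)
  expect_true(all(vapply(iso0$masks, function(m) all(m == 0), logical(1))))
  expect_error(make_iso_regions(dose_grid(vals, geo), 0), "n must be")
})

test_that("rings partition the level-1 region into 1 Gy dose bands", {
  geo <- toy_geometry(c(5, 5, 5))
  for (seed in 1:10) {
    dose <- random_dose(geo, seed, max_gy = 8, prescriptions = c(PTV45 = 6))
    iso <- make_iso_regions(dose, 6)
    rings <- make_rings(iso)
    total <- Reduce(`+`, lapply(rings$rings, function(r) r$values))
    expect_true(all(total <= 1))                      # pairwise disjoint
    expect_identical(total * 255, iso$masks[[1]])     # union = level-1 region
    for (k in 1:5) {
      d <- dose$values[rings$rings[[k]]$values > 0]
      if (length(d)) expect_true(all(d > k & d <= k + 1))
    }
    dn <- dose$values[rings$rings[[6]]$values > 0]
    if (length(dn)) expect_true(all(dn > 6))
  }
})

test_that("degenerate and invalid ring inputs are handled", {
  geo <- toy_geometry(c(4, 4, 4))
  dose <- random_dose(geo, 2, max_gy = 3, prescriptions = c(PTV45 = 1))
  rings1 <- make_rings(make_iso_regions(dose, 1))
  expect_identical(rings1$rings[["Ring 1"]]$values * 255,
                   make_iso_regions(dose, 1)$masks[[1]])
  bad <- make_iso_regions(dose, 2)
  bad$masks[[2]] <- array(255, dim = geo$shape)  # break the nesting
  expect_error(make_rings(bad), "nesting")
})

test_that("a concentric radial dose yields analytic shell counts per ring", {
  geo <- grid_geometry(c(21, 21, 21), c(1, 1, 1))
  ctr <- rep(10, 3)
  r <- sqrt(outer(outer((axis_coords(geo, 1) - ctr[1])^2,
                        (axis_coords(geo, 2) - ctr[2])^2, "+"),
                  (axis_coords(geo, 3) - ctr[3])^2, "+"))
  dose_vals <- pmax(8 - r, 0)   # radial ramp, 1 Gy per mm
  dose <- dose_grid(dose_vals, geo, c(PTV45 = 6))
  rings <- make_rings(make_iso_regions(dose, 6))
  for (k in 1:5) {
    shell <- sum(dose_vals > k & dose_vals <= k + 1)
    expect_equal(sum(rings$rings[[k]]$values), shell)
  }
})

test_that("ring-organ intersection equals the voxelwise AND", {
  geo <- toy_geometry(c(6, 6, 6))
  set.seed(5)
  a <- binary_mask((array(runif(216), dim = geo$shape) > 0.5) * 1, geo)
  b <- binary_mask((array(runif(216), dim = geo$shape) > 0.5) * 1, geo)
  expect_identical(intersect_ring_organ(a, b)$values, a$values * b$values)
  sub <- binary_mask(a$values * b$values, geo)
  expect_identical(intersect_ring_organ(a, sub)$values, sub$values)
  empty <- binary_mask(array(0, geo$shape), geo)
  expect_true(all(intersect_ring_organ(a, empty)$values == 0))
  other <- binary_mask(array(0, c(5, 5, 5)), toy_geometry(c(5, 5, 5)))
  expect_error(intersect_ring_organ(a, other), "geometr")
})

test_that("ring export keeps levels >= 25 and round-trips through RTSTRUCT", {
  case <- generate_case(phantom_spec(
    seed = 6, geometry = grid_geometry(c(48, 48, 24), c(8, 8, 8))))
  dose <- generate_reference_dose(case)
  rings <- make_rings(make_iso_regions(dose, 45))
  f <- withr::local_tempfile(fileext = ".dcm")
  written <- rings_to_rtstruct(rings, f, min_level = 25, seed = 4)
  expect_false("Ring 24" %in% written)
  expect_true(all(as.integer(sub("Ring ", "", written)) >= 25))
  expect_true("Ring 45" %in% written)
  back <- read_structures(f, dose$geometry)
  for (nm in written) {
    a <- rings$rings[[nm]]$values
    b <- back[[nm]]$values
    expect_gte(2 * sum(a * b) / (sum(a) + sum(b)), 0.95)
  }
  # exporting everything is available as an explicit opt-in
  f2 <- withr::local_tempfile(fileext = ".dcm")
  all_written <- rings_to_rtstruct(rings, f2, export_all_rings = TRUE, seed = 4)
  expect_true("Ring 1" %in% all_written)
  expect_error(rings_to_rtstruct(
    make_rings(make_iso_regions(dose_grid(array(0, c(4, 4, 4)),
                                          toy_geometry(c(4, 4, 4))), 45)),
    withr::local_tempfile()), "empty")
})

test_that("mask contour extraction handles squares, blobs, holes and voxels", {
  geo <- grid_geometry(c(14, 14, 1), c(3, 3, 3))
  sq <- array(0, dim = c(14, 14, 1)); sq[3:12, 3:12, 1] <- 1
  loops <- mask_to_contours(binary_mask(sq, geo))
  expect_length(loops, 1)
  expect_identical(rasterize_contours(loops, geo)$values, sq)
  expect_length(mask_to_contours(binary_mask(array(0, c(14, 14, 1)), geo)), 0)
  blobs <- array(0, dim = c(14, 14, 1))
  blobs[2:4, 2:4, 1] <- 1; blobs[9:12, 9:12, 1] <- 1
  expect_length(mask_to_contours(binary_mask(blobs, geo)), 2)
  # a ring-shaped region emits the hole as a second loop; even-odd
  # rasterization restores the hole
  donut <- array(0, dim = c(14, 14, 1)); donut[4:11, 4:11, 1] <- 1
  donut[6:9, 6:9, 1] <- 0
  dl <- mask_to_contours(binary_mask(donut, geo))
  expect_length(dl, 2)
  expect_identical(rasterize_contours(dl, geo)$values, donut)
  # a single voxel becomes one small square contour
  one <- array(0, dim = c(14, 14, 1)); one[7, 7, 1] <- 1
  ol <- mask_to_contours(binary_mask(one, geo))
  expect_length(ol, 1)
  expect_equal(nrow(ol[[1]]$xy), 4)
})
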