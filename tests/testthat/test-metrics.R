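test_that("the cumulative DVH is a proper survival curve of the dose", {
  geo <- toy_geometry(c(4, 4, 4))
  mask <- binary_mask(array(1, dim = geo$shape), geo)
  uni <- dose_grid(array(45, dim = geo$shape), geo)
  dvh <- cumulative_dvh(uni, mask)
  expect_equal(dvh$volume_fraction[dvh$dose_gy <= 45], rep(1, sum(dvh$dose_gy <= 45)))
  expect_equal(dvh$volume_fraction[dvh$dose_gy > 45], rep(0, sum(dvh$dose_gy > 45)))
  # two voxels at 40 and 50 Gy: half the volume at the 45 Gy edge
  geo2 <- grid_geometry(c(2, 1, 1), c(3, 3, 3))
  two <- dose_grid(array(c(40, 50), dim = c(2, 1, 1)), geo2)
  m2 <- binary_mask(array(1, dim = c(2, 1, 1)), geo2)
  dvh2 <- cumulative_dvh(two, m2)
  expect_equal(dvh2$volume_fraction[which.min(abs(dvh2$dose_gy - 45))], 0.5)
  # monotone non-increasing, starts at 1, ends at 0, for random grids
  for (seed in 1:5) {
    d <- random_dose(toy_geometry(c(6, 6, 6)), seed)
    m <- binary_mask(array(1, dim = c(6, 6, 6)), toy_geometry(c(6, 6, 6)))
    curve <- cumulative_dvh(d, m)
    expect_equal(curve$volume_fraction[1], 1)
    expect_equal(curve$volume_fraction[length(curve$volume_fraction)], 0)
    expect_true(all(diff(curve$volume_fraction) <= 0))
  }
  expect_error(cumulative_dvh(uni, binary_mask(array(0, geo$shape), geo)), "empty")
})

test_that("V_x and D_q agree with direct voxel counting", {
  geo <- toy_geometry(c(6, 6, 6))
  dose <- random_dose(geo, 11)
  mask <- binary_mask((array(runif(216), dim = geo$shape) > 0.3) * 1, geo)
  d <- dose$values[mask$values > 0.5]
  set.seed(12)
  for (lev in runif(20, 0, 55)) {
    expect_equal(v_at(dose, mask, lev), 100 * sum(d >= lev) / length(d))
  }
  dvh <- cumulative_dvh(dose, mask, bin_width = 0.05)
  for (edge in sample(seq_along(dvh$dose_gy), 10)) {
    expect_equal(dvh$volume_fraction[edge], mean(d >= dvh$dose_gy[edge]))
  }
  # duality: at least q% of the volume receives d_at(q), up to the one-voxel
  # slack the interpolated quantile allows
  for (q in c(5, 20, 50, 80, 95)) {
    expect_gte(v_at(dose, mask, d_at(dose, mask, q)) + 100 / length(d), q)
  }
  # d_at is non-increasing in q; a uniform dose returns itself
  qs <- seq(5, 100, by = 5)
  das <- vapply(qs, function(q) d_at(dose, mask, q), numeric(1))
  expect_true(all(diff(das) <= 0))
  uni <- dose_grid(array(42, dim = geo$shape), geo)
  expect_equal(d_at(uni, mask, 95), 42)
  expect_equal(v_at(uni, mask, 42), 100)
  expect_equal(d_mean(uni, mask), 42)
  expect_error(d_at(dose, mask, 0), "q must be")
  expect_error(d_at(dose, mask, 101), "q must be")
})

test_that("D_q interpolates linearly on a 10-voxel ramp", {
  geo <- grid_geometry(c(10, 1, 1), c(3, 3, 3))
  ramp <- dose_grid(array(1:10, dim = c(10, 1, 1)), geo)
  mask <- binary_mask(array(1, dim = c(10, 1, 1)), geo)
  # order statistics 1..10; the 5% point interpolates to 1.45
  expect_equal(d_at(ramp, mask, 95), 1.45)
  expect_equal(d_at(ramp, mask, 5), 9.55)
  expect_equal(homogeneity_index(ramp, mask), 9.55 / 1.45)
  expect_equal(d_mean(ramp, mask), 5.5)
})

test_that("conformity index follows the Paddick formula", {
  geo <- toy_geometry(c(10, 10, 10))
  ptv <- sphere_mask(geo, rep(13.5, 3), 9)
  # dose exactly the prescription on the PTV and zero elsewhere: CI = 1
  perfect <- dose_grid(ptv$values * 45, geo)
  expect_equal(conformity_index(perfect, ptv, 45), 1)
  # PIV twice the PTV with full coverage: CI = 1/2
  tv <- sum(ptv$values)
  outside <- which(ptv$values == 0)[seq_len(tv)]
  vals <- ptv$values * 45
  vals[outside] <- 45
  expect_equal(conformity_index(dose_grid(vals, geo), ptv, 45), 0.5)
  # PIV disjoint from the PTV: CI = 0
  vals2 <- array(0, dim = geo$shape)
  vals2[outside] <- 45
  expect_equal(conformity_index(dose_grid(vals2, geo), ptv, 45), 0)
  # empty PIV warns and returns 0
  expect_warning(ci0 <- conformity_index(dose_grid(array(0, geo$shape), geo),
                                         ptv, 45), "empty")
  expect_equal(ci0, 0)
})

test_that("homogeneity index is 1 for uniform dose and never below 1", {
  geo <- toy_geometry(c(6, 6, 6))
  mask <- binary_mask(array(1, dim = geo$shape), geo)
  expect_equal(homogeneity_index(dose_grid(array(45, geo$shape), geo), mask), 1)
  for (seed in 1:5) {
    expect_gte(homogeneity_index(random_dose(geo, seed, max_gy = 50) , mask), 1)
  }
  expect_error(homogeneity_index(dose_grid(array(0, geo$shape), geo), mask),
               "zero")
})

test_that("DSC per isodose level is symmetric, bounded and exact on identities", {
  geo <- toy_geometry(c(8, 8, 8))
  a <- random_dose(geo, 21)
  b <- random_dose(geo, 22)
  expect_true(all(dsc_curve(a, a, 45)$dsc == 1))
  zero <- dose_grid(array(0, dim = geo$shape), geo)
  za <- dsc_curve(a, zero, 45)
  nonempty <- vapply(za$level_pct, function(L) any(a$values >= 45 * L / 100),
                     logical(1))
  expect_true(all(za$dsc[nonempty] == 0))
  expect_true(all(za$dsc[!nonempty] == 1))  # both empty counts as agreement
  ab <- dsc_curve(a, b, 45); ba <- dsc_curve(b, a, 45)
  expect_equal(ab$dsc, ba$dsc)
  expect_true(all(ab$dsc >= 0 & ab$dsc <= 1))
})

test_that("a shifted spherical dose matches the analytic lens overlap", {
  geo <- grid_geometry(c(40, 40, 40), c(3, 3, 3))
  ctr <- rep(58.5, 3)
  R <- 30
  sph <- sphere_mask(geo, ctr, R)
  dose_a <- dose_grid(sph$values * 45, geo)
  d <- 3
  sph_b <- sphere_mask(geo, ctr + c(d, 0, 0), R)
  dose_b <- dose_grid(sph_b$values * 45, geo)
  dsc <- dsc_curve(dose_a, dose_b, 45, levels_pct = 100)$dsc
  # equal spheres radius R at distance d: lens volume pi (4R+d)(2R-d)^2 / 12
  v_lens <- pi * (4 * R + d) * (2 * R - d)^2 / 12
  v_sph <- 4 / 3 * pi * R^3
  expect_equal(dsc, v_lens / v_sph, tolerance = 0.02)
})
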