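# Shared fixtures and independent oracles, all built in code.

toy_geometry <- function(shape = c(6, 6, 6), spacing = c(3, 3, 3),
                         origin = c(0, 0, 0)) {
  grid_geometry(shape, spacing, origin)
}

random_dose <- function(geo, seed, max_gy = 50, prescriptions = c(PTV45 = 45)) {
  set.seed(seed)
  dose_grid(array(runif(prod(geo$shape), 0, max_gy), dim = geo$shape),
            geo, prescriptions)
}

sphere_mask <- function(geo, center_mm, radius_mm) {
  q <- outer(outer((axis_coords(geo, 1) - center_mm[1])^2,
                   (axis_coords(geo, 2) - center_mm[2])^2, "+"),
             (axis_coords(geo, 3) - center_mm[3])^2, "+")
  binary_mask((q <= radius_mm^2) * 1, geo)
}

# Even-odd point-in-polygon (scalar, direct crossing count); independent of
# the package's rasterizer.
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((xy[i, 2] > py) != (xy[j, 2] > py)) {
      xc <- xy[i, 1] + (py - xy[i, 2]) / (xy[j, 2] - xy[i, 2]) * (xy[j, 1] - xy[i, 1])
      if (px < xc) inside <- !inside
    }
    j <- i
  }
  inside
}

# Exhaustive gamma search: every offset of the interpolation lattice inside
# the search radius, per voxel, with no shortcuts.
oracle_gamma <- function(dose_eval, dose_ref, cr) {
  geo <- dose_ref$geometry
  rmax <- max(dose_ref$values)
  sq <- seq(-cr$search_radius_mm, cr$search_radius_mm, by = cr$step_mm)
  offs <- as.matrix(expand.grid(x = sq, y = sq, z = sq))
  offs <- offs[rowSums(offs^2) <= cr$search_radius_mm^2 + 1e-9, , drop = FALSE]
  r2 <- rowSums(offs^2)
  out <- array(NA_real_, geo$shape)
  for (i in seq_len(geo$shape[1])) for (j in seq_len(geo$shape[2])) {
    for (k in seq_len(geo$shape[3])) {
      rv <- dose_ref$values[i, j, k]
      if (rv < cr$threshold_pct / 100 * rmax) next
      ddc <- if (cr$normalization == "global") cr$dd_pct / 100 * rmax
             else cr$dd_pct / 100 * rv
      p0 <- c(axis_coords(geo, 1)[i], axis_coords(geo, 2)[j],
              axis_coords(geo, 3)[k])
      de <- doserings:::sample_points_trilinear(
        dose_eval$values, dose_eval$geometry, sweep(offs, 2, p0, "+"))
      g2 <- r2 / cr$dta_mm^2 + ((de - rv) / ddc)^2
      out[i, j, k] <- sqrt(min(g2, na.rm = TRUE))
    }
  }
  out
}

# A SIB case together with a second reference dose whose 50 Gy boost is
# deliberately shifted two voxels along x (the steep-gradient disagreement
# regime).
sib_misregistered_pair <- function(seed = 5) {
  spec <- phantom_spec(seed = seed, case_type = "SIB",
                       geometry = grid_geometry(c(64, 64, 32), c(6, 6, 6)))
  case <- generate_case(spec)
  ref <- generate_reference_dose(case)
  st <- case$structures$masks
  m <- st$PTV50$values
  nx <- dim(m)[1]
  m2 <- m * 0
  m2[3:nx, , ] <- m[1:(nx - 2), , ]
  st$PTV50 <- binary_mask(m2 * st$PTV45$values, case$ct$geometry)
  case_b <- patient_case(case$ct, structure_set(st),
                         modality = case$modality, case_type = "SIB")
  list(case = case, ref = ref, ref_shifted_boost = generate_reference_dose(case_b))
}

overfit_phantom_case <- function(seed = 1) {
  spec <- phantom_spec(seed = seed,
                       geometry = grid_geometry(c(32, 32, 32), c(9, 9, 9)))
  case <- generate_case(spec)
  case$dose <- generate_reference_dose(case)
  case
}

golden_template_path <- function(name) {
  system.file("extdata", "templates", paste0(name, ".tsv"),
              package = "doserings", mustWork = TRUE)
}
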