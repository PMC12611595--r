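# Synthetic pelvic phantom generator: CT-like volume, target and OAR masks,
# and a distance-transform-based reference dose. Stands in for clinical
# cohorts so the full pipeline is testable without patient data.

#' Phantom specification
#'
#' Defines one synthetic pelvic case. Default target volume goals follow the
#' cohort averages the generator emulates: PTV45 of 1098 cm^3 for VMAT and
#' 1447 cm^3 for IMRT, PTV50 of 116 cm^3 for simultaneous-integrated-boost
#' (SIB) cases.
#'
#' @param seed integer; fixes every random draw, so equal seeds give
#'   voxel-identical cases.
#' @param modality `"VMAT"` or `"IMRT"`.
#' @param case_type `"single"` or `"SIB"` (SIB adds a 50 Gy boost target).
#' @param geometry grid, default 128 x 128 x 64 voxels at 3 mm.
#' @param ptv45_cc,ptv50_cc target volume goals in cm^3; `NULL` picks the
#'   modality default.
#' @param jitter_mm half-range of uniform positional jitter applied to
#'   structure centers (mm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         modality = c("VMAT", "IMRT"),
                         case_type = c("single", "SIB"),
                         geometry = grid_geometry(c(128, 128, 64), c(3, 3, 3)),
                         ptv45_cc = NULL, ptv50_cc = NULL,
                         jitter_mm = 6) {
  modality <- match.arg(modality)
  case_type <- match.arg(case_type)
  if (is.null(ptv45_cc)) ptv45_cc <- if (modality == "VMAT") 1098 else 1447
  if (is.null(ptv50_cc)) ptv50_cc <- 116
  stopifnot(ptv45_cc > 0, ptv50_cc > 0, jitter_mm >= 0)
  structure(list(seed = as.integer(seed), modality = modality,
                 case_type = case_type, geometry = geometry,
                 ptv45_cc = ptv45_cc, ptv50_cc = ptv50_cc,
                 jitter_mm = jitter_mm),
            class = "phantom_spec")
}

#' Reference dose model parameters
#'
#' The phantom's reference dose is a logistic falloff of the signed Euclidean
#' distance to the target surface — not a beam model, but it yields
#' clinically shaped DVHs and the steep boost gradients that matter for
#' ring discretization and DSC analysis.
#'
#' @param sigma_mm penumbra width of the logistic falloff (mm).
#' @param cap_frac maximum dose as a fraction of the highest prescription.
#' @param oar_sparing fractional dose reduction inside OAR-minus-PTV
#'   regions, blended smoothly at the region boundary.
#' @return An object of class `dose_model_params`.
#' @export
dose_model_params <- function(sigma_mm = 8, cap_frac = 1.10, oar_sparing = 0.15) {
  stopifnot(sigma_mm > 0, cap_frac >= 1, oar_sparing >= 0, oar_sparing < 1)
  structure(list(sigma_mm = sigma_mm, cap_frac = cap_frac,
                 oar_sparing = oar_sparing),
            class = "dose_model_params")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Soft-min quadratic field of a set of ellipsoids; mask = field <= 1 is a
# smoothed union. centers: m x 3 mm, semi: m x 3 mm.
ellipsoid_union_field <- function(geometry, centers, semi, tau = 0.15) {
  xs <- axis_coords(geometry, 1); ys <- axis_coords(geometry, 2)
  zs <- axis_coords(geometry, 3)
  n <- geometry$shape
  field <- NULL
  for (e in seq_len(nrow(centers))) {
    qx <- ((xs - centers[e, 1]) / semi[e, 1])^2
    qy <- ((ys - centers[e, 2]) / semi[e, 2])^2
    qz <- ((zs - centers[e, 3]) / semi[e, 3])^2
    q <- outer(outer(qx, qy, "+"), qz, "+")
    contrib <- exp(-q / tau)
    field <- if (is.null(field)) contrib else field + contrib
  }
  -tau * log(pmax(field, 1e-300))
}

calibrated_union_mask <- function(geometry, centers, semi, goal_cc,
                                  clip = NULL, iters = 3) {
  vox_cc <- voxel_volume_cm3(geometry)
  mask <- NULL
  for (it in seq_len(iters)) {
    field <- ellipsoid_union_field(geometry, centers, semi)
    m <- (field <= 1) * 1
    if (!is.null(clip)) m <- m * clip
    ach <- sum(m) * vox_cc
    if (ach == 0) stop("calibrated_union_mask: structure vanished during calibration")
    mask <- m
    if (abs(ach - goal_cc) / goal_cc < 0.02) break
    semi <- semi * (goal_cc / ach)^(1 / 3)
  }
  list(mask = mask, semi = semi)
}

#' Generate a synthetic pelvic case
#'
#' Builds an elliptical soft-tissue body (~40 HU with Gaussian texture) in an
#' air background (-1000 HU), bony femoral-head inserts (~700 HU), a PTV45
#' target as a smoothed union of jittered ellipsoids calibrated to the volume
#' goal, an interior PTV50 boost for SIB cases, and ellipsoidal/tubular OARs
#' (bladder anterior, rectum posterior, small intestine superior, femoral
#' heads lateral). All structures are clipped to the Body; femoral heads are
#' kept disjoint from the PTV.
#'
#' @param spec a [phantom_spec()].
#' @return A [patient_case()] without dose (see [generate_reference_dose()]).
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- spec$geometry
  extent <- geo$spacing * geo$shape
  # feasibility: the sphere-equivalent PTV diameter must fit inside the body
  req_r <- (3 * spec$ptv45_cc * 1000 / (4 * pi))^(1 / 3)
  lim <- 0.40 * extent
  if (any(req_r > lim)) {
    stop(sprintf("PTV45 volume goal %.0f cm^3 needs radius %.0f mm; axis %s extent %.0f mm is too small",
                 spec$ptv45_cc, req_r, c("x", "y", "z")[which(req_r > lim)[1]],
                 extent[which(req_r > lim)[1]]))
  }
  with_seed(spec$seed, {
    center <- geo$origin + extent / 2
    jit <- function(n = 3) stats::runif(n, -spec$jitter_mm, spec$jitter_mm)
    xs <- axis_coords(geo, 1); ys <- axis_coords(geo, 2); zs <- axis_coords(geo, 3)

    # Body: elliptical cylinder over the full z range
    body_ab <- c(0.44, 0.36) * extent[1:2]
    q <- outer(((xs - center[1]) / body_ab[1])^2,
               ((ys - center[2]) / body_ab[2])^2, "+")
    body2d <- q <= 1
    body <- array(rep(body2d, geo$shape[3]), dim = geo$shape) * 1

    # PTV45: primary ellipsoid plus two overlapping lobes, volume-calibrated
    pc <- center + jit()
    base_r <- req_r * c(1.05, 0.95, 1.0) * stats::runif(3, 0.92, 1.08)
    lobe_off <- rbind(c(0, 0, 0),
                      c(0.6, 0.2, 0.3) * base_r * sample(c(-1, 1), 3, TRUE),
                      c(-0.3, 0.5, -0.4) * base_r * sample(c(-1, 1), 3, TRUE))
    centers45 <- sweep(lobe_off, 2, pc, "+")
    semi45 <- rbind(base_r, base_r * 0.55, base_r * 0.45)
    cal45 <- calibrated_union_mask(geo, centers45, semi45, spec$ptv45_cc, clip = body)
    ptv45 <- cal45$mask

    ptv50 <- NULL
    if (spec$case_type == "SIB") {
      r50 <- (3 * spec$ptv50_cc * 1000 / (4 * pi))^(1 / 3)
      c50 <- pc + jit() * 0.8
      cal50 <- calibrated_union_mask(geo, rbind(c50),
                                     rbind(r50 * stats::runif(3, 0.9, 1.1)),
                                     spec$ptv50_cc, clip = ptv45)
      ptv50 <- cal50$mask
    }

    # OARs (plausible pelvic defaults; sizes are not cohort-calibrated)
    ptv_front <- pc[2] - cal45$semi[1, 2]
    bladder_c <- c(center[1] + jit(1), ptv_front - 18 + jit(1), pc[3] + jit(1))
    bladder <- calibrated_union_mask(geo, rbind(bladder_c),
                                     rbind(c(45, 35, 40)), 250, clip = body)$mask
    rectum_c <- c(center[1] + jit(1), pc[2] + cal45$semi[1, 2] + 12 + jit(1), pc[3])
    rectum <- calibrated_union_mask(geo, rbind(rectum_c),
                                    rbind(c(16, 16, 70)), 90, clip = body)$mask
    bowel_c <- c(center[1] + jit(1), center[2] - 20 + jit(1),
                 pc[3] + cal45$semi[1, 3] + 25 + jit(1))
    bowel <- calibrated_union_mask(geo, rbind(bowel_c),
                                   rbind(c(90, 60, 45)), 500, clip = body)$mask
    fem_r <- 23
    fem_y <- center[2] + 10
    feml_c <- c(center[1] - 0.80 * body_ab[1] + jit(1) * 0.5, fem_y + jit(1), pc[3] + jit(1))
    femr_c <- c(center[1] + 0.80 * body_ab[1] + jit(1) * 0.5, fem_y + jit(1), pc[3] + jit(1))
    feml <- calibrated_union_mask(geo, rbind(feml_c), rbind(rep(fem_r, 3)),
                                  50, clip = body)$mask
    femr <- calibrated_union_mask(geo, rbind(femr_c), rbind(rep(fem_r, 3)),
                                  50, clip = body)$mask
    feml <- feml * (1 - ptv45)   # femoral heads never overlap the target
    femr <- femr * (1 - ptv45)

    # CT: class-constant HU plus mild Gaussian texture
    hu <- array(-1000, dim = geo$shape)
    nb <- sum(body > 0)
    hu[body > 0] <- 40 + stats::rnorm(nb, 0, 12)
    bone <- (feml + femr) > 0
    hu[bone] <- 700 + stats::rnorm(sum(bone), 0, 25)
    hu <- pmin(pmax(hu, -1000), 1000)

    masks <- list(
      Body = binary_mask(body, geo),
      PTV45 = binary_mask(ptv45, geo),
      bladder = binary_mask(bladder, geo),
      rectum = binary_mask(rectum, geo),
      small_intestine = binary_mask(bowel, geo),
      femoral_head_l = binary_mask(feml, geo),
      femoral_head_r = binary_mask(femr, geo))
    if (!is.null(ptv50)) {
      masks <- append(masks, list(PTV50 = binary_mask(ptv50, geo)), after = 2)
    }
    patient_case(scalar_volume(hu, geo, "HU"), structure_set(masks),
                 modality = spec$modality, case_type = spec$case_type)
  })
}

#' Signed Euclidean distance to a mask surface
#'
#' @param mask a [binary_mask()].
#' @return Array of signed distances in mm: negative inside the mask,
#'   positive outside (voxel-center distances).
#' @export
signed_distance_mm <- function(mask) {
  geo <- mask$geometry
  d_out <- sqrt(cpp_sedt(mask$values, geo$spacing))        # 0 inside
  d_in <- sqrt(cpp_sedt(1 - mask$values, geo$spacing))     # 0 outside
  d_out - d_in
}

#' Generate the phantom's reference dose
#'
#' Dose is `Rx * plogis(-d / sigma)` with `d` the signed distance to the
#' PTV45 surface (negative inside, so in-target dose approaches the
#' prescription). SIB cases add an analogous 5 Gy boost term toward 50 Gy
#' inside PTV50. Dose inside OAR-minus-PTV regions is reduced by the sparing
#' depth with smooth blending, the result is capped at
#' `cap_frac * max(prescription)`, and finally [renormalize_plan()] enforces
#' the 95% coverage rule per target.
#'
#' Renormalization scales the whole grid (boundary voxels of a logistic
#' falloff sit near half the prescription, so the factor is well above 1);
#' the raw falloff model — for which the dose a distance `3 * sigma` outside
#' the target is below 5% of the prescription — can be inspected with
#' `renormalize = FALSE`.
#'
#' @param case a [patient_case()] with structures.
#' @param params a [dose_model_params()].
#' @param renormalize apply the coverage renormalization (default) or return
#'   the raw falloff model.
#' @return A [dose_grid()].
#' @export
generate_reference_dose <- function(case, params = dose_model_params(),
                                    renormalize = TRUE) {
  stopifnot(inherits(case, "patient_case"), inherits(params, "dose_model_params"))
  st <- case$structures
  if (is.null(st[["PTV45"]])) stop("generate_reference_dose: case has no PTV45")
  geo <- case$ct$geometry
  d45 <- signed_distance_mm(st[["PTV45"]])
  dose <- 45 * stats::plogis(-d45 / params$sigma_mm)
  sib <- case$case_type == "SIB" && !is.null(st[["PTV50"]])
  if (sib) {
    d50 <- signed_distance_mm(st[["PTV50"]])
    dose <- dose + 5 * stats::plogis(-d50 / params$sigma_mm)
  }
  # OAR sparing with smooth blending at the region edge
  oar_names <- intersect(c("bladder", "rectum", "small_intestine",
                           "femoral_head_l", "femoral_head_r"), names(st))
  if (length(oar_names) > 0 && params$oar_sparing > 0) {
    u <- Reduce(`+`, lapply(oar_names, function(nm) st[[nm]]$values))
    u <- (u > 0) * (1 - st[["PTV45"]]$values)
    if (any(u > 0)) {
      du <- signed_distance_mm(binary_mask(u, geo))
      w <- stats::plogis(-du / (params$sigma_mm / 2))
      dose <- dose * (1 - params$oar_sparing * w)
    }
  }
  cap <- params$cap_frac * if (sib) 50 else 45
  prescriptions <- if (sib) c(PTV45 = 45, PTV50 = 50) else c(PTV45 = 45)
  dg <- dose_grid(pmin(pmax(dose, 0), cap), geo, prescriptions)
  if (renormalize) {
    dg <- renormalize_plan(dg, st[["PTV45"]], 45)$dose
    if (sib) dg <- renormalize_plan(dg, st[["PTV50"]], 50)$dose
    dg$values <- pmin(dg$values, cap)
  }
  dg
}

#' Perturb a dose grid
#'
#' Applies a rigid translation (trilinear interpolation; regions shifted in
#' from outside the original extent become 0) followed by multiplicative
#' Gaussian noise `dose * (1 + noise_frac * N(0,1))`, clamped at 0.
#' Deterministic for a fixed seed. Used to produce controlled disagreement
#' for DSC and gamma testing.
#'
#' @param dose a [dose_grid()].
#' @param seed integer RNG seed for the noise.
#' @param shift_mm numeric length 3 (or scalar, applied to x) translation of
#'   the dose distribution in mm.
#' @param noise_frac fractional noise magnitude (0 disables).
#' @return A [dose_grid()] on the same geometry.
#' @export
perturb_dose <- function(dose, seed = 1L, shift_mm = c(0, 0, 0), noise_frac = 0) {
  stopifnot(inherits(dose, "dose_grid"))
  if (length(shift_mm) == 1) shift_mm <- c(shift_mm, 0, 0)
  geo <- dose$geometry
  vals <- dose$values
  if (any(shift_mm != 0)) {
    vals <- sample_volume_at(dose$values, geo,
                             xs = axis_coords(geo, 1) - shift_mm[1],
                             ys = axis_coords(geo, 2) - shift_mm[2],
                             zs = axis_coords(geo, 3) - shift_mm[3],
                             mode = "linear", background = 0)
  }
  if (noise_frac > 0) {
    vals <- with_seed(seed, vals * (1 + noise_frac * stats::rnorm(length(vals))))
  }
  dose_grid(pmax(vals, 0), geo, dose$prescriptions)
}
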