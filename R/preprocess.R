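# Input conditioning for dose prediction: CT windowing and normalization,
# isotropic resampling, dose normalization, and plan renormalization.

#' Preprocessing configuration
#'
#' @param window_width,window_level CT display window in HU (defaults 600 /
#'   40, i.e. clamp to `[-260, 340]` before mapping to `[0, 1]`).
#' @param hu_clamp outer HU clamp interval; the default `[-1000, 1000]` is
#'   dominated by the window clamp and therefore inert by default.
#' @param target_spacing isotropic resampling target in mm (default 3).
#' @param dose_norm_max_gy normalization maximum in Gy; `NULL` selects the
#'   modality default at call time (55 for VMAT, 50 for IMRT).
#' @param coverage_pct target coverage threshold for plan renormalization
#'   (percent of structure volume, default 95).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(window_width = 600, window_level = 40,
                              hu_clamp = c(-1000, 1000),
                              target_spacing = c(3, 3, 3),
                              dose_norm_max_gy = NULL,
                              coverage_pct = 95) {
  stopifnot(window_width > 0, length(target_spacing) == 3,
            all(target_spacing > 0), coverage_pct > 0, coverage_pct <= 100)
  structure(list(window_width = window_width, window_level = window_level,
                 hu_clamp = hu_clamp, target_spacing = target_spacing,
                 dose_norm_max_gy = dose_norm_max_gy,
                 coverage_pct = coverage_pct),
            class = "preprocess_config")
}

dose_norm_max <- function(config, modality) {
  if (!is.null(config$dose_norm_max_gy)) return(config$dose_norm_max_gy)
  if (modality == "VMAT") 55 else 50
}

#' Window and normalize a CT volume
#'
#' Clamps HU to the window `[level - width/2, level + width/2]` (the default
#' 600/40 window gives `[-260, 340]`) after the outer `hu_clamp`, then maps
#' the window linearly to `[0, 1]`. Monotone non-decreasing in HU.
#'
#' @param ct a [scalar_volume()] with unit HU.
#' @param config a [preprocess_config()].
#' @return A unitless [scalar_volume()] with values in `[0, 1]`.
#' @export
window_normalize_ct <- function(ct, config = preprocess_config()) {
  stopifnot(inherits(ct, "scalar_volume"), ct$unit == "HU")
  lo <- config$window_level - config$window_width / 2
  hi <- config$window_level + config$window_width / 2
  v <- pmin(pmax(ct$values, config$hu_clamp[1]), config$hu_clamp[2])
  v <- (pmin(pmax(v, lo), hi) - lo) / (hi - lo)
  scalar_volume(v, ct$geometry, "unitless")
}

#' Resample a case to the target isotropic grid
#'
#' CT and dose are interpolated trilinearly, masks with nearest neighbour;
#' all members end up on one grid at `config$target_spacing` covering the
#' original extent.
#'
#' @param case a [patient_case()].
#' @param config a [preprocess_config()].
#' @return A [patient_case()] on the resampled grid.
#' @export
resample_case <- function(case, config = preprocess_config()) {
  stopifnot(inherits(case, "patient_case"))
  geo <- case$ct$geometry
  sp <- config$target_spacing
  if (all(abs(geo$spacing - sp) < 1e-9)) return(case)
  extent <- geo$spacing * (geo$shape - 1)
  shape <- pmax(floor(extent / sp) + 1, 1)
  target <- grid_geometry(shape, sp, geo$origin)
  ct <- resample(case$ct, target, "linear")
  masks <- lapply(case$structures$masks, resample, target = target, mode = "nearest")
  dose <- if (!is.null(case$dose)) resample(case$dose, target, "linear")
  patient_case(ct, structure_set(masks), dose,
               modality = case$modality, case_type = case$case_type)
}

#' Normalize a dose grid to the modality maximum
#'
#' Divides by the normalization maximum (55 Gy VMAT, 50 Gy IMRT by default).
#' Values above the maximum are clipped with a warning reporting the count.
#'
#' @param dose a [dose_grid()].
#' @param modality `"VMAT"` or `"IMRT"` (picks the default maximum).
#' @param config a [preprocess_config()].
#' @return A unitless [scalar_volume()] in `[0, 1]`, with the maximum used
#'   stored in attribute `"dose_norm_max_gy"`.
#' @export
normalize_dose <- function(dose, modality = "VMAT", config = preprocess_config()) {
  stopifnot(inherits(dose, "dose_grid"))
  dmax <- dose_norm_max(config, modality)
  if (dmax < max(dose$prescriptions)) {
    stop("normalize_dose: normalization maximum below the largest prescription")
  }
  n_over <- sum(dose$values > dmax)
  if (n_over > 0) {
    warning(sprintf("normalize_dose: %d voxels above %g Gy were clipped", n_over, dmax))
  }
  out <- scalar_volume(pmin(dose$values, dmax) / dmax, dose$geometry, "unitless")
  attr(out, "dose_norm_max_gy") <- dmax
  out
}

#' Invert [normalize_dose()]
#'
#' Exact inverse on unclipped inputs.
#'
#' @param volume unitless [scalar_volume()] from [normalize_dose()].
#' @param prescriptions named prescription vector for the resulting grid.
#' @param modality,config as in [normalize_dose()].
#' @return A [dose_grid()] in Gy.
#' @export
denormalize_dose <- function(volume, prescriptions = c(PTV45 = 45),
                             modality = "VMAT", config = preprocess_config()) {
  stopifnot(inherits(volume, "scalar_volume"))
  dmax <- attr(volume, "dose_norm_max_gy")
  if (is.null(dmax)) dmax <- dose_norm_max(config, modality)
  dose_grid(pmax(volume$values * dmax, 0), volume$geometry, prescriptions)
}

#' Renormalize a plan to the coverage rule
#'
#' If less than `coverage_pct` percent of the target receives the
#' prescription, the whole grid is scaled by
#' `prescription / D_threshold` — where `D_threshold` is the dose received by
#' `coverage_pct`% of the target (linear-interpolation quantile) — so that
#' coverage meets the threshold exactly. An already-compliant plan is
#' returned unchanged with factor 1.
#'
#' @param dose a [dose_grid()].
#' @param ptv a non-empty [binary_mask()] for the target.
#' @param prescription the target's prescription in Gy.
#' @param config a [preprocess_config()] (supplies `coverage_pct`).
#' @return `list(dose = <dose_grid>, factor = <scaling applied>)`.
#' @export
renormalize_plan <- function(dose, ptv, prescription,
                             config = preprocess_config()) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ptv, "binary_mask"))
  if (sum(ptv$values) == 0) stop("renormalize_plan: PTV mask is empty")
  thr <- config$coverage_pct
  cov <- v_at(dose, ptv, prescription)
  if (cov >= thr) {
    return(list(dose = dose, factor = 1))
  }
  d_thr <- d_at(dose, ptv, thr)
  if (d_thr <= 0) stop("renormalize_plan: D_threshold is zero; cannot rescale")
  factor <- prescription / d_thr
  out <- dose_grid(dose$values * factor, dose$geometry, dose$prescriptions)
  if (v_at(out, ptv, prescription) < thr) {
    # the interpolated quantile can leave coverage a hair short; fall back to
    # the exact order statistic (largest dose with >= thr% of voxels at or
    # above it) which guarantees the threshold
    d <- sort(mask_doses(dose, ptv), decreasing = TRUE)
    d_thr <- d[ceiling(thr / 100 * length(d))]
    factor <- prescription / d_thr
    out <- dose_grid(dose$values * factor, dose$geometry, dose$prescriptions)
  }
  list(dose = out, factor = factor)
}
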