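#' Grid geometry of a voxel lattice
#'
#' Describes an axis-aligned 3D voxel lattice in the DICOM patient (LPS)
#' coordinate frame. Voxel indices are 0-based in the coordinate mapping:
#' the patient-space position of voxel `(i, j, k)` is
#' `origin + spacing * c(i, j, k)`, i.e. `origin` is the position of the
#' *center* of the first voxel. Only identity (axis-aligned) orientation is
#' supported; oblique grids are rejected at the I/O boundary.
#'
#' @param shape integer vector of length 3, voxel counts per axis (x, y, z).
#' @param spacing numeric vector of length 3, voxel size in mm per axis.
#' @param origin numeric vector of length 3, mm position of the first voxel
#'   center (default `c(0, 0, 0)`).
#' @return An object of class `grid_geometry`.
#' @examples
#' geo <- grid_geometry(c(64, 64, 32), c(3, 3, 3))
#' voxel_volume_cm3(geo)
#' @export
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid_geometry: all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid_geometry: all spacings must be positive and finite")
  }
  if (any(!is.finite(origin))) stop("grid_geometry: origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm [LPS, voxel-center]\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("%dx%dx%d @ %gx%gx%g mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Voxel volume of a grid geometry
#'
#' @param geometry a [grid_geometry()].
#' @return Volume of one voxel in cm^3.
#' @export
voxel_volume_cm3 <- function(geometry) {
  prod(geometry$spacing) / 1000
}

#' Axis coordinates of voxel centers
#'
#' @param geometry a [grid_geometry()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of patient-space mm coordinates of voxel centers
#'   along the axis.
#' @export
axis_coords <- function(geometry, axis) {
  geometry$origin[axis] + geometry$spacing[axis] * (seq_len(geometry$shape[axis]) - 1)
}

#' Scalar volume on a grid
#'
#' A 3D scalar lattice (CT, dose, or unitless) bound to a [grid_geometry()].
#'
#' @param values 3D numeric array matching `geometry$shape`.
#' @param geometry a [grid_geometry()].
#' @param unit one of `"HU"`, `"Gy"`, `"unitless"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, geometry, unit = c("unitless", "HU", "Gy")) {
  unit <- match.arg(unit)
  values <- as_array3d(values, geometry$shape)
  if (any(!is.finite(values))) stop("scalar_volume: all values must be finite")
  structure(list(values = values, geometry = geometry, unit = unit),
            class = "scalar_volume")
}

as_array3d <- function(values, shape) {
  if (is.null(dim(values))) {
    if (length(values) == 1L) values <- array(values, dim = shape)
    else if (length(values) == prod(shape)) dim(values) <- shape
    else stop("values length does not match geometry shape")
  }
  if (length(dim(values)) != 3L || !all(dim(values) == shape)) {
    stop(sprintf("values dimensions (%s) do not match geometry shape (%s)",
                 paste(dim(values), collapse = "x"),
                 paste(shape, collapse = "x")))
  }
  storage.mode(values) <- "double"
  values
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> [%s] %s, range [%.4g, %.4g]\n", x$unit,
              format(x$geometry), min(x$values), max(x$values)))
  invisible(x)
}

#' Dose grid
#'
#' A [scalar_volume()] in Gy plus the prescription dose(s) of the plan it
#' represents. Prescriptions are a named numeric vector in Gy, e.g.
#' `c(PTV45 = 45)` or `c(PTV45 = 45, PTV50 = 50)` for a simultaneous
#' integrated boost (SIB) plan.
#'
#' @param values 3D numeric array of absolute dose in Gy (non-negative).
#' @param geometry a [grid_geometry()].
#' @param prescriptions named numeric vector of prescription doses in Gy.
#' @return An object of class `dose_grid` (inherits `scalar_volume`).
#' @export
dose_grid <- function(values, geometry, prescriptions = c(PTV45 = 45)) {
  vol <- scalar_volume(values, geometry, unit = "Gy")
  if (any(vol$values < 0)) stop("dose_grid: dose values must be non-negative")
  if (length(prescriptions) < 1 || any(prescriptions <= 0)) {
    stop("dose_grid: at least one positive prescription is required")
  }
  vol$prescriptions <- sort(prescriptions)  # ascending, names kept
  class(vol) <- c("dose_grid", "scalar_volume")
  vol
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s, max %.3f Gy, prescription(s): %s\n",
              format(x$geometry), max(x$values),
              paste(sprintf("%s=%g Gy", names(x$prescriptions), x$prescriptions),
                    collapse = ", ")))
  invisible(x)
}

#' Highest prescription of a dose grid
#' @param dose a [dose_grid()].
#' @return The largest prescription in Gy.
#' @export
prescription_max <- function(dose) {
  max(dose$prescriptions)
}

#' Binary mask on a grid
#'
#' @param values 3D array over \{0, 1\} (logical or numeric) matching the
#'   geometry shape.
#' @param geometry a [grid_geometry()].
#' @return An object of class `binary_mask`; values are stored as 0/1 doubles.
#' @export
binary_mask <- function(values, geometry) {
  if (is.logical(values)) values <- values * 1
  values <- as_array3d(values, geometry$shape)
  if (!all(values %in% c(0, 1))) stop("binary_mask: values must be 0 or 1")
  structure(list(values = values, geometry = geometry),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %d voxels set (%.1f cm^3)\n",
              format(x$geometry), sum(x$values),
              mask_volume_cm3(x)))
  invisible(x)
}

#' Volume of a binary mask
#' @param mask a [binary_mask()].
#' @return Volume in cm^3 (voxel count times voxel volume; partial-volume
#'   effects are ignored).
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$values) * voxel_volume_cm3(mask$geometry)
}

#' Structure set
#'
#' Named collection of [binary_mask()]s sharing one geometry. Conventional
#' roles: `Body`, targets `PTV45` (and `PTV50` for SIB cases), and organs at
#' risk from \{bladder, rectum, small intestine, femoral heads\}.
#'
#' @param masks named list of [binary_mask()]s with unique names.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks) {
  if (length(masks) > 0) {
    nms <- names(masks)
    if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
      stop("structure_set: masks must have unique non-empty names")
    }
    geo <- masks[[1]]$geometry
    for (m in masks) {
      if (!inherits(m, "binary_mask")) stop("structure_set: all members must be binary_mask")
      if (!same_geometry(m$geometry, geo)) stop("structure_set: masks must share one geometry")
    }
    if (all(c("PTV45", "PTV50") %in% nms)) {
      if (any(masks$PTV50$values > masks$PTV45$values)) {
        stop("structure_set: PTV50 must be a subset of PTV45")
      }
    }
  }
  structure(list(masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures: %s\n", length(x$masks),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' @export
names.structure_set <- function(x) names(x$masks)

#' @export
`[[.structure_set` <- function(x, name) x$masks[[name]]

#' @export
length.structure_set <- function(x) length(x$masks)

#' Patient case
#'
#' Bundles the CT volume, structure set and (optionally) a dose grid for one
#' case, plus the delivery modality and case type.
#'
#' @param ct a [scalar_volume()] with unit HU.
#' @param structures a [structure_set()].
#' @param dose optional [dose_grid()].
#' @param modality `"VMAT"` or `"IMRT"`.
#' @param case_type `"single"` (one 45 Gy target) or `"SIB"`
#'   (simultaneous integrated boost, 45 + 50 Gy).
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(ct, structures, dose = NULL,
                         modality = c("VMAT", "IMRT"),
                         case_type = c("single", "SIB")) {
  modality <- match.arg(modality)
  case_type <- match.arg(case_type)
  stopifnot(inherits(ct, "scalar_volume"), ct$unit == "HU",
            inherits(structures, "structure_set"))
  if (length(structures$masks) > 0 &&
      !same_geometry(ct$geometry, structures$masks[[1]]$geometry)) {
    stop("patient_case: CT and structures must share one geometry")
  }
  if (!is.null(dose)) {
    stopifnot(inherits(dose, "dose_grid"))
    if (!same_geometry(ct$geometry, dose$geometry)) {
      stop("patient_case: CT and dose must share one geometry")
    }
  }
  structure(list(ct = ct, structures = structures, dose = dose,
                 modality = modality, case_type = case_type),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s %s, %s\n", x$modality, x$case_type,
              format(x$ct$geometry)))
  cat(sprintf("  structures: %s\n", paste(names(x$structures), collapse = ", ")))
  if (!is.null(x$dose)) cat(sprintf("  dose: max %.2f Gy\n", max(x$dose$values)))
  invisible(x)
}
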