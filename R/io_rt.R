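SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

IDENTITY_ORIENTATION <- c(1, 0, 0, 0, 1, 0)

check_orientation <- function(iop, what) {
  if (is.null(iop)) return(invisible(TRUE))
  if (max(abs(iop - IDENTITY_ORIENTATION)) > 1e-6) {
    stop(sprintf("%s: unsupported orientation (only axis-aligned identity is supported)",
                 what))
  }
  invisible(TRUE)
}

#' Write a CT series to DICOM files
#'
#' Writes one DICOM CT image per axial slice. Hounsfield units are stored as
#' unsigned 16-bit pixels with rescale slope 1 and intercept -1024; HU outside
#' `[-1024, 3071]` are clamped.
#'
#' @param ct a [scalar_volume()] with unit `"HU"`.
#' @param dir output directory (created if missing).
#' @param seed optional integer; when supplied, generated DICOM UIDs are
#'   reproducible.
#' @return Invisibly, the vector of file paths written (one per slice).
#' @seealso [read_ct_series()]
#' @export
write_ct_series <- function(ct, dir, seed = NULL) {
  stopifnot(inherits(ct, "scalar_volume"), ct$unit == "HU")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  uid <- dcm_uid_factory(seed)
  study_uid <- uid(); series_uid <- uid(); frame_uid <- uid()
  geo <- ct$geometry
  nz <- geo$shape[3]
  zs <- axis_coords(geo, 3)
  paths <- character(nz)
  for (k in seq_len(nz)) {
    stored <- round(pmin(pmax(ct$values[, , k], -1024), 3071)) + 1024
    sop_uid <- uid()
    ds <- list(
      "0008,0016" = dcm_element("UI", SOP_CT),
      "0008,0018" = dcm_element("UI", sop_uid),
      "0008,0060" = dcm_element("CS", "CT"),
      "0020,000D" = dcm_element("UI", study_uid),
      "0020,000E" = dcm_element("UI", series_uid),
      "0020,0052" = dcm_element("UI", frame_uid),
      "0020,0013" = dcm_element("IS", k),
      "0020,0032" = dcm_element("DS", c(geo$origin[1], geo$origin[2], zs[k])),
      "0020,0037" = dcm_element("DS", IDENTITY_ORIENTATION),
      "0028,0002" = dcm_element("US", 1),
      "0028,0004" = dcm_element("CS", "MONOCHROME2"),
      "0028,0010" = dcm_element("US", geo$shape[2]),   # Rows (y)
      "0028,0011" = dcm_element("US", geo$shape[1]),   # Columns (x)
      "0028,0030" = dcm_element("DS", c(geo$spacing[2], geo$spacing[1])),
      "0018,0050" = dcm_element("DS", geo$spacing[3]),
      "0028,0100" = dcm_element("US", 16),
      "0028,0101" = dcm_element("US", 16),
      "0028,0102" = dcm_element("US", 15),
      "0028,0103" = dcm_element("US", 0),
      "0028,1052" = dcm_element("DS", -1024),
      "0028,1053" = dcm_element("DS", 1),
      "7FE0,0010" = dcm_element("OW",
        writeBin(as.integer(stored), raw(), size = 2, endian = "little"))
    )
    paths[k] <- file.path(dir, sprintf("CT_%04d.dcm", k))
    dcm_write_file(paths[k], ds, SOP_CT, sop_uid)
  }
  invisible(paths)
}

#' Read a DICOM CT series
#'
#' Reads all DICOM files in a directory, sorts slices by patient z position,
#' checks for uniform slice spacing, and returns a Hounsfield-unit volume
#' (`HU = RescaleSlope * stored + RescaleIntercept`).
#'
#' @param dir directory containing one DICOM CT file per slice.
#' @return A [scalar_volume()] with unit `"HU"`, slices ascending in z.
#' @export
read_ct_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE, pattern = "\\.dcm$", ignore.case = TRUE)
  if (length(files) == 0) files <- list.files(dir, full.names = TRUE)
  if (length(files) == 0) stop(sprintf("no DICOM files found in '%s'", dir))
  slices <- lapply(files, dcm_read_file)
  zs <- vapply(slices, function(ds) dcm_get(ds, "0020,0032")[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  if (anyDuplicated(round(zs, 6))) {
    stop(sprintf("duplicate CT slice at z = %.4g mm", zs[which(duplicated(round(zs, 6)))[1]]))
  }
  first <- slices[[1]]
  check_orientation(dcm_get(first, "0020,0037", required = FALSE), "read_ct_series")
  rows <- dcm_get(first, "0028,0010")
  cols <- dcm_get(first, "0028,0011")
  ps <- dcm_get(first, "0028,0030")  # row spacing (y), col spacing (x)
  if (length(zs) > 1) {
    dz <- diff(zs)
    if (max(dz) - min(dz) > 1e-3) {
      gap_at <- which.max(abs(dz - stats::median(dz)))
      stop(sprintf("non-uniform CT slice spacing: gap between z = %.4g and %.4g mm",
                   zs[gap_at], zs[gap_at + 1]))
    }
    dz <- stats::median(dz)
  } else {
    dz <- dcm_get(first, "0018,0050", required = FALSE)
    if (is.null(dz)) dz <- 1
  }
  ipp <- dcm_get(first, "0020,0032")
  geo <- grid_geometry(c(cols, rows, length(zs)), c(ps[2], ps[1], dz),
                       c(ipp[1], ipp[2], zs[1]))
  vol <- array(0, dim = geo$shape)
  for (k in seq_along(slices)) {
    ds <- slices[[k]]
    slope <- dcm_get(ds, "0028,1053", required = FALSE)
    intercept <- dcm_get(ds, "0028,1052", required = FALSE)
    if (is.null(slope)) slope <- 1
    if (is.null(intercept)) intercept <- 0
    stored <- readBin(dcm_get(ds, "7FE0,0010"), "integer", n = rows * cols,
                      size = 2, endian = "little", signed = FALSE)
    vol[, , k] <- slope * stored + intercept
  }
  scalar_volume(vol, geo, unit = "HU")
}

#' Write a dose grid to a DICOM RTDOSE file
#'
#' Dose values are stored as 32-bit pixels with
#' `DoseGridScaling = max(dose) / (2^31 - 1)`, so for a 55 Gy maximum the
#' quantization step is at most `55 / 2^31` Gy.
#'
#' @param dose a [dose_grid()] (finite, non-negative).
#' @param path output file path.
#' @param seed optional integer for reproducible UIDs.
#' @return Invisibly, `path`.
#' @export
write_dose <- function(dose, path, seed = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  if (any(dose$values < 0)) stop("write_dose: dose must be non-negative")
  geo <- dose$geometry
  maxd <- max(dose$values)
  scaling <- if (maxd > 0) maxd / (2^31 - 1) else 1e-8
  stored <- as.integer(round(dose$values / scaling))
  uid <- dcm_uid_factory(seed)
  sop_uid <- uid()
  nz <- geo$shape[3]
  ds <- list(
    "0008,0016" = dcm_element("UI", SOP_RTDOSE),
    "0008,0018" = dcm_element("UI", sop_uid),
    "0008,0060" = dcm_element("CS", "RTDOSE"),
    "0020,000D" = dcm_element("UI", uid()),
    "0020,000E" = dcm_element("UI", uid()),
    "0020,0032" = dcm_element("DS", geo$origin),
    "0020,0037" = dcm_element("DS", IDENTITY_ORIENTATION),
    "0028,0002" = dcm_element("US", 1),
    "0028,0008" = dcm_element("IS", nz),
    "0028,0010" = dcm_element("US", geo$shape[2]),
    "0028,0011" = dcm_element("US", geo$shape[1]),
    "0028,0030" = dcm_element("DS", c(geo$spacing[2], geo$spacing[1])),
    "3004,000C" = dcm_element("DS", geo$spacing[3] * (seq_len(nz) - 1)),
    "0028,0100" = dcm_element("US", 32),
    "0028,0101" = dcm_element("US", 32),
    "0028,0102" = dcm_element("US", 31),
    "0028,0103" = dcm_element("US", 0),
    "3004,0002" = dcm_element("CS", "GY"),
    "3004,0004" = dcm_element("CS", "PHYSICAL"),
    "3004,000A" = dcm_element("CS", "PLAN"),
    "3004,000E" = dcm_element("DS", scaling),
    "7777,1001" = dcm_element("DS", as.numeric(dose$prescriptions)),
    "7FE0,0010" = dcm_element("OW",
      writeBin(stored, raw(), size = 4, endian = "little"))
  )
  dcm_write_file(path, ds, SOP_RTDOSE, sop_uid)
  invisible(path)
}

#' Read a DICOM RTDOSE file
#'
#' @param path RTDOSE file path.
#' @param prescriptions optional named prescription vector (Gy); defaults to
#'   the private tag written by [write_dose()] when present, else 45 Gy.
#' @return A [dose_grid()] with pixel values multiplied by `DoseGridScaling`.
#' @export
read_dose <- function(path, prescriptions = NULL) {
  ds <- dcm_read_file(path)
  scaling <- dcm_get(ds, "3004,000E", required = FALSE)
  if (is.null(scaling)) stop("read_dose: DoseGridScaling (3004,000E) is missing")
  check_orientation(dcm_get(ds, "0020,0037", required = FALSE), "read_dose")
  rows <- dcm_get(ds, "0028,0010")
  cols <- dcm_get(ds, "0028,0011")
  nz <- dcm_get(ds, "0028,0008")
  ps <- dcm_get(ds, "0028,0030")
  offsets <- dcm_get(ds, "3004,000C")
  ipp <- dcm_get(ds, "0020,0032")
  if (nz > 1) {
    dz <- diff(offsets)
    if (max(dz) - min(dz) > 1e-3) stop("read_dose: non-uniform frame offsets")
    dz <- stats::median(dz)
  } else dz <- 1
  geo <- grid_geometry(c(cols, rows, nz), c(ps[2], ps[1], dz),
                       c(ipp[1], ipp[2], ipp[3] + offsets[1]))
  stored <- readBin(dcm_get(ds, "7FE0,0010"), "integer", n = cols * rows * nz,
                    size = 4, endian = "little")
  if (is.null(prescriptions)) {
    pres <- dcm_get(ds, "7777,1001", required = FALSE)
    prescriptions <- if (is.null(pres)) c(PTV45 = 45)
                     else stats::setNames(pres, paste0("PTV", round(pres)))
  }
  dose_grid(array(stored * scaling, dim = geo$shape), geo, prescriptions)
}

#' Write a structure set to a DICOM RTSTRUCT file
#'
#' Each mask becomes one region of interest (ROI) whose per-slice closed
#' contours are produced by [mask_to_contours()]. ROI display colors are
#' assigned distinct values from a fixed palette.
#'
#' @param structures a [structure_set()].
#' @param path output file path.
#' @param seed optional integer for reproducible UIDs.
#' @return Invisibly, `path`.
#' @export
write_structures <- function(structures, path, seed = NULL) {
  stopifnot(inherits(structures, "structure_set"))
  nms <- names(structures)
  if (anyDuplicated(nms)) stop("write_structures: duplicate ROI names")
  uid <- dcm_uid_factory(seed)
  sop_uid <- uid(); frame_uid <- uid()
  colors <- grDevices::col2rgb(grDevices::hcl.colors(max(length(nms), 2), "Dark 3"))
  roi_seq <- list(); contour_seq <- list(); obs_seq <- list()
  for (i in seq_along(nms)) {
    mask <- structures[[nms[i]]]
    roi_seq[[i]] <- list(
      "3006,0022" = dcm_element("IS", i),
      "3006,0024" = dcm_element("UI", frame_uid),
      "3006,0026" = dcm_element("LO", nms[i]),
      "3006,0036" = dcm_element("CS", "AUTOMATIC")
    )
    loops <- mask_to_contours(mask)
    items <- lapply(loops, function(loop) {
      pts <- t(cbind(loop$xy, loop$z))  # x y z interleaved
      list(
        "3006,0042" = dcm_element("CS", "CLOSED_PLANAR"),
        "3006,0046" = dcm_element("IS", nrow(loop$xy)),
        "3006,0050" = dcm_element("DS", as.numeric(pts))
      )
    })
    contour_seq[[i]] <- list(
      "3006,002A" = dcm_element("IS", colors[, i]),
      "3006,0040" = dcm_element("SQ", items),
      "3006,0084" = dcm_element("IS", i)
    )
    obs_seq[[i]] <- list(
      "3006,0082" = dcm_element("IS", i),
      "3006,0084" = dcm_element("IS", i),
      "3006,00A4" = dcm_element("CS", "ORGAN")
    )
  }
  ds <- list(
    "0008,0016" = dcm_element("UI", SOP_RTSTRUCT),
    "0008,0018" = dcm_element("UI", sop_uid),
    "0008,0060" = dcm_element("CS", "RTSTRUCT"),
    "0020,000D" = dcm_element("UI", uid()),
    "0020,000E" = dcm_element("UI", uid()),
    "3006,0002" = dcm_element("SH", "doserings"),
    "3006,0020" = dcm_element("SQ", roi_seq),
    "3006,0039" = dcm_element("SQ", contour_seq),
    "3006,0080" = dcm_element("SQ", obs_seq)
  )
  dcm_write_file(path, ds, SOP_RTSTRUCT, sop_uid)
  invisible(path)
}

#' Read a DICOM RTSTRUCT file and rasterize onto a grid
#'
#' Every ROI's closed planar contours are rasterized slice by slice onto the
#' supplied geometry with the even-odd voxel-center-in-polygon rule. An ROI
#' without contours yields an empty mask with a warning.
#'
#' @param path RTSTRUCT file path.
#' @param geometry target [grid_geometry()].
#' @return A [structure_set()] on `geometry`.
#' @export
read_structures <- function(path, geometry) {
  ds <- dcm_read_file(path)
  roi_seq <- dcm_get(ds, "3006,0020", required = FALSE)
  contour_seq <- dcm_get(ds, "3006,0039", required = FALSE)
  if (is.null(roi_seq) || length(roi_seq) == 0) {
    return(structure_set(list()))
  }
  roi_names <- stats::setNames(
    vapply(roi_seq, function(item) dcm_get(item, "3006,0026"), character(1)),
    vapply(roi_seq, function(item) as.character(dcm_get(item, "3006,0022")), character(1)))
  masks <- list()
  for (item in contour_seq) {
    roi_num <- as.character(dcm_get(item, "3006,0084"))
    name <- roi_names[[roi_num]]
    contours <- dcm_get(item, "3006,0040", required = FALSE)
    loops <- list()
    if (!is.null(contours)) {
      loops <- lapply(contours, function(ci) {
        pts <- matrix(dcm_get(ci, "3006,0050"), ncol = 3, byrow = TRUE)
        list(xy = pts[, 1:2, drop = FALSE], z = pts[1, 3])
      })
    }
    if (length(loops) == 0) {
      warning(sprintf("ROI '%s' has no contours; returning an empty mask", name))
      masks[[name]] <- binary_mask(array(0, geometry$shape), geometry)
    } else {
      masks[[name]] <- rasterize_contours(loops, geometry)
    }
  }
  structure_set(masks)
}
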