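# Core discretization: dose -> integer-Gy ISO regions -> dose rings ->
# ring/organ intersections -> RTSTRUCT export.

#' Discretize a dose grid into ISO regions
#'
#' For each integer level `k` in `1..n` Gy, the level-`k` ISO region codes a
#' voxel 255 when its dose strictly exceeds `k` Gy ("inside") and 0
#' otherwise. Regions are monotonically nested: level `k+1` is a subset of
#' level `k`.
#'
#' @param dose a [dose_grid()].
#' @param n number of levels (integer Gy); conventionally the prescription
#'   dose, e.g. 45, or 50 for SIB plans. Defaults to the highest
#'   prescription of `dose`.
#' @return An object of class `iso_region_set`: `levels` (1..n), `masks`
#'   (list of \{0, 255\}-coded arrays), `n`, `geometry`.
#' @export
make_iso_regions <- function(dose, n = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  if (is.null(n)) n <- round(prescription_max(dose))
  n <- as.integer(n)
  if (n <= 0) stop("make_iso_regions: n must be >= 1")
  masks <- lapply(seq_len(n), function(k) (dose$values > k) * 255)
  structure(list(levels = seq_len(n), masks = masks, n = n,
                 geometry = dose$geometry),
            class = "iso_region_set")
}

#' @export
print.iso_region_set <- function(x, ...) {
  cat(sprintf("<iso_region_set> levels 1..%d Gy on %s\n", x$n, format(x$geometry)))
  invisible(x)
}

check_iso_nesting <- function(iso) {
  for (k in seq_len(iso$n - 1)) {
    if (any(iso$masks[[k + 1]] > iso$masks[[k]])) {
      stop(sprintf("iso_region_set: nesting violated between levels %d and %d", k, k + 1))
    }
  }
  invisible(TRUE)
}

#' Build dose rings from ISO regions
#'
#' `Ring k` is the set difference of adjacent ISO regions — level `k` minus
#' level `k+1` — so it holds the voxels with dose in the `(k, k+1]` Gy band;
#' `Ring n` equals the level-`n` ISO region itself (dose > n Gy). Rings are
#' pairwise disjoint and their union is the level-1 region. Rings use 0/1
#' coding internally; the \{0, 255\} image coding is an ISO-region detail.
#'
#' @param iso an `iso_region_set` from [make_iso_regions()].
#' @return An object of class `ring_set`: `rings` (named list
#'   `"Ring 1".."Ring n"` of [binary_mask()]s), `n`, `geometry`.
#' @export
make_rings <- function(iso) {
  stopifnot(inherits(iso, "iso_region_set"))
  check_iso_nesting(iso)
  geo <- iso$geometry
  rings <- vector("list", iso$n)
  for (k in seq_len(iso$n)) {
    vals <- if (k < iso$n) {
      (iso$masks[[k]] > 0) * (1 - (iso$masks[[k + 1]] > 0))
    } else {
      (iso$masks[[k]] > 0) * 1
    }
    rings[[k]] <- binary_mask(vals, geo)
  }
  names(rings) <- sprintf("Ring %d", seq_len(iso$n))
  structure(list(rings = rings, n = iso$n, geometry = geo), class = "ring_set")
}

#' @export
print.ring_set <- function(x, ...) {
  occupied <- sum(vapply(x$rings, function(r) sum(r$values) > 0, logical(1)))
  cat(sprintf("<ring_set> Ring 1..Ring %d (%d non-empty) on %s\n",
              x$n, occupied, format(x$geometry)))
  invisible(x)
}

#' Intersect a ring with an organ mask
#'
#' Voxelwise AND of the two masks; used to build the "Ring k ∩ organ"
#' structures that the IMRT template constrains.
#'
#' @param ring,organ [binary_mask()]s on one geometry.
#' @return A [binary_mask()].
#' @export
intersect_ring_organ <- function(ring, organ) {
  stopifnot(inherits(ring, "binary_mask"), inherits(organ, "binary_mask"))
  if (!same_geometry(ring$geometry, organ$geometry)) {
    stop("intersect_ring_organ: geometries do not match")
  }
  binary_mask(ring$values * organ$values, ring$geometry)
}

#' Export rings to a DICOM RTSTRUCT file
#'
#' Writes one ROI per ring at level `min_level` and above (low-dose rings
#' below that are excluded from the export by default, since constraining an
#' excessive number of rings degrades planning efficiency), named
#' `"Ring <k>"`.
#'
#' @param ringset a `ring_set`.
#' @param path output RTSTRUCT path.
#' @param min_level lowest ring exported (default 25).
#' @param export_all_rings if `TRUE`, export every ring regardless of
#'   `min_level`.
#' @param seed optional integer for reproducible UIDs.
#' @return Invisibly, the ROI names written.
#' @export
rings_to_rtstruct <- function(ringset, path, min_level = 25,
                              export_all_rings = FALSE, seed = NULL) {
  stopifnot(inherits(ringset, "ring_set"))
  keep <- if (export_all_rings) seq_len(ringset$n)
          else seq(from = min(min_level, ringset$n), to = ringset$n)
  rois <- ringset$rings[keep]
  rois <- rois[vapply(rois, function(r) sum(r$values) > 0, logical(1))]
  if (length(rois) == 0) stop("rings_to_rtstruct: all selected rings are empty")
  write_structures(structure_set(rois), path, seed = seed)
  invisible(names(rois))
}
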