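#' Extract per-slice closed contours from a binary mask
#'
#' Traces the exact voxel-edge boundary of each axial slice: polygon vertices
#' lie on voxel corners (voxel centers +/- half a spacing), outer boundaries
#' and interior holes come out as separate closed loops, and even-odd
#' rasterization of the loops ([rasterize_contours()]) reproduces the mask
#' voxel-exactly. Collinear runs are merged so axis-aligned boundaries stay
#' compact.
#'
#' @param mask a [binary_mask()].
#' @return A list of loops, each `list(xy = <n x 2 mm matrix>, z = <mm>,
#'   slice = <slice index>)`; empty list for an empty mask.
#' @export
mask_to_contours <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  geo <- mask$geometry
  nx <- geo$shape[1]; ny <- geo$shape[2]
  zs <- axis_coords(geo, 3)
  loops <- list()
  for (k in seq_len(geo$shape[3])) {
    m <- mask$values[, , k] > 0.5
    if (!any(m)) next
    for (loop in trace_slice_boundaries(m)) {
      xy <- cbind(geo$origin[1] + geo$spacing[1] * (loop[, 1] - 0.5),
                  geo$origin[2] + geo$spacing[2] * (loop[, 2] - 0.5))
      loops[[length(loops) + 1L]] <- list(xy = xy, z = zs[k], slice = k)
    }
  }
  loops
}

# Boundary tracing on one logical slice. Returns a list of closed loops as
# matrices of 0-based corner coordinates (corner (a, b) sits at voxel
# coordinate (a - 0.5, b - 0.5)). Directed boundary edges (counter-clockwise
# around filled area) are collected, then chained into loops.
trace_slice_boundaries <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  inside <- function(di, dj) pad[2:(nx + 1) + di, 2:(ny + 1) + dj]
  idx <- which(m, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  sel <- function(nb) nb[cbind(i, j)]
  starts <- list(); ends <- list()
  add <- function(sa, sb, ea, eb, keep) {
    starts[[length(starts) + 1L]] <<- cbind(sa, sb)[keep, , drop = FALSE]
    ends[[length(ends) + 1L]] <<- cbind(ea, eb)[keep, , drop = FALSE]
  }
  add(i - 1, j - 1, i,     j - 1, !sel(inside(0, -1)))  # bottom
  add(i,     j - 1, i,     j,     !sel(inside(1, 0)))   # right
  add(i,     j,     i - 1, j,     !sel(inside(0, 1)))   # top
  add(i - 1, j,     i - 1, j - 1, !sel(inside(-1, 0)))  # left
  S <- do.call(rbind, starts); E <- do.call(rbind, ends)
  n_edge <- nrow(S)
  skey <- S[, 1] * (ny + 2) + S[, 2]
  ekey <- E[, 1] * (ny + 2) + E[, 2]
  nxt <- match(ekey, skey)  # one successor per edge (first match)
  # vertices with two outgoing edges (diagonal-touching corners) need a
  # fallback when the first choice is already consumed
  dup <- which(duplicated(skey) | duplicated(skey, fromLast = TRUE))
  alt <- if (length(dup)) split(dup, skey[dup]) else list()
  used <- rep(FALSE, n_edge)
  out <- list()
  for (e0 in seq_len(n_edge)) {
    if (used[e0]) next
    verts <- matrix(0, n_edge + 1, 2)
    nv <- 0L
    e <- e0
    repeat {
      used[e] <- TRUE
      nv <- nv + 1L
      verts[nv, ] <- S[e, ]
      nx <- nxt[e]
      if (used[nx]) {
        cand <- alt[[as.character(ekey[e])]]
        cand <- if (is.null(cand)) integer(0) else cand[!used[cand]]
        if (length(cand) == 0) break  # loop closed
        nx <- cand[1]
      }
      e <- nx
    }
    out[[length(out) + 1L]] <- merge_collinear(verts[seq_len(nv), , drop = FALSE])
  }
  out
}

merge_collinear <- function(verts) {
  n <- nrow(verts)
  if (n < 3) return(verts)
  prev <- verts[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- verts[c(2:n, 1), , drop = FALSE]
  d1 <- verts - prev; d2 <- nxt - verts
  keep <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1] != 0 | rowSums(d1 * d2) < 0
  verts[keep, , drop = FALSE]
}

#' Rasterize closed planar contours onto a grid
#'
#' Applies the even-odd voxel-center-in-polygon rule per axial slice: a voxel
#' belongs to the structure iff its center lies inside an odd number of the
#' slice's loops. This is the inverse of [mask_to_contours()] for masks the
#' package itself exported.
#'
#' @param loops list of `list(xy, z)` loops (mm coordinates).
#' @param geometry target [grid_geometry()].
#' @return A [binary_mask()].
#' @export
rasterize_contours <- function(loops, geometry) {
  vals <- array(0, geometry$shape)
  if (length(loops) == 0) return(binary_mask(vals, geometry))
  xs <- axis_coords(geometry, 1); ys <- axis_coords(geometry, 2)
  zsl <- vapply(loops, function(l) l$z, numeric(1))
  ks <- round((zsl - geometry$origin[3]) / geometry$spacing[3]) + 1
  for (k in unique(ks)) {
    if (k < 1 || k > geometry$shape[3]) next
    crossings <- matrix(0L, geometry$shape[1], geometry$shape[2])
    for (l in which(ks == k)) {
      crossings <- crossings + polygon_crossings(loops[[l]]$xy, xs, ys)
    }
    vals[, , k] <- vals[, , k] + (crossings %% 2L)
  }
  binary_mask(pmin(vals, 1), geometry)
}

# Crossing counts of a rightward ray from every grid center (xs x ys) with the
# polygon boundary; odd count = inside (even-odd rule).
polygon_crossings <- function(xy, xs, ys) {
  n <- nrow(xy)
  cross <- matrix(0L, length(xs), length(ys))
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- xy[c(2:n, 1), 1]; y2 <- xy[c(2:n, 1), 2]
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next
    jy <- which((ys >= min(y1[e], y2[e])) & (ys < max(y1[e], y2[e])))
    if (length(jy) == 0) next
    # x where the edge crosses each of those center rows
    t <- (ys[jy] - y1[e]) / (y2[e] - y1[e])
    xc <- x1[e] + t * (x2[e] - x1[e])
    for (q in seq_along(jy)) {
      ix <- which(xs < xc[q])
      if (length(ix)) cross[ix, jy[q]] <- cross[ix, jy[q]] + 1L
    }
  }
  cross
}
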