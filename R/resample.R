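#' Resample a volume or mask onto a target geometry
#'
#' Voxel-center sampling in the shared patient frame: the value at each target
#' voxel center is interpolated from the source lattice. `mode = "linear"`
#' (trilinear) is for CT and dose; `mode = "nearest"` is for masks, which stay
#' strictly 0/1. Positions outside the source extent are filled with the
#' background value: -1000 for HU, 0 for dose, masks and unitless volumes.
#'
#' @param volume a [scalar_volume()], [dose_grid()] or [binary_mask()].
#' @param target a [grid_geometry()].
#' @param mode `"linear"` or `"nearest"`; masks force `"nearest"`.
#' @return The same class of object on `target`.
#' @export
resample <- function(volume, target, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (any(target$spacing <= 0)) stop("resample: target spacings must be positive")
  is_mask <- inherits(volume, "binary_mask")
  if (is_mask) mode <- "nearest"
  src_geo <- volume$geometry
  if (same_geometry(src_geo, target)) return(volume)
  background <- if (is_mask) 0
                else switch(volume$unit, HU = -1000, Gy = 0, 0)
  vals <- sample_volume_at(
    volume$values, src_geo,
    xs = axis_coords(target, 1), ys = axis_coords(target, 2),
    zs = axis_coords(target, 3),
    mode = mode, background = background)
  dim(vals) <- target$shape
  if (is_mask) {
    binary_mask(vals, target)
  } else if (inherits(volume, "dose_grid")) {
    dose_grid(pmax(vals, 0), target, volume$prescriptions)
  } else {
    scalar_volume(vals, target, volume$unit)
  }
}

# Sample `values` (on geometry `geo`) at the tensor grid xs x ys x zs of
# patient-space mm positions. Returns an array length(xs) x length(ys) x
# length(zs). Separable, so index weights are computed once per axis.
sample_volume_at <- function(values, geo, xs, ys, zs, mode, background) {
  axf <- function(coords, axis) {
    # fractional 0-based index of each coordinate along `axis`
    (coords - geo$origin[axis]) / geo$spacing[axis]
  }
  fx <- axf(xs, 1); fy <- axf(ys, 2); fz <- axf(zs, 3)
  n <- geo$shape
  if (mode == "nearest") {
    ix <- round(fx); iy <- round(fy); iz <- round(fz)
    okx <- ix >= 0 & ix <= n[1] - 1
    oky <- iy >= 0 & iy <= n[2] - 1
    okz <- iz >= 0 & iz <= n[3] - 1
    ix <- pmin(pmax(ix, 0), n[1] - 1)
    iy <- pmin(pmax(iy, 0), n[2] - 1)
    iz <- pmin(pmax(iz, 0), n[3] - 1)
    out <- values[cbind(
      rep(ix + 1, times = length(iy) * length(iz)),
      rep(rep(iy + 1, each = length(ix)), times = length(iz)),
      rep(iz + 1, each = length(ix) * length(iy)))]
    ok <- outer(outer(okx, oky, "&"), okz, "&")
    out[!ok] <- background
    array(out, dim = c(length(xs), length(ys), length(zs)))
  } else {
    lin_axis <- function(f, nn) {
      ok <- f >= 0 & f <= nn - 1
      f <- pmin(pmax(f, 0), nn - 1)
      i0 <- pmin(floor(f), nn - 2 + (nn == 1))
      w <- f - i0
      if (nn == 1) { i0 <- rep(0, length(f)); w <- rep(0, length(f)) }
      list(i0 = i0 + 1, w = w, ok = ok)
    }
    ax <- lin_axis(fx, n[1]); ay <- lin_axis(fy, n[2]); az <- lin_axis(fz, n[3])
    nx <- length(xs); ny <- length(ys); nz <- length(zs)
    out <- array(0, dim = c(nx, ny, nz))
    i1x <- pmin(ax$i0 + 1, n[1]); i1y <- pmin(ay$i0 + 1, n[2]); i1z <- pmin(az$i0 + 1, n[3])
    for (k in seq_len(nz)) {
      k0 <- az$i0[k]; k1 <- i1z[k]; wz <- az$w[k]
      # bilinear on the two bounding slices, then blend
      sl <- function(kk) {
        m00 <- values[ax$i0, ay$i0, kk, drop = FALSE]; dim(m00) <- c(nx, ny)
        m10 <- values[i1x,   ay$i0, kk, drop = FALSE]; dim(m10) <- c(nx, ny)
        m01 <- values[ax$i0, i1y,   kk, drop = FALSE]; dim(m01) <- c(nx, ny)
        m11 <- values[i1x,   i1y,   kk, drop = FALSE]; dim(m11) <- c(nx, ny)
        wxm <- matrix(ax$w, nx, ny); wym <- matrix(ay$w, nx, ny, byrow = TRUE)
        m00 * (1 - wxm) * (1 - wym) + m10 * wxm * (1 - wym) +
          m01 * (1 - wxm) * wym + m11 * wxm * wym
      }
      s0 <- sl(k0)
      out[, , k] <- if (wz > 0) s0 * (1 - wz) + sl(k1) * wz else s0
    }
    ok <- outer(outer(ax$ok, ay$ok, "&"), az$ok, "&")
    out[!ok] <- background
    out
  }
}

# Trilinear point sampling at arbitrary (not tensor-grid) positions; used by
# dose perturbation and gamma analysis. `points` is an n x 3 matrix of mm
# positions. Out-of-extent points return NA.
sample_points_trilinear <- function(values, geo, points) {
  f <- sweep(sweep(points, 2, geo$origin, "-"), 2, geo$spacing, "/")
  n <- geo$shape
  ok <- f[, 1] >= 0 & f[, 1] <= n[1] - 1 &
        f[, 2] >= 0 & f[, 2] <= n[2] - 1 &
        f[, 3] >= 0 & f[, 3] <= n[3] - 1
  f <- pmin(pmax(f, 0), matrix(n - 1, nrow(f), 3, byrow = TRUE))
  i0 <- pmin(floor(f), matrix(pmax(n - 2, 0), nrow(f), 3, byrow = TRUE))
  w <- f - i0
  i0 <- i0 + 1
  i1 <- pmin(i0 + 1, matrix(n, nrow(f), 3, byrow = TRUE))
  g <- function(a, b, c) values[cbind(a, b, c)]
  v <- g(i0[,1], i0[,2], i0[,3]) * (1-w[,1])*(1-w[,2])*(1-w[,3]) +
       g(i1[,1], i0[,2], i0[,3]) *    w[,1] *(1-w[,2])*(1-w[,3]) +
       g(i0[,1], i1[,2], i0[,3]) * (1-w[,1])*   w[,2] *(1-w[,3]) +
       g(i1[,1], i1[,2], i0[,3]) *    w[,1] *   w[,2] *(1-w[,3]) +
       g(i0[,1], i0[,2], i1[,3]) * (1-w[,1])*(1-w[,2])*   w[,3]  +
       g(i1[,1], i0[,2], i1[,3]) *    w[,1] *(1-w[,2])*   w[,3]  +
       g(i0[,1], i1[,2], i1[,3]) * (1-w[,1])*   w[,2] *   w[,3]  +
       g(i1[,1], i1[,2], i1[,3]) *    w[,1] *   w[,2] *   w[,3]
  v[!ok] <- NA_real_
  v
}
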