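# Plan evaluation: cumulative DVH, V_x / D_q / D_mean, Paddick conformity
# index, homogeneity index, and dice-per-isodose-level curves.

mask_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(mask, "binary_mask"))
  if (!same_geometry(dose$geometry, mask$geometry)) {
    stop("dose and mask geometries do not match")
  }
  d <- dose$values[mask$values > 0.5]
  if (length(d) == 0) stop("mask is empty")
  d
}

#' Cumulative dose-volume histogram
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [binary_mask()].
#' @param bin_width histogram bin width in Gy (default 0.05).
#' @param name structure name carried in the result.
#' @return An object of class `dvh_curve`: `dose_gy` (bin edges from 0 past
#'   the maximum dose), `volume_fraction` (fraction of the structure
#'   receiving at least each edge; starts at 1, monotone non-increasing,
#'   ends at 0), `structure`, `volume_cm3`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.05, name = "structure") {
  d <- mask_doses(dose, mask)
  edges <- seq(0, max(d) + 2 * bin_width, by = bin_width)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  frac[1] <- 1  # every voxel receives at least 0 Gy
  structure(list(dose_gy = edges, volume_fraction = frac, structure = name,
                 volume_cm3 = sum(mask$values) * voxel_volume_cm3(mask$geometry)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s (%.1f cm^3), %d bins to %.2f Gy\n",
              x$structure, x$volume_cm3, length(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}

#' Volume receiving at least a dose level
#'
#' @param dose a [dose_grid()] (or any scalar volume in Gy).
#' @param mask a non-empty [binary_mask()].
#' @param level_gy dose level in Gy.
#' @return Percent of the structure volume with dose >= `level_gy`.
#' @export
v_at <- function(dose, mask, level_gy) {
  100 * mean(mask_doses(dose, mask) >= level_gy)
}

#' Dose received by at least q percent of the volume
#'
#' Linear-interpolation quantile of the in-mask dose values (the same
#' convention used by [renormalize_plan()]).
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [binary_mask()].
#' @param q_pct volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
d_at <- function(dose, mask, q_pct) {
  if (q_pct <= 0 || q_pct > 100) stop("d_at: q must be in (0, 100]")
  stats::quantile(mask_doses(dose, mask), probs = 1 - q_pct / 100,
                  names = FALSE, type = 7)
}

#' Mean structure dose
#' @inheritParams v_at
#' @return Mean dose in Gy.
#' @export
d_mean <- function(dose, mask) {
  mean(mask_doses(dose, mask))
}

#' Paddick conformity index
#'
#' `CI = TV_PIV^2 / (TV * PIV)` with `TV` the target volume, `PIV` the
#' prescription isodose volume (dose >= prescription) and `TV_PIV` their
#' intersection. 1 is perfect conformity; 0 when the prescription isodose
#' volume is empty (with a warning) or disjoint from the target.
#'
#' @param dose a [dose_grid()].
#' @param ptv a non-empty [binary_mask()].
#' @param prescription prescription dose in Gy.
#' @return CI in `[0, 1]`.
#' @export
conformity_index <- function(dose, ptv, prescription) {
  if (sum(ptv$values) == 0) stop("conformity_index: PTV mask is empty")
  if (!same_geometry(dose$geometry, ptv$geometry)) stop("geometry mismatch")
  piv <- dose$values >= prescription
  tv <- sum(ptv$values)
  npiv <- sum(piv)
  if (npiv == 0) {
    warning("conformity_index: prescription isodose volume is empty; CI = 0")
    return(0)
  }
  inter <- sum(piv & ptv$values > 0.5)
  inter^2 / (tv * npiv)
}

#' Homogeneity index
#'
#' Default `HI = D_5 / D_95` over the target (>= 1; 1 is perfectly uniform).
#' The near/far quantiles are configurable (e.g. `c(2, 98)` for D2/D98).
#'
#' @param dose a [dose_grid()].
#' @param ptv a non-empty [binary_mask()].
#' @param quantiles length-2 vector `c(near, far)` of volume percentages.
#' @return HI (>= 1 for any dose distribution).
#' @export
homogeneity_index <- function(dose, ptv, quantiles = c(5, 95)) {
  d_hi <- d_at(dose, ptv, quantiles[1])
  d_lo <- d_at(dose, ptv, quantiles[2])
  if (d_lo <= 0) stop("homogeneity_index: denominator quantile is zero")
  d_hi / d_lo
}

#' Dice similarity per isodose level
#'
#' For each level `L` (% of the prescription), compares the isodose regions
#' `dose >= L` of two distributions by dice similarity coefficient
#' `DSC = 2|A n B| / (|A| + |B|)`. Both regions empty is defined as DSC 1.
#' Isodose masks here use the inclusive `>=` convention (unlike the strict
#' `>` of ring construction); the two differ only on exact-tie voxels.
#'
#' @param dose_a,dose_b [dose_grid()]s on one geometry.
#' @param prescription reference prescription in Gy.
#' @param levels_pct vector of levels as % of prescription
#'   (default 10 to 110 by 2).
#' @return An object of class `dsc_curve`: `level_pct`, `dsc`.
#' @export
dsc_curve <- function(dose_a, dose_b, prescription,
                      levels_pct = seq(10, 110, by = 2)) {
  if (!same_geometry(dose_a$geometry, dose_b$geometry)) {
    stop("dsc_curve: geometries do not match")
  }
  dsc <- vapply(levels_pct, function(L) {
    thr <- prescription * L / 100
    a <- dose_a$values >= thr
    b <- dose_b$values >= thr
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0) return(1)
    2 * sum(a & b) / (na + nb)
  }, numeric(1))
  structure(list(level_pct = levels_pct, dsc = dsc), class = "dsc_curve")
}

#' @export
print.dsc_curve <- function(x, ...) {
  cat(sprintf("<dsc_curve> %d levels (%g-%g%%), min DSC %.3f at %g%%\n",
              length(x$level_pct), min(x$level_pct), max(x$level_pct),
              min(x$dsc), x$level_pct[which.min(x$dsc)]))
  invisible(x)
}

#' Standard plan metrics table
#'
#' Computes the usual target metrics (V45, V50 where applicable, D95, CI,
#' HI) and OAR metrics (Dmean, V45, V40, V30, V20) for every structure of a
#' case against a dose grid.
#'
#' @param dose a [dose_grid()].
#' @param structures a [structure_set()].
#' @param prescriptions named prescription vector (Gy) keyed by target name.
#' @return A data.frame with columns `structure`, `metric`, `value`.
#' @export
plan_metrics <- function(dose, structures,
                         prescriptions = c(PTV45 = 45)) {
  rows <- list()
  put <- function(st, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(structure = st, metric = metric,
                                             value = value)
  }
  for (nm in names(structures)) {
    mask <- structures[[nm]]
    if (sum(mask$values) == 0) next
    if (nm %in% names(prescriptions)) {
      rx <- prescriptions[[nm]]
      put(nm, sprintf("V%dGy_pct", round(rx)), v_at(dose, mask, rx))
      put(nm, "D95_gy", d_at(dose, mask, 95))
      put(nm, "CI", conformity_index(dose, mask, rx))
      put(nm, "HI", homogeneity_index(dose, mask))
    } else if (nm != "Body") {
      put(nm, "Dmean_gy", d_mean(dose, mask))
      for (lev in c(45, 40, 30, 20)) {
        put(nm, sprintf("V%dGy_pct", lev), v_at(dose, mask, lev))
      }
    }
  }
  do.call(rbind, rows)
}
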