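# Wall-mechanics post-processing: von Mises equivalent stress from Cauchy
# stress tensors, area-based engineering strain, cycle pulsatility and time
# averages, and the per-region summary table (median / median pulsatility /
# robust maximum / maximum pulsatility) used for comparative reporting.

#' Von Mises equivalent stress of a symmetric stress tensor series
#'
#' Per element and sample time, sigma_M = sqrt(3/2 * tr(sigma_d . sigma_d))
#' with sigma_d = sigma - tr(sigma)/3 * I the deviatoric part. Expanded in
#' components (xx, yy, zz, xy, xz, yz) this is the familiar
#' sqrt(0.5 * ((sxx-syy)^2 + (syy-szz)^2 + (szz-sxx)^2) +
#'      3 * (sxy^2 + sxz^2 + syz^2)).
#' Invariant under hydrostatic shifts and rigid rotations.
#'
#' @param stress element-attached `sym_tensor3` [field_series()] (Pa).
#' @return scalar `field_series` (Pa) on the same window and attachment.
#' @export
von_mises <- function(stress) {
  stopifnot(inherits(stress, "field_series"))
  if (stress$kind != "sym_tensor3") stop("von_mises needs a sym_tensor3 series")
  v <- stress$values
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite stress component at time index %d, element %d",
                 bad[1L], bad[2L]))
  }
  sxx <- v[, , 1L]; syy <- v[, , 2L]; szz <- v[, , 3L]
  sxy <- v[, , 4L]; sxz <- v[, , 5L]; syz <- v[, , 6L]
  vm <- sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
               3 * (sxy^2 + sxz^2 + syz^2))
  vm <- array(vm, dim = c(dim(v)[1L], dim(v)[2L], 1L))
  field_series(vm, kind = "scalar", attachment = stress$attachment,
               window = stress$window, units = "Pa")
}

#' Area-based engineering strain
#'
#' Per element and sample time, epsilon = sqrt((A_n - A_0) / A_0), the square
#' root of the relative area change of a surface element; it lumps
#' circumferential and longitudinal stretch into one engineering-strain-like
#' scalar. For transiently compressed elements (A_n < A_0) the definition has
#' no real value; a signed extension -sqrt((A_0 - A_n)/A_0) is reported
#' instead and those samples are flagged, keeping the map total.
#'
#' @param area0 per-element reference areas A_0 (m^2), all > 0.
#' @param areas matrix (n_times x n_elements) of deformed areas A_n (m^2),
#'   all > 0.
#' @param window the [cycle_window()] the samples cover.
#' @return scalar `field_series` (dimensionless) with attribute
#'   `n_compressed` counting flagged (element, time) samples.
#' @export
engineering_strain <- function(area0, areas, window) {
  area0 <- as.numeric(area0)
  stopifnot(is.matrix(areas), length(area0) == ncol(areas))
  if (any(area0 <= 0) || any(areas <= 0)) stop("areas must be strictly positive")
  rel <- sweep(areas, 2L, area0, "/") - 1
  eps <- sign(rel) * sqrt(abs(rel))
  n_comp <- sum(rel < 0)
  if (n_comp > 0)
    warning(sprintf(
      "%d sample(s) with A_n < A_0: signed strain extension used", n_comp))
  out <- field_series(array(eps, dim = c(dim(eps), 1L)), kind = "scalar",
                      attachment = "element", window = window, units = "")
  attr(out, "n_compressed") <- n_comp
  out
}

#' Cycle pulsatility of a scalar field series
#'
#' Per element, the difference between the maximum and the minimum value
#' observed over the analysed cycle (always >= 0).
#'
#' @param series scalar [field_series()].
#' @param window the [cycle_window()] the series covers.
#' @return `metric_map` in the series' units.
#' @export
pulsatility <- function(series, window = series$window) {
  stopifnot(inherits(series, "field_series"), series$kind == "scalar")
  m <- series$values[, , 1L, drop = TRUE]
  if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
  metric_map(apply(m, 2L, max) - apply(m, 2L, min),
             "pulsatility", series$units, window)
}

#' Trapezoidal time average of a scalar field series
#'
#' @inheritParams pulsatility
#' @return `metric_map` in the series' units.
#' @export
time_average <- function(series, window = series$window) {
  stopifnot(inherits(series, "field_series"), series$kind == "scalar")
  m <- series$values[, , 1L, drop = TRUE]
  if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
  metric_map(trapz_time(window$sample_times, m) / window$period_T,
             "time_average", series$units, window)
}

#' Per-region mechanics summary table
#'
#' For each region and each supplied quantity (von Mises stress in kPa,
#' strain in %), reports the area-weighted median of the time-averaged map,
#' the area-weighted median of the pulsatility map, the artefact-robust
#' maximum (top-1%-area omitted) of the time-averaged map, and the robust
#' maximum of the pulsatility map.
#'
#' @param stress element-attached `sym_tensor3` [field_series()] (Pa), or a
#'   precomputed scalar von Mises series; NULL to skip stress rows.
#' @param strain scalar strain [field_series()] (dimensionless); NULL to skip.
#' @param regions named list of [region_mask()]s.
#' @param mesh the `surface_mesh` the maps live on.
#' @param omit_area_fraction robust-maximum omission fraction.
#' @return data.frame with columns region, quantity, median,
#'   median_pulsatility, robust_max, max_pulsatility, units.
#' @export
mechanics_report <- function(stress = NULL, strain = NULL, regions, mesh,
                             omit_area_fraction = 0.01) {
  stopifnot(length(regions) > 0, !is.null(names(regions)))
  rows <- list()
  summarise <- function(series, quantity, scale, units) {
    avg <- time_average(series)
    puls <- pulsatility(series)
    for (rn in names(regions)) {
      reg <- regions[[rn]]
      rows[[length(rows) + 1L]] <<- data.frame(
        region = rn, quantity = quantity,
        median = scale * region_median(avg, reg, mesh),
        median_pulsatility = scale * region_median(puls, reg, mesh),
        robust_max = scale * robust_max(avg, reg, mesh, omit_area_fraction),
        max_pulsatility = scale * robust_max(puls, reg, mesh, omit_area_fraction),
        units = units, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(stress)) {
    vm <- if (stress$kind == "sym_tensor3") von_mises(stress) else stress
    summarise(vm, "von_mises", 1e-3, "kPa")
  }
  if (!is.null(strain)) summarise(strain, "strain", 100, "%")
  if (!length(rows)) stop("at least one of stress or strain must be supplied")
  do.call(rbind, rows)
}
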