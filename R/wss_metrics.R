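# Wall-shear-stress metrics over one cardiac cycle: cycle-averaged magnitude
# (TAWSS), sampled time-maximum (WSS_max), the oscillatory shear index (OSI),
# threshold-exceedance area fractions, artefact-robust maxima and
# area-weighted medians. All time integrals are trapezoidal on the window's
# actual sample times, so non-uniform solver stepping is handled directly.

#' Per-element scalar metric map
#'
#' The common result container: one scalar per surface element, with units,
#' a metric name and (optionally) the cycle window it was computed over.
#' `flags` marks elements where a degenerate definition was substituted
#' (e.g. OSI on an identically zero WSS signal).
#'
#' @param values numeric per-element vector.
#' @param metric_name short name, e.g. "TAWSS".
#' @param units unit string.
#' @param window optional [cycle_window()].
#' @param flags optional logical vector marking degenerate elements.
#' @return object of class `metric_map`.
#' @export
metric_map <- function(values, metric_name, units = "", window = NULL,
                       flags = NULL) {
  values <- as.numeric(values)
  if (!is.null(flags)) stopifnot(length(flags) == length(values))
  structure(list(values = values, metric_name = metric_name, units = units,
                 window = window, flags = flags),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("metric_map '%s' [%s]: %d elements, range [%.6g, %.6g]\n",
              x$metric_name, x$units, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

.check_wss_input <- function(wss, window) {
  stopifnot(inherits(wss, "field_series"))
  if (wss$kind != "vector3") stop("WSS series must be a vector3 field")
  if (wss$attachment != "element")
    stop("WSS series must be element-attached (use node_to_element first)")
  if (!isTRUE(all.equal(wss$window$sample_times, window$sample_times,
                        tolerance = 1e-12)))
    stop("field sample times do not match the requested cycle window")
}

#' Time-averaged wall shear stress magnitude (TAWSS)
#'
#' Per element, (1/T) * integral over the cycle of ||tau(t)|| dt, by the
#' trapezoidal rule on the window's sample times. Values below 0.1 Pa are
#' conventionally regarded as non-physiologically low shear.
#'
#' @param wss element-attached vector3 [field_series()] of WSS (Pa).
#' @param window the [cycle_window()] the series covers.
#' @return `metric_map` in Pa.
#' @export
compute_tawss <- function(wss, window = wss$window) {
  .check_wss_input(wss, window)
  mag <- vec_magnitude(wss)
  metric_map(trapz_time(window$sample_times, mag) / window$period_T,
             "TAWSS", "Pa", window)
}

#' Time-maximum wall shear stress
#'
#' Per element, the maximum of ||tau(t)|| over the sampled times (no
#' sub-sample interpolation: with typical solver stepping of ~1e-4 s the
#' difference is negligible and the sampled maximum is reproducible).
#'
#' @inheritParams compute_tawss
#' @return `metric_map` in Pa.
#' @export
compute_wss_max <- function(wss, window = wss$window) {
  .check_wss_input(wss, window)
  mag <- vec_magnitude(wss)
  metric_map(apply(mag, 2L, max), "WSS_max", "Pa", window)
}

#' Oscillatory shear index (OSI)
#'
#' Per element, 0.5 * (1 - ||integral tau dt|| / integral ||tau|| dt), which
#' ranges from 0 (steady, unidirectional shear) to 0.5 (perfectly oscillatory
#' shear with zero mean). Elements whose cycle-integrated magnitude falls
#' below `zero_tolerance * T` are reported as OSI = 0 (no oscillation is the
#' conservative reading of the 0/0 limit) and flagged.
#'
#' @inheritParams compute_tawss
#' @param zero_tolerance magnitude floor (Pa) for the degenerate-element test.
#' @return dimensionless `metric_map` with a `flags` vector.
#' @export
compute_osi <- function(wss, window = wss$window, zero_tolerance = 1e-12) {
  .check_wss_input(wss, window)
  ts <- window$sample_times
  int_x <- trapz_time(ts, wss$values[, , 1L, drop = TRUE])
  int_y <- trapz_time(ts, wss$values[, , 2L, drop = TRUE])
  int_z <- trapz_time(ts, wss$values[, , 3L, drop = TRUE])
  num <- sqrt(int_x^2 + int_y^2 + int_z^2)
  den <- trapz_time(ts, vec_magnitude(wss))
  degenerate <- den < zero_tolerance * window$period_T
  osi <- rep(0, length(den))
  ok <- !degenerate
  osi[ok] <- 0.5 * (1 - num[ok] / den[ok])
  # clip quadrature round-off just outside the definitional range
  osi <- pmin(pmax(osi, 0), 0.5)
  if (any(degenerate))
    warning(sprintf("%d element(s) with (near-)zero WSS reported as OSI = 0",
                    sum(degenerate)))
  metric_map(osi, "OSI", "", window, flags = degenerate)
}

## ---------------------------------------------------------------------------
## region statistics

#' Threshold specification for exceedance statistics
#'
#' @param metric_name name of the metric the bound applies to.
#' @param bound finite scalar bound (in the metric's units).
#' @param direction "above" (strictly greater) or "below" (strictly less).
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(metric_name, bound, direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(bound))
  structure(list(metric_name = metric_name, bound = bound,
                 direction = direction), class = "threshold_spec")
}

#' Reference threshold set for WSS exposure reporting
#'
#' The four standard exposure rows: highly oscillatory shear (OSI > 0.25),
#' non-physiologically low shear (TAWSS < 0.1 Pa), non-physiologically high
#' shear (WSS_max > 7 Pa) and very high shear that damages endothelium
#' (WSS_max > 40 Pa).
#'
#' @return named list of `threshold_spec`s.
#' @export
default_wss_thresholds <- function() {
  list(
    osi_high   = threshold_spec("OSI",     0.25, "above"),
    tawss_low  = threshold_spec("TAWSS",   0.1,  "below"),
    wss_high   = threshold_spec("WSS_max", 7,    "above"),
    wss_very_high = threshold_spec("WSS_max", 40, "above")
  )
}

.region_values <- function(map, region, mesh) {
  ids <- region$element_ids + 1L
  if (!length(ids)) stop("region '", region$label, "' is empty")
  if (length(map$values) != n_elements(mesh))
    stop("metric map length does not match mesh element count")
  list(values = map$values[ids], areas = mesh$element_area[ids])
}

#' Area fraction of a region satisfying a threshold
#'
#' 100 x (member area where the metric is strictly above/below the bound) /
#' (total region area). The inequality at the bound is strict, matching the
#' printed operators of the exposure thresholds (OSI > 0.25, TAWSS < 0.1 Pa,
#' WSS > 7 Pa, WSS > 40 Pa).
#'
#' @param map a `metric_map`.
#' @param threshold a [threshold_spec()].
#' @param region a [region_mask()].
#' @param mesh the `surface_mesh` supplying element areas.
#' @return percentage in [0, 100].
#' @export
area_fraction <- function(map, threshold, region, mesh) {
  rv <- .region_values(map, region, mesh)
  hit <- if (threshold$direction == "above") rv$values > threshold$bound
         else rv$values < threshold$bound
  100 * sum(rv$areas[hit]) / region$total_area
}

#' Artefact-robust maximum (top-area-fraction omitted)
#'
#' Sorts member elements by value descending, accumulates area until just
#' exceeding `omit_area_fraction` of the region area, removes those elements,
#' and returns the maximum of the rest. With the default 1% omission this
#' discards isolated numerical artefacts while keeping genuine hot spots that
#' cover more than 1% of the region. Ties in value are broken by element id
#' ascending, so the result is deterministic.
#'
#' @inheritParams area_fraction
#' @param omit_area_fraction fraction of region area to omit (default 0.01).
#' @return scalar in the metric's units.
#' @export
robust_max <- function(map, region, mesh, omit_area_fraction = 0.01) {
  if (omit_area_fraction >= 1) stop("omit_area_fraction must be < 1")
  if (omit_area_fraction < 0) stop("omit_area_fraction must be >= 0")
  rv <- .region_values(map, region, mesh)
  if (omit_area_fraction == 0) return(max(rv$values))
  ord <- order(rv$values, region$element_ids, decreasing = c(TRUE, FALSE),
               method = "radix")
  cum <- cumsum(rv$areas[ord])
  target <- omit_area_fraction * region$total_area
  # omit the minimal prefix whose cumulative area reaches the omit target
  k <- match(TRUE, cum >= target)
  if (is.na(k) || k >= length(ord)) return(rv$values[ord][length(ord)])
  max(rv$values[ord][(k + 1L):length(ord)])
}

#' Area-weighted region median
#'
#' The value at which cumulative member area (elements sorted by value
#' ascending) first reaches half the region area. Area weighting makes the
#' statistic independent of local mesh density; an element-count median is
#' available via `weighted = FALSE`.
#'
#' @inheritParams area_fraction
#' @param weighted if FALSE, plain element-count median.
#' @return scalar in the metric's units.
#' @export
region_median <- function(map, region, mesh, weighted = TRUE) {
  rv <- .region_values(map, region, mesh)
  if (!weighted) return(stats::median(rv$values))
  ord <- order(rv$values)
  cum <- cumsum(rv$areas[ord])
  k <- match(TRUE, cum >= 0.5 * region$total_area)
  rv$values[ord][k]
}
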