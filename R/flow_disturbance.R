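# Flow-disturbance quantification: Reynolds decomposition of the velocity
# magnitude into a slow cardiac-harmonic trend and high-frequency
# perturbations, perturbation RMS maps, cross-sectional medians along the
# centreline, and the time-averaged centreline pressure profile.

#' Trend specification for Reynolds decomposition
#'
#' The trend is the Fourier reconstruction of the signal retaining cardiac
#' harmonics 0..cutoff of frequency 1/T. Fourier truncation is reproducible
#' and parameter-light; the cutoff (default 10) must accompany every reported
#' perturbation statistic, since the absolute perturbation RMS depends on it.
#'
#' @param cutoff_harmonics number of retained cardiac harmonics (>= 1).
#' @return object of class `trend_spec`.
#' @export
trend_spec <- function(cutoff_harmonics = 10L) {
  cutoff_harmonics <- as.integer(cutoff_harmonics)
  if (cutoff_harmonics < 1L) stop("cutoff_harmonics must be >= 1")
  structure(list(method = "fourier_truncation",
                 cutoff_harmonics = cutoff_harmonics), class = "trend_spec")
}

.is_uniform <- function(ts) {
  d <- diff(ts)
  max(abs(d - d[1L])) <= 1e-9 * max(d)
}

#' Reynolds decomposition of a scalar velocity series
#'
#' Splits u(t, x) into the sum of a slow trend u_bar (harmonics 0..cutoff of
#' the cardiac frequency 1/T) and high-frequency perturbations
#' u_tilde = u - u_bar. Additivity u = u_bar + u_tilde is exact at every
#' sample by construction. Non-uniformly sampled input is linearly resampled
#' onto 2^k uniform points (k chosen so the resampled spacing does not exceed
#' the smallest input spacing) before the Fourier step; the trend is then
#' evaluated back at the original sample times from its harmonic
#' coefficients.
#'
#' @param u_mag scalar [field_series()] of velocity magnitude over one cycle.
#' @param window the [cycle_window()] the series covers.
#' @param trend a [trend_spec()].
#' @return list with `trend` and `perturbation`, both scalar `field_series`.
#' @export
reynolds_decompose <- function(u_mag, window = u_mag$window,
                               trend = trend_spec()) {
  stopifnot(inherits(u_mag, "field_series"), u_mag$kind == "scalar",
            inherits(trend, "trend_spec"))
  ts <- window$sample_times
  cutoff <- trend$cutoff_harmonics
  if (length(ts) < 2L * (cutoff + 1L))
    stop(sprintf("need at least %d samples to resolve %d harmonics, have %d",
                 2L * (cutoff + 1L), cutoff, length(ts)))
  T_ <- window$period_T
  u <- u_mag$values[, , 1L, drop = TRUE]
  if (!is.matrix(u)) u <- matrix(u, ncol = 1L)

  if (.is_uniform(ts)) {
    tu <- ts; uu <- u
  } else {
    n_target <- 2^ceiling(log2(T_ / min(diff(ts)) + 1))
    tu <- seq(window$t_start, window$t_start + T_, length.out = n_target + 1L)
    uu <- apply(u, 2L, function(col) stats::approx(ts, col, xout = tu)$y)
  }
  # drop the duplicated closing endpoint for the periodic transform
  N <- nrow(uu) - 1L
  if (cutoff >= N / 2) stop("cutoff harmonics exceed the Nyquist limit")
  X <- stats::mvfft(uu[seq_len(N), , drop = FALSE])
  a0 <- Re(X[1L, ]) / N
  k <- seq_len(cutoff)
  ak <- 2 * Re(X[k + 1L, , drop = FALSE]) / N
  bk <- -2 * Im(X[k + 1L, , drop = FALSE]) / N
  # synthesise the trend at the original sample times
  ph <- outer(ts - window$t_start, k) * (2 * pi / T_) # n_t x cutoff
  ubar <- matrix(a0, nrow = length(ts), ncol = ncol(u), byrow = TRUE) +
    cos(ph) %*% ak + sin(ph) %*% bk
  utilde <- u - ubar
  wrap <- function(m, units) field_series(array(m, dim = c(dim(m), 1L)),
                                          kind = "scalar",
                                          attachment = u_mag$attachment,
                                          window = window, units = units)
  list(trend = wrap(ubar, u_mag$units), perturbation = wrap(utilde, u_mag$units))
}

#' Root-mean-square of a perturbation series over the cycle
#'
#' Per point, sqrt((1/T) * integral of u_tilde^2 dt) by the trapezoidal rule;
#' the standard scalar measure of disturbed flow.
#'
#' @param perturbation scalar perturbation [field_series()].
#' @param window the [cycle_window()] the series covers.
#' @return `metric_map` in the series' units.
#' @export
perturbation_rms <- function(perturbation, window = perturbation$window) {
  stopifnot(inherits(perturbation, "field_series"),
            perturbation$kind == "scalar")
  m <- perturbation$values[, , 1L, drop = TRUE]
  if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
  metric_map(sqrt(trapz_time(window$sample_times, m^2) / window$period_T),
             "perturbation_RMS", perturbation$units, window)
}

#' Cross-sectional medians of a nodal map along the centreline
#'
#' For each station arclength, collects the mesh nodes whose projection onto
#' the local centreline tangent lies within +/- `slab_half_width` of the
#' station point and reports the plain (unweighted) median of their values.
#' Stations whose slab contains no nodes are reported as NA with a warning.
#'
#' @param values per-node numeric vector (e.g. a perturbation-RMS map's
#'   values) on `mesh`'s nodes.
#' @param mesh a [volume_mesh()] (or `surface_mesh`).
#' @param cl a [centreline()].
#' @param station_arclengths numeric arclengths (m).
#' @param slab_half_width slab half-width (m), default 1 mm.
#' @return data.frame with columns arclength, median, n_members.
#' @export
cross_section_median <- function(values, mesh, cl, station_arclengths,
                                 slab_half_width = 1e-3) {
  if (inherits(values, "metric_map")) values <- values$values
  stopifnot(length(values) == nrow(mesh$points), slab_half_width > 0)
  out <- lapply(station_arclengths, function(s) {
    loc <- centreline_at(cl, s)
    d_ax <- as.numeric((mesh$points - matrix(loc$point, nrow(mesh$points), 3L,
                                             byrow = TRUE)) %*% loc$tangent)
    member <- abs(d_ax) <= slab_half_width
    if (!any(member)) {
      warning(sprintf("empty cross-section slab at arclength %.6g m", s))
      data.frame(arclength = s, median = NA_real_, n_members = 0L)
    } else {
      data.frame(arclength = s, median = stats::median(values[member]),
                 n_members = sum(member))
    }
  })
  do.call(rbind, out)
}

## ---------------------------------------------------------------------------
## centreline pressure profile

# barycentric interpolation weights of points in a tet mesh;
# returns list(element, weights 4-col matrix); elements are 1-based or NA
.locate_in_tets <- function(mesh, pts, tol = 1e-10) {
  stopifnot(inherits(mesh, "volume_mesh"))
  tets <- mesh$tets + 1L
  a <- mesh$points[tets[, 1L], , drop = FALSE]
  inv <- vector("list", nrow(tets))
  for (e in seq_len(nrow(tets))) {
    M <- t(mesh$points[tets[e, 2:4], , drop = FALSE]) - a[e, ]
    inv[[e]] <- solve(M)
  }
  elem <- rep(NA_integer_, nrow(pts))
  wts <- matrix(NA_real_, nrow(pts), 4L)
  for (i in seq_len(nrow(pts))) {
    for (e in seq_len(nrow(tets))) {
      b <- inv[[e]] %*% (pts[i, ] - a[e, ])
      if (all(b >= -tol) && sum(b) <= 1 + tol) {
        elem[i] <- e
        wts[i, ] <- c(1 - sum(b), b)
        break
      }
    }
  }
  list(element = elem, weights = wts)
}

#' Time-averaged pressure profile along the centreline
#'
#' Time-averages the nodal pressure field over the cycle (trapezoid), then
#' samples it at every centreline point by locating the containing
#' tetrahedron and interpolating barycentrically. Centreline points outside
#' the mesh fall back to the nearest mesh node, with a warning. The overall
#' drop p_bar(0) - p_bar(s_end) is reported alongside the profile.
#'
#' @param p node-attached scalar pressure [field_series()] (Pa) on `mesh`.
#' @param mesh a [volume_mesh()].
#' @param cl a [centreline()].
#' @param window the [cycle_window()] the series covers.
#' @return list with `profile` (data.frame: arclength_m, mean_pressure_Pa,
#'   landmark) and `drop_Pa`.
#' @export
centreline_pressure_profile <- function(p, mesh, cl, window = p$window) {
  stopifnot(inherits(p, "field_series"), p$kind == "scalar",
            p$attachment == "node", inherits(mesh, "volume_mesh"))
  pbar <- time_average(p, window)$values
  loc <- .locate_in_tets(mesh, cl$points)
  vals <- numeric(nrow(cl$points))
  n_out <- 0L
  for (i in seq_len(nrow(cl$points))) {
    if (is.na(loc$element[i])) {
      n_out <- n_out + 1L
      d2 <- rowSums((mesh$points - matrix(cl$points[i, ], nrow(mesh$points),
                                          3L, byrow = TRUE))^2)
      vals[i] <- pbar[which.min(d2)]
    } else {
      nodes <- mesh$tets[loc$element[i], ] + 1L
      vals[i] <- sum(loc$weights[i, ] * pbar[nodes])
    }
  }
  if (n_out > 0)
    warning(sprintf("%d centreline point(s) outside the mesh: nearest-node fallback",
                    n_out))
  lm_names <- rep(NA_character_, nrow(cl$points))
  if (length(cl$landmarks)) {
    for (nm in names(cl$landmarks)) {
      i <- which.min(abs(cl$arclength - cl$landmarks[[nm]]))
      lm_names[i] <- nm
    }
  }
  profile <- data.frame(arclength_m = cl$arclength, mean_pressure_Pa = vals,
                        landmark = lm_names, stringsAsFactors = FALSE)
  list(profile = profile, drop_Pa = vals[1L] - vals[length(vals)])
}
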