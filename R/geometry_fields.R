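# Core data model: meshes, cycle windows, time-resolved fields, centrelines,
# region masks. Everything downstream (WSS metrics, disturbance, mechanics,
# ROI reports) consumes these containers. Units are strictly SI internally
# (m, s, Pa); mmHg is converted at the interface with mmhg_to_pa().

PA_PER_MMHG <- 133.322

#' Convert pressures between mmHg and Pa
#'
#' Internal computations use Pa throughout; clinical pressures are usually
#' quoted in mmHg. 1 mmHg = 133.322 Pa.
#'
#' @param p numeric pressure(s).
#' @return numeric, converted pressure(s).
#' @export
mmhg_to_pa <- function(p) p * PA_PER_MMHG

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(p) p / PA_PER_MMHG

## ---------------------------------------------------------------------------
## surface mesh

#' Triangulated surface mesh
#'
#' Stores node coordinates and 0-based triangle connectivity, and derives
#' per-element areas, centroids and unit normals. Areas must be strictly
#' positive; degenerate triangles are rejected.
#'
#' @param points numeric n x 3 matrix of node coordinates (m).
#' @param triangles integer m x 3 matrix of 0-based node indices.
#' @return object of class `surface_mesh` with fields `points`, `triangles`,
#'   `element_area` (m^2), `element_centroid`, `element_normal`.
#' @export
surface_mesh <- function(points, triangles) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(points) == 3L, ncol(triangles) == 3L)
  if (min(triangles) < 0L || max(triangles) >= nrow(points))
    stop("triangle node indices must be 0-based and < number of points")
  a <- points[triangles[, 1L] + 1L, , drop = FALSE]
  b <- points[triangles[, 2L] + 1L, , drop = FALSE]
  c_ <- points[triangles[, 3L] + 1L, , drop = FALSE]
  cr <- .cross3(b - a, c_ - a)
  nrm2 <- sqrt(rowSums(cr^2))
  if (any(nrm2 <= 0)) stop("degenerate triangle(s) with zero area: ",
                           paste(which(nrm2 <= 0) - 1L, collapse = ", "))
  structure(list(
    points = points,
    triangles = triangles,
    element_area = nrm2 / 2,
    element_centroid = (a + b + c_) / 3,
    element_normal = cr / nrm2
  ), class = "surface_mesh")
}

.cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d nodes, %d triangles, total area %.6g m^2\n",
              nrow(x$points), nrow(x$triangles), sum(x$element_area)))
  invisible(x)
}

n_elements <- function(mesh) {
  if (inherits(mesh, "surface_mesh")) nrow(mesh$triangles) else nrow(mesh$tets)
}

## ---------------------------------------------------------------------------
## volume mesh

#' Tetrahedral volume mesh
#'
#' Node coordinates plus 0-based tetrahedron connectivity. Element volumes are
#' computed on load; tets with negative signed volume are re-oriented (two
#' nodes swapped) so all volumes are positive.
#'
#' @param points numeric n x 3 matrix (m).
#' @param tets integer m x 4 matrix of 0-based node indices.
#' @return object of class `volume_mesh` with `element_volume` (m^3).
#' @export
volume_mesh <- function(points, tets) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(points) == 3L, ncol(tets) == 4L)
  if (min(tets) < 0L || max(tets) >= nrow(points))
    stop("tet node indices must be 0-based and < number of points")
  vol <- .tet_signed_volume(points, tets)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
    vol <- abs(vol)
  }
  if (any(vol == 0)) stop("degenerate tetrahedron(s) with zero volume")
  structure(list(points = points, tets = tets, element_volume = vol),
            class = "volume_mesh")
}

.tet_signed_volume <- function(points, tets) {
  a <- points[tets[, 1L] + 1L, , drop = FALSE]
  u <- points[tets[, 2L] + 1L, , drop = FALSE] - a
  v <- points[tets[, 3L] + 1L, , drop = FALSE] - a
  w <- points[tets[, 4L] + 1L, , drop = FALSE] - a
  rowSums(.cross3(u, v) * w) / 6
}

## ---------------------------------------------------------------------------
## cycle window

#' Analysed cardiac cycle window
#'
#' The single cycle [t_start, t_start + T] over which all metrics are
#' integrated. Sample times may be non-uniform (solvers often refine stepping
#' through systole); all time integrals downstream use the trapezoidal rule on
#' these actual times.
#'
#' @param sample_times strictly increasing numeric vector (s), spanning the
#'   full cycle; at least 3 samples.
#' @param period_T optional cycle duration (s); defaults to
#'   `diff(range(sample_times))`.
#' @return object of class `cycle_window` with `t_start`, `period_T`,
#'   `sample_times`.
#' @export
cycle_window <- function(sample_times, period_T = NULL) {
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) < 3L) stop("a cycle window needs at least 3 samples")
  if (any(diff(sample_times) <= 0)) stop("sample_times must be strictly increasing")
  t0 <- sample_times[1L]
  span <- sample_times[length(sample_times)] - t0
  if (is.null(period_T)) period_T <- span
  if (abs(span - period_T) > 1e-9)
    stop(sprintf("sample_times span %.12g s but period_T is %.12g s", span, period_T))
  structure(list(t_start = t0, period_T = period_T, sample_times = sample_times),
            class = "cycle_window")
}

#' Uniformly sampled cycle window
#'
#' @param period_T cycle duration (s).
#' @param n_samples number of samples, endpoints included.
#' @param t_start window start (s).
#' @return `cycle_window` with `n_samples` uniform times over one cycle.
#' @export
uniform_window <- function(period_T, n_samples, t_start = 0) {
  ts <- seq(t_start, t_start + period_T, length.out = n_samples)
  # guard the closing endpoint against seq() rounding
  ts[n_samples] <- t_start + period_T
  cycle_window(ts, period_T)
}

## ---------------------------------------------------------------------------
## field series

FIELD_KINDS <- c(scalar = 1L, vector3 = 3L, sym_tensor3 = 6L)

#' Time-sampled field on a mesh
#'
#' A scalar, 3-vector, or symmetric 3x3 tensor field attached to mesh nodes or
#' elements, sampled at the times of a [cycle_window()]. Symmetric tensors are
#' stored as 6 components in Voigt-like order (xx, yy, zz, xy, xz, yz).
#'
#' @param values numeric array of dim (n_times, n_entities, n_components), or
#'   a (n_times x n_entities) matrix for scalar fields.
#' @param kind one of "scalar", "vector3", "sym_tensor3".
#' @param attachment "node" or "element".
#' @param window a [cycle_window()].
#' @param units SI unit string (e.g. "Pa", "m s-1").
#' @return object of class `field_series`.
#' @export
field_series <- function(values, kind = c("scalar", "vector3", "sym_tensor3"),
                         attachment = c("element", "node"), window,
                         units = "") {
  kind <- match.arg(kind)
  attachment <- match.arg(attachment)
  stopifnot(inherits(window, "cycle_window"))
  ncomp <- FIELD_KINDS[[kind]]
  if (is.matrix(values)) {
    if (ncomp != 1L) stop("matrix input only valid for scalar fields")
    values <- array(values, dim = c(dim(values), 1L))
  }
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[3L] != ncomp)
    stop(sprintf("kind '%s' needs %d components, got %d", kind, ncomp, dim(values)[3L]))
  if (dim(values)[1L] != length(window$sample_times))
    stop(sprintf("values have %d time slabs but window has %d sample times",
                 dim(values)[1L], length(window$sample_times)))
  structure(list(values = values, kind = kind, attachment = attachment,
                 window = window, units = units),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("field_series: %s, %s-attached, %d x %d x %d [%s], T = %g s\n",
              x$kind, x$attachment, d[1L], d[2L], d[3L], x$units,
              x$window$period_T))
  invisible(x)
}

n_entities <- function(field) dim(field$values)[2L]

#' Average a node-attached field onto elements
#'
#' Per element and time sample, the unweighted arithmetic mean of its vertex
#' values (component-wise for vectors/tensors). A spatially constant field is
#' preserved exactly. Element-attached input is returned unchanged with a
#' warning.
#'
#' @param field a node-attached [field_series()].
#' @param mesh the `surface_mesh` or `volume_mesh` the field lives on.
#' @return an element-attached `field_series`.
#' @export
node_to_element <- function(field, mesh) {
  stopifnot(inherits(field, "field_series"))
  if (field$attachment == "element") {
    warning("field is already element-attached; returning unchanged")
    return(field)
  }
  conn <- if (inherits(mesh, "surface_mesh")) mesh$triangles else mesh$tets
  if (n_entities(field) != nrow(mesh$points))
    stop("node-attached field length does not match mesh point count")
  nvert <- ncol(conn)
  d <- dim(field$values)
  out <- array(0, dim = c(d[1L], nrow(conn), d[3L]))
  for (v in seq_len(nvert)) {
    out <- out + field$values[, conn[, v] + 1L, , drop = FALSE]
  }
  out <- out / nvert
  field_series(out, kind = field$kind, attachment = "element",
               window = field$window, units = field$units)
}

## ---------------------------------------------------------------------------
## centreline

#' Vessel centreline polyline
#'
#' Ordered points along the vessel axis with cumulative arclength (starting at
#' 0) and optional named landmark positions (arclengths, m), e.g. the
#' graft-vein transition.
#'
#' @param points numeric n x 3 matrix (m), ordered along the vessel.
#' @param landmarks named numeric vector of arclength positions (m).
#' @return object of class `centreline` with `points`, `arclength`, `landmarks`.
#' @export
centreline <- function(points, landmarks = numeric(0)) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("centreline has coincident consecutive points")
  arc <- c(0, cumsum(seg))
  if (length(landmarks)) stopifnot(!is.null(names(landmarks)))
  structure(list(points = points, arclength = arc,
                 landmarks = as.numeric(landmarks) |>
                   stats::setNames(names(landmarks))),
            class = "centreline")
}

#' Interpolate a point and unit tangent at an arclength position
#' @param cl a [centreline()].
#' @param s arclength (m), within [0, total length].
#' @return list with `point` (xyz) and `tangent` (unit xyz).
#' @export
centreline_at <- function(cl, s) {
  stopifnot(inherits(cl, "centreline"))
  arc <- cl$arclength
  if (s < arc[1L] - 1e-12 || s > arc[length(arc)] + 1e-12)
    stop(sprintf("arclength %.6g m outside centreline [0, %.6g]", s, arc[length(arc)]))
  s <- min(max(s, arc[1L]), arc[length(arc)])
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(arc) - 1L)
  w <- (s - arc[i]) / (arc[i + 1L] - arc[i])
  p <- (1 - w) * cl$points[i, ] + w * cl$points[i + 1L, ]
  tg <- cl$points[i + 1L, ] - cl$points[i, ]
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

#' Read / write a centreline as CSV (columns x,y,z in m)
#' @param path CSV file path.
#' @param landmarks named numeric vector of arclengths (read side).
#' @return `centreline` (read) or invisible path (write).
#' @export
read_centreline_csv <- function(path, landmarks = numeric(0)) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  centreline(as.matrix(df[, c("x", "y", "z")]), landmarks)
}

#' @rdname read_centreline_csv
#' @param cl a [centreline()].
#' @export
write_centreline_csv <- function(cl, path) {
  df <- data.frame(x = cl$points[, 1L], y = cl$points[, 2L], z = cl$points[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## region mask

#' Element subset of a surface mesh
#'
#' Holds 0-based element ids, a label, and the total member area; the
#' substrate for all region statistics (area fractions, medians, robust
#' maxima).
#'
#' @param element_ids integer vector of 0-based element ids (unique).
#' @param mesh the `surface_mesh` the ids refer to.
#' @param label region label, e.g. "graft", "vein", "anastomosis".
#' @return object of class `region_mask` with `element_ids`, `label`,
#'   `total_area` (m^2).
#' @export
region_mask <- function(element_ids, mesh, label = "custom") {
  element_ids <- as.integer(element_ids)
  if (anyDuplicated(element_ids)) stop("region element ids must be unique")
  if (length(element_ids) &&
      (min(element_ids) < 0L || max(element_ids) >= n_elements(mesh)))
    stop("region element ids out of range")
  structure(list(element_ids = element_ids, label = label,
                 total_area = sum(mesh$element_area[element_ids + 1L])),
            class = "region_mask")
}

#' All-elements region of a surface mesh
#' @param mesh a `surface_mesh`.
#' @param label region label.
#' @return `region_mask` covering every element.
#' @export
whole_surface_region <- function(mesh, label = "all") {
  region_mask(seq_len(n_elements(mesh)) - 1L, mesh, label)
}

## ---------------------------------------------------------------------------
## trapezoidal time integration (shared by all metric modules)

# trapezoidal integral of y over t; y may be a vector (per time) or a
# (n_times x k) matrix integrated column-wise
trapz_time <- function(t, y) {
  dt <- diff(t)
  if (is.matrix(y)) {
    n <- nrow(y)
    colSums((y[-n, , drop = FALSE] + y[-1L, , drop = FALSE]) * (dt / 2))
  } else {
    n <- length(y)
    sum((y[-n] + y[-1L]) * dt / 2)
  }
}

# per-entity vector magnitude matrix (n_times x n_entities) of a vector3 series
vec_magnitude <- function(field) {
  stopifnot(field$kind == "vector3")
  d <- dim(field$values)
  matrix(sqrt(field$values[, , 1L]^2 + field$values[, , 2L]^2 +
                field$values[, , 3L]^2), d[1L], d[2L])
}
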