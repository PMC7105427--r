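# Synthetic meshes, waveforms and time-resolved fields with analytically
# known metric values. These generators stand in for fluid-structure
# interaction output so every post-processing stage can be validated against
# closed forms: quasi-steady Poiseuille WSS for TAWSS/OSI, a
# prescribed-OSI reversing signal, Laplace-law pressurised-tube stress for
# von Mises / strain, seeded sinusoidal velocity perturbations for Reynolds
# decomposition, and an idealised end-to-side graft-vein anastomosis surface
# for region and report integration tests.

#' Straight-tube specification
#'
#' @param radius_zero_pressure lumen radius at zero transmural pressure (m).
#' @param length tube length (m).
#' @param wall_thickness wall thickness (m).
#' @param n_circ circumferential element resolution (>= 8).
#' @param n_axial axial element resolution.
#' @return object of class `tube_spec`.
#' @export
tube_spec <- function(radius_zero_pressure, length, wall_thickness,
                      n_circ = 32L, n_axial = 30L) {
  stopifnot(radius_zero_pressure > 0, length > 0, wall_thickness > 0)
  n_circ <- as.integer(n_circ); n_axial <- as.integer(n_axial)
  if (n_circ < 8L) stop("n_circ must be >= 8")
  if (n_axial < 1L) stop("n_axial must be >= 1")
  structure(list(radius_zero_pressure = radius_zero_pressure, length = length,
                 wall_thickness = wall_thickness, n_circ = n_circ,
                 n_axial = n_axial), class = "tube_spec")
}

#' Reference tube specifications
#'
#' The default dimensions of the modelled conduits: graft zero-pressure
#' diameter 6 mm with 0.63 mm wall, trimmed to 3 cm; vein zero-pressure
#' diameter 7.14 mm with wall thickness 10% of the pre-operative radius,
#' trimmed to 7.5 cm.
#'
#' @param n_circ,n_axial mesh resolution.
#' @return `tube_spec`.
#' @export
graft_tube_spec <- function(n_circ = 32L, n_axial = 30L)
  tube_spec(3e-3, 0.03, 0.63e-3, n_circ, n_axial)

#' @rdname graft_tube_spec
#' @export
vein_tube_spec <- function(n_circ = 32L, n_axial = 60L)
  tube_spec(7.14e-3 / 2, 0.075, 0.1 * 7.14e-3 / 2, n_circ, n_axial)

#' Pulsatile inflow waveform specification
#'
#' Q(t) = mean_flow * (1 + sum_k amplitude_k * cos(2 pi k t / T + phase_k)),
#' with relative harmonic amplitudes. The reconstructed flow must stay
#' positive throughout the cycle (no retrograde graft flow); this is checked
#' on a fine grid at construction.
#'
#' @param mean_flow cycle-mean flow (m^3 s^-1).
#' @param period_T cardiac period (s).
#' @param harmonics list of c(relative amplitude, phase rad) pairs, one per
#'   harmonic k = 1, 2, ...
#' @return object of class `waveform_spec`.
#' @export
waveform_spec <- function(mean_flow, period_T, harmonics = list()) {
  stopifnot(mean_flow > 0, period_T > 0)
  wf <- structure(list(mean_flow = mean_flow, period_T = period_T,
                       harmonics = harmonics), class = "waveform_spec")
  qs <- waveform_eval(wf, seq(0, period_T, length.out = 2048L))
  if (any(qs <= 0))
    stop("waveform reconstructs to non-positive flow; reduce harmonic amplitudes")
  wf
}

#' Evaluate a waveform at given times
#' @param wf a [waveform_spec()].
#' @param t times (s).
#' @return flow values (m^3 s^-1).
#' @export
waveform_eval <- function(wf, t) {
  q <- rep(1, length(t))
  for (k in seq_along(wf$harmonics)) {
    h <- wf$harmonics[[k]]
    q <- q + h[1L] * cos(2 * pi * k * t / wf$period_T + h[2L])
  }
  wf$mean_flow * q
}

#' Default graft-inlet waveform (parametric stand-in)
#'
#' A smooth pulsatile dialysis-access waveform: 600 ml/min mean flow over a
#' 1 s cycle with two decaying harmonics, qualitatively resembling a measured
#' graft-inlet flow curve (systolic peak, diastolic decay, always positive).
#' It is a parametric stand-in, not a digitisation of any measurement.
#'
#' @return `waveform_spec`.
#' @export
default_waveform <- function()
  waveform_spec(1e-5, 1.0,
                harmonics = list(c(0.35, -pi / 2), c(0.12, pi)))

#' Newtonian fluid specification
#'
#' Defaults are the blood surrogate used throughout: dynamic viscosity
#' 4.5e-3 Pa s, density 1000 kg m^-3.
#'
#' @param dynamic_viscosity Pa s.
#' @param density kg m^-3.
#' @return object of class `fluid_spec`.
#' @export
fluid_spec <- function(dynamic_viscosity = 4.5e-3, density = 1000) {
  stopifnot(dynamic_viscosity > 0, density > 0)
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_spec")
}

## ---------------------------------------------------------------------------
## tube surface mesh

#' Structured triangulated cylinder surface with its centreline
#'
#' Tube axis along +z from 0 to `length`. The faceted surface area is
#' 2 * n_circ * r * sin(pi / n_circ) * L and converges to the analytic
#' 2 pi r L as n_circ grows.
#'
#' @param spec a [tube_spec()].
#' @return list with `mesh` ([surface_mesh()]) and `centreline`.
#' @export
make_tube_surface <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  r <- spec$radius_zero_pressure
  nc <- spec$n_circ; na_ <- spec$n_axial
  phi <- 2 * pi * (seq_len(nc) - 1L) / nc
  z <- seq(0, spec$length, length.out = na_ + 1L)
  pts <- cbind(rep(r * cos(phi), na_ + 1L),
               rep(r * sin(phi), na_ + 1L),
               rep(z, each = nc))
  tri <- matrix(0L, nrow = 2L * nc * na_, ncol = 3L)
  row <- 1L
  for (j in seq_len(na_) - 1L) {
    for (i in seq_len(nc) - 1L) {
      i2 <- (i + 1L) %% nc
      a <- j * nc + i;      b <- j * nc + i2
      c_ <- (j + 1L) * nc + i; d <- (j + 1L) * nc + i2
      tri[row, ] <- c(a, b, c_); tri[row + 1L, ] <- c(b, d, c_)
      row <- row + 2L
    }
  }
  cl <- centreline(cbind(0, 0, z))
  list(mesh = surface_mesh(pts, tri), centreline = cl)
}

#' Quasi-steady Poiseuille WSS series on a tube wall
#'
#' Axial WSS vector of magnitude 4 mu Q(t) / (pi r^3), uniform over the wall,
#' sampled at `n_samples` uniform times over one period. The quasi-steady
#' closed form gives exact TAWSS/OSI/WSS_max targets under any positive
#' waveform, which is the oracle's job; it makes no claim of unsteady-flow
#' realism (no Womersley dynamics).
#'
#' @param spec a [tube_spec()].
#' @param waveform a [waveform_spec()].
#' @param fluid a [fluid_spec()].
#' @param n_samples uniform sample count over one cycle.
#' @param radius_override optional effective lumen radius (m), e.g. a
#'   pressure-distended radius from [tube_distension()].
#' @return list with `mesh`, `centreline`, `field` (element-attached vector3
#'   `field_series`, Pa) and `window`.
#' @export
poiseuille_wss_series <- function(spec, waveform, fluid, n_samples = 64L,
                                  radius_override = NULL) {
  tube <- make_tube_surface(spec)
  window <- uniform_window(waveform$period_T, n_samples)
  r <- if (is.null(radius_override)) spec$radius_zero_pressure else radius_override
  q <- waveform_eval(waveform, window$sample_times)
  tau <- 4 * fluid$dynamic_viscosity * q / (pi * r^3)
  ne <- nrow(tube$mesh$triangles)
  vals <- array(0, dim = c(n_samples, ne, 3L))
  vals[, , 3L] <- tau # axial (+z) traction, uniform over the wall
  field <- field_series(vals, "vector3", "element", window, "Pa")
  list(mesh = tube$mesh, centreline = tube$centreline, field = field,
       window = window)
}

## ---------------------------------------------------------------------------
## prescribed-OSI signal

#' Reversing WSS signal with exactly prescribed OSI
#'
#' A two-phase axial signal: forward at +magnitude for a nominal fraction f
#' of the cycle, reversed at -magnitude for the rest, where
#' OSI = (1 - |2 f - 1|) / 2. Because the reversal instant of a continuous
#' two-phase signal quantises onto the sample grid, the two samples
#' bracketing the reversal take intermediate values solved so that the
#' trapezoidal evaluation of the oscillatory shear index on the actual
#' sample times equals `target_osi` exactly (to round-off). The nominal
#' forward fraction is returned as attribute `f_nominal`.
#'
#' Targets in (0, 0.5/(n-2)) would need a reverse phase shorter than one
#' sample interval and are rejected; use more samples.
#'
#' @param target_osi desired OSI in [0, 0.5].
#' @param magnitude signal magnitude (Pa).
#' @param window a uniformly sampled [cycle_window()].
#' @param n_elements number of (identical) elements to carry the signal.
#' @return element-attached vector3 `field_series` (Pa).
#' @export
prescribed_osi_wss_series <- function(target_osi, magnitude, window,
                                      n_elements = 1L) {
  if (target_osi < 0 || target_osi > 0.5)
    stop("target_osi must lie in [0, 0.5]")
  stopifnot(magnitude > 0, inherits(window, "cycle_window"))
  ts <- window$sample_times
  n <- length(ts)
  if (!.is_uniform(ts)) stop("prescribed-OSI signal needs uniform sample times")
  m <- magnitude
  if (target_osi == 0) {
    sig <- rep(m, n)
  } else {
    if (n < 6L) stop("need at least 6 samples")
    if (target_osi < 0.5 / (n - 2))
      stop(sprintf("target OSI %.3g below the resolvable minimum %.3g for %d samples",
                   target_osi, 0.5 / (n - 2), n))
    r <- 1 - 2 * target_osi
    X <- r * (n - 2)
    k <- round((X + n - 2) / 2)     # 0-based index of the first blend sample
    k <- min(max(k, 1L), n - 3L)
    S <- m * (X - (2 * k - n + 2))
    c1 <- (m + S) / 2
    c2 <- (S - m) / 2
    sig <- c(rep(m, k), c1, c2, rep(-m, n - k - 2L))
  }
  vals <- array(0, dim = c(n, n_elements, 3L))
  vals[, , 1L] <- sig
  out <- field_series(vals, "vector3", "element", window, "Pa")
  attr(out, "f_nominal") <- 1 - target_osi
  out
}

## ---------------------------------------------------------------------------
## pressurised tube wall mechanics

#' Laplace-law stress and area series on a pressurised thin-walled tube
#'
#' Per element, the thin-wall membrane stress state at each sampled pressure:
#' hoop sigma_theta = p r / h, axial sigma_z = p r / (2 h), radial ~ 0,
#' rotated from the element's local (circumferential, axial) frame into
#' global coordinates. The von Mises stress of this plane-stress state is
#' sqrt(sigma_theta^2 + sigma_z^2 - sigma_theta sigma_z). When a Young's
#' modulus is supplied, element areas follow the linear-elastic hoop strain
#' e(t) = p(t) r / (E h) as A_n(t) = A_0 (1 + e(t)) (circumferential stretch
#' at fixed length).
#'
#' @param spec a [tube_spec()]; a thick wall (h/r > 0.2) warns but computes.
#' @param pressure_values pressure at each window sample (Pa).
#' @param window the [cycle_window()].
#' @param youngs_modulus optional modulus (Pa) for the area series.
#' @return list with `mesh`, `stress` (sym_tensor3 `field_series`, Pa),
#'   `area0`, `areas` (n_times x n_elements), `window`.
#' @export
pressurised_tube_stress_series <- function(spec, pressure_values, window,
                                           youngs_modulus = NULL) {
  stopifnot(inherits(spec, "tube_spec"),
            length(pressure_values) == length(window$sample_times))
  r <- spec$radius_zero_pressure; h <- spec$wall_thickness
  if (h / r > 0.2)
    warning(sprintf("h/r = %.3g exceeds the thin-wall range; Laplace stresses are approximate",
                    h / r))
  tube <- make_tube_surface(spec)
  cen <- tube$mesh$element_centroid
  phi <- atan2(cen[, 2L], cen[, 1L])
  ne <- nrow(cen); nt <- length(pressure_values)
  s_th <- outer(pressure_values, rep(r / h, ne))        # hoop, nt x ne
  s_z <- s_th / 2                                       # axial
  vals <- array(0, dim = c(nt, ne, 6L))
  sin2 <- sin(phi)^2; cos2 <- cos(phi)^2; sc <- sin(phi) * cos(phi)
  vals[, , 1L] <- sweep(s_th, 2L, sin2, "*")            # xx
  vals[, , 2L] <- sweep(s_th, 2L, cos2, "*")            # yy
  vals[, , 3L] <- s_z                                   # zz
  vals[, , 4L] <- sweep(s_th, 2L, -sc, "*")             # xy
  stress <- field_series(vals, "sym_tensor3", "element", window, "Pa")
  area0 <- tube$mesh$element_area
  areas <- if (is.null(youngs_modulus)) {
    matrix(area0, nrow = nt, ncol = ne, byrow = TRUE)
  } else {
    hoop_strain <- pressure_values * r / (youngs_modulus * h)
    outer(1 + hoop_strain, area0)
  }
  list(mesh = tube$mesh, stress = stress, area0 = area0, areas = areas,
       window = window)
}

## ---------------------------------------------------------------------------
## disturbed velocity

#' Add seeded high-frequency sinusoidal perturbations to a velocity series
#'
#' Adds amplitude * sin(2 pi f (t - t0) + phase(x)) with an independent
#' uniform random phase per entity (reproducible under `seed`) to a scalar
#' velocity-magnitude series. The perturbation frequency must exceed the
#' trend cutoff harmonic, otherwise the trend of a Reynolds decomposition
#' would absorb it.
#'
#' @param base scalar [field_series()] of velocity magnitude.
#' @param perturbation_amplitude amplitude (m s^-1); may be 0.
#' @param perturbation_frequency frequency (Hz).
#' @param seed integer RNG seed.
#' @param trend_cutoff trend cutoff (cardiac harmonics) the perturbation must
#'   stay above.
#' @return perturbed scalar `field_series`.
#' @export
disturbed_velocity_series <- function(base, perturbation_amplitude,
                                      perturbation_frequency, seed,
                                      trend_cutoff = 10L) {
  stopifnot(inherits(base, "field_series"), base$kind == "scalar",
            perturbation_amplitude >= 0)
  T_ <- base$window$period_T
  if (perturbation_frequency <= (trend_cutoff + 1) / T_)
    stop(sprintf("perturbation frequency %.3g Hz is at or below the trend cutoff (%g Hz)",
                 perturbation_frequency, (trend_cutoff + 1) / T_))
  ne <- n_entities(base)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  ph <- stats::runif(ne, 0, 2 * pi)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  ts <- base$window$sample_times - base$window$t_start
  pert <- perturbation_amplitude *
    sin(outer(ts, rep(2 * pi * perturbation_frequency, ne)) +
          matrix(ph, length(ts), ne, byrow = TRUE))
  out <- base
  out$values[, , 1L] <- base$values[, , 1L] + pert
  out
}

## ---------------------------------------------------------------------------
## idealised anastomosis

# Rodrigues rotation matrix taking unit vector a onto unit vector b
.rotation_onto <- function(a, b) {
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  cth <- sum(a * b)
  if (abs(cth - 1) < 1e-14) return(diag(3))
  if (abs(cth + 1) < 1e-14) stop("antiparallel rotation is ambiguous")
  vx <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
               3L, 3L, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Idealised end-to-side graft-vein anastomosis surface
#'
#' Two straight tubes: the vein along +x, and the graft joined onto the vein
#' surface at one third of the venous length, tilted by `angle` from the vein
#' axis. The junction is a geometric idealisation for region/report
#' integration tests; no flow realism is claimed. Elements within
#' `roi_radius` of the junction are labelled "anastomosis"; the remaining
#' graft/vein elements keep their tube of origin, so the three labels
#' partition the surface.
#'
#' @param graft_spec,vein_spec [tube_spec()]s.
#' @param angle graft-vein angle (rad) in (0, pi/2]; 0 is degenerate.
#' @param roi_radius anastomotic sphere radius (m), default 1.2 cm.
#' @return list with `mesh`, `regions` (named [region_mask()] list:
#'   graft/vein/anastomosis), `junction` (xyz), `centreline` (graft-to-vein
#'   path with a "transition" landmark), and `truth` (unclipped graft/vein
#'   masks).
#' @export
make_anastomosis_surface <- function(graft_spec, vein_spec, angle = pi / 4,
                                     roi_radius = 0.012) {
  if (angle <= 0 || angle > pi / 2)
    stop("angle must lie in (0, pi/2]: a zero angle degenerates the junction")
  vein <- make_tube_surface(vein_spec)
  # vein axis along +x: rotate the z-aligned tube
  Rv <- .rotation_onto(c(0, 0, 1), c(1, 0, 0))
  vein_pts <- vein$mesh$points %*% t(Rv)
  graft <- make_tube_surface(graft_spec)
  junction <- c(vein_spec$length / 3, vein_spec$radius_zero_pressure, 0)
  u <- c(cos(angle), sin(angle), 0) # graft axis direction, away from the vein
  Rg <- .rotation_onto(c(0, 0, 1), u)
  graft_pts <- graft$mesh$points %*% t(Rg) +
    matrix(junction, nrow(graft$mesh$points), 3L, byrow = TRUE)
  n_vp <- nrow(vein_pts)
  pts <- rbind(vein_pts, graft_pts)
  tris <- rbind(vein$mesh$triangles, graft$mesh$triangles + n_vp)
  mesh <- surface_mesh(pts, tris)
  n_ve <- nrow(vein$mesh$triangles)
  ids_vein <- seq_len(n_ve) - 1L
  ids_graft <- seq_len(nrow(graft$mesh$triangles)) + n_ve - 1L
  truth <- list(vein = region_mask(ids_vein, mesh, "vein"),
                graft = region_mask(ids_graft, mesh, "graft"))
  d_junction <- sqrt(rowSums(
    (mesh$element_centroid -
       matrix(junction, n_elements(mesh), 3L, byrow = TRUE))^2))
  in_roi <- d_junction < roi_radius
  regions <- list(
    graft = region_mask(setdiff(ids_graft, which(in_roi) - 1L), mesh, "graft"),
    vein = region_mask(setdiff(ids_vein, which(in_roi) - 1L), mesh, "vein"),
    anastomosis = region_mask(which(in_roi) - 1L, mesh, "anastomosis"))
  # centreline path: graft free end -> junction, then a vein leg that covers
  # the full vein (junction -> venous inlet -> venous outlet), so
  # nearest-point segment assignment sees both the upstream and downstream
  # vein wall
  g_axis <- t(Rg %*% t(cbind(0, 0, seq(graft_spec$length, 0,
                                       length.out = 20L)))) +
    matrix(junction, 20L, 3L, byrow = TRUE)
  v_in <- cbind(seq(junction[1L], 0, length.out = 10L)[-1L],
                seq(junction[2L], 0, length.out = 10L)[-1L], 0)
  v_axis <- cbind(seq(0, vein_spec$length, length.out = 30L)[-1L], 0, 0)
  cl <- centreline(rbind(g_axis, v_in, v_axis))
  transition <- cl$arclength[20L] # junction reached at the end of the graft leg
  cl$landmarks <- c(transition = transition)
  list(mesh = mesh, regions = regions, junction = junction, centreline = cl,
       truth = truth)
}

## ---------------------------------------------------------------------------
## structured tube volume mesh (velocity / pressure substrate)

#' Structured tetrahedral tube volume mesh
#'
#' Disk cross-section (centre node + `n_rad` concentric rings of `n_circ`
#' nodes) extruded along +z and split prism-wise into tetrahedra. Substrate
#' for nodal velocity and pressure fields in tests and demos.
#'
#' @param radius lumen radius (m).
#' @param length tube length (m).
#' @param n_circ nodes per ring.
#' @param n_rad number of rings.
#' @param n_axial axial layers.
#' @return list with `mesh` ([volume_mesh()]) and `centreline`.
#' @export
make_tube_volume <- function(radius, length, n_circ = 12L, n_rad = 3L,
                             n_axial = 20L) {
  stopifnot(radius > 0, length > 0, n_circ >= 6L, n_rad >= 1L, n_axial >= 2L)
  phi <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  disk <- rbind(c(0, 0),
                do.call(rbind, lapply(seq_len(n_rad), function(k)
                  cbind(radius * k / n_rad * cos(phi),
                        radius * k / n_rad * sin(phi)))))
  # disk triangulation: fan around the centre, quads between rings
  tri2 <- matrix(0L, 0L, 3L)
  ring_start <- function(k) 1L + (k - 1L) * n_circ # 0-based start of ring k
  for (i in seq_len(n_circ) - 1L) {
    i2 <- (i + 1L) %% n_circ
    tri2 <- rbind(tri2, c(0L, ring_start(1L) + i, ring_start(1L) + i2))
  }
  if (n_rad > 1L) for (k in seq_len(n_rad - 1L)) {
    for (i in seq_len(n_circ) - 1L) {
      i2 <- (i + 1L) %% n_circ
      a <- ring_start(k) + i;      b <- ring_start(k) + i2
      c_ <- ring_start(k + 1L) + i; d <- ring_start(k + 1L) + i2
      tri2 <- rbind(tri2, c(a, b, c_), c(b, d, c_))
    }
  }
  npd <- nrow(disk)
  z <- seq(0, length, length.out = n_axial + 1L)
  pts <- cbind(disk[rep(seq_len(npd), n_axial + 1L), , drop = FALSE],
               rep(z, each = npd))
  tets <- matrix(0L, 0L, 4L)
  for (j in seq_len(n_axial) - 1L) {
    off_b <- j * npd; off_t <- (j + 1L) * npd
    p1 <- tri2[, 1L] + off_b; p2 <- tri2[, 2L] + off_b; p3 <- tri2[, 3L] + off_b
    q1 <- tri2[, 1L] + off_t; q2 <- tri2[, 2L] + off_t; q3 <- tri2[, 3L] + off_t
    tets <- rbind(tets,
                  cbind(p1, p2, p3, q1),
                  cbind(p2, p3, q1, q2),
                  cbind(p3, q1, q2, q3))
  }
  cl <- centreline(cbind(0, 0, z))
  list(mesh = volume_mesh(pts, tets), centreline = cl)
}
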