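# Material-parameter utilities built on the linear thin-wall (Laplace) tube
# law: modulus linearisation of a stress-strain curve over a working pressure
# range, pressure-diameter distension and its inverse (zero-pressure diameter
# reconstruction), and compliance per unit length. The default registry
# carries the reference constants: vein E = 0.445 MPa (linearised over the
# 30-60 mmHg post-operative working range), ePTFE E = 55 MPa, ePU E = 1.5 MPa.

#' Material specification
#'
#' Either an absolute wall thickness or a thickness ratio h/r0 (thickness
#' proportional to the zero-pressure radius) may be given; exactly one is
#' required.
#'
#' @param name material name.
#' @param youngs_modulus Young's modulus (Pa), > 0.
#' @param wall_thickness wall thickness (m), or NULL.
#' @param thickness_ratio h / r0 (dimensionless), or NULL.
#' @return object of class `material_spec`.
#' @export
material_spec <- function(name, youngs_modulus, wall_thickness = NULL,
                          thickness_ratio = NULL) {
  stopifnot(youngs_modulus > 0)
  if (is.null(wall_thickness) == is.null(thickness_ratio))
    stop("give exactly one of wall_thickness or thickness_ratio")
  if (!is.null(wall_thickness)) stopifnot(wall_thickness > 0)
  if (!is.null(thickness_ratio)) stopifnot(thickness_ratio > 0)
  structure(list(name = name, youngs_modulus = youngs_modulus,
                 wall_thickness = wall_thickness,
                 thickness_ratio = thickness_ratio), class = "material_spec")
}

.thickness_at <- function(material, r0) {
  if (!is.null(material$wall_thickness)) material$wall_thickness
  else material$thickness_ratio * r0
}

#' Load the bundled material registry
#'
#' Reads `inst/extdata/materials.yaml`: the reference vein, ePTFE and ePU
#' parameter sets (moduli, thicknesses, zero-pressure diameters).
#'
#' @param path optional path to an alternative YAML registry.
#' @return named list of entries, each with a `material` ([material_spec()])
#'   and `d0` (zero-pressure diameter, m).
#' @export
load_material_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.yaml", package = "graftmetrics")
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e)
    list(material = material_spec(e$name, e$youngs_modulus_Pa,
                                  wall_thickness = e$wall_thickness_m,
                                  thickness_ratio = e$thickness_ratio),
         d0 = e$zero_pressure_diameter_m))
}

#' Stress-strain curve
#'
#' @param strain strictly increasing strains (dimensionless), >= 2 points.
#' @param stress stresses (Pa), same length.
#' @return object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress) {
  stopifnot(length(strain) == length(stress), length(strain) >= 2L,
            all(diff(strain) > 0))
  structure(list(strain = as.numeric(strain), stress = as.numeric(stress)),
            class = "stress_strain_curve")
}

#' Linearised modulus of a stress-strain curve over a pressure range
#'
#' Maps the pressure range to hoop stresses via the Laplace law
#' (sigma = p r / h with the tube's zero-pressure radius and thickness),
#' restricts the curve to the strain interval spanning those stresses
#' (interpolating the endpoints linearly), and returns the least-squares
#' slope of stress against strain over that interval. For an exactly affine
#' curve this recovers its slope regardless of the range.
#'
#' @param curve a [stress_strain_curve()] with increasing stress.
#' @param pressure_range c(low, high) transmural pressures (Pa).
#' @param tube a [tube_spec()] providing r and h for the stress mapping.
#' @return Young's modulus estimate (Pa).
#' @export
linearise_modulus <- function(curve, pressure_range, tube) {
  stopifnot(inherits(curve, "stress_strain_curve"), inherits(tube, "tube_spec"),
            length(pressure_range) == 2L, diff(pressure_range) > 0)
  r <- tube$radius_zero_pressure; h <- tube$wall_thickness
  s_lo <- pressure_range[1L] * r / h
  s_hi <- pressure_range[2L] * r / h
  if (any(diff(curve$stress) <= 0))
    stop("curve stress must be strictly increasing for pressure mapping")
  rng <- range(curve$stress)
  if (s_lo < rng[1L] || s_hi > rng[2L])
    stop(sprintf(
      "pressure range maps to stresses [%.6g, %.6g] Pa outside the curve's attainable span [%.6g, %.6g] Pa",
      s_lo, s_hi, rng[1L], rng[2L]))
  e_lo <- stats::approx(curve$stress, curve$strain, xout = s_lo)$y
  e_hi <- stats::approx(curve$stress, curve$strain, xout = s_hi)$y
  inside <- curve$strain > e_lo & curve$strain < e_hi
  e <- c(e_lo, curve$strain[inside], e_hi)
  s <- c(s_lo, curve$stress[inside], s_hi)
  stats::coef(stats::lm(s ~ e))[["e"]]
}

#' Pressure-distended diameter of a thin-walled linear-elastic tube
#'
#' d(p) = d0 (1 + p r0 / (E h)), the linear Laplace-law distension with
#' r0 = d0 / 2. Hoop strains beyond 0.3 trigger a warning: the linearisation
#' is out of its range.
#'
#' @param material a [material_spec()].
#' @param d0 zero-pressure diameter (m).
#' @param pressure transmural pressure (Pa), >= 0.
#' @return distended diameter (m).
#' @export
tube_distension <- function(material, d0, pressure) {
  stopifnot(inherits(material, "material_spec"), d0 > 0, pressure >= 0)
  r0 <- d0 / 2
  h <- .thickness_at(material, r0)
  strain <- pressure * r0 / (material$youngs_modulus * h)
  if (any(strain > 0.3))
    warning(sprintf("hoop strain %.3g exceeds 0.3: linear tube law out of range",
                    max(strain)))
  d0 * (1 + strain)
}

#' Zero-pressure diameter from a pressurised measurement
#'
#' Exact inverse of [tube_distension()]: solves d(p) = measured_d for d0.
#' With a thickness ratio, the hoop strain p r0 / (E h) = p / (E h/r0) is
#' independent of d0 and the inverse is closed-form; with a fixed thickness
#' the scalar equation is solved by bisection on (0, measured_d] to 1e-12 m.
#'
#' @param measured_d measured diameter (m) at `pressure_at_measurement`.
#' @param pressure_at_measurement transmural pressure (Pa).
#' @param material a [material_spec()].
#' @return zero-pressure diameter d0 (m).
#' @export
zero_pressure_diameter <- function(measured_d, pressure_at_measurement,
                                   material) {
  stopifnot(measured_d > 0, pressure_at_measurement >= 0)
  p <- pressure_at_measurement
  if (p == 0) return(measured_d)
  if (!is.null(material$thickness_ratio)) {
    strain <- p / (material$youngs_modulus * material$thickness_ratio)
    return(measured_d / (1 + strain))
  }
  g <- function(d0) suppressWarnings(tube_distension(material, d0, p)) - measured_d
  lo <- measured_d * 1e-6; hi <- measured_d
  if (g(hi) < 0 || g(lo) > 0)
    stop("no zero-pressure diameter in (0, measured_d] reproduces the measurement")
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (g(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Area compliance per unit length of the linear tube law
#'
#' C(p) = dA/dp with A(p) = pi d(p)^2 / 4, i.e.
#' C = pi d(p) d0 r0 / (2 E h): the local pressure-area distensibility that
#' quantifies graft-vein compliance mismatch.
#'
#' @inheritParams tube_distension
#' @return compliance (m^2 Pa^-1).
#' @export
compliance_per_length <- function(material, d0, pressure) {
  r0 <- d0 / 2
  h <- .thickness_at(material, r0)
  dp <- tube_distension(material, d0, pressure)
  pi * dp * d0 * r0 / (2 * material$youngs_modulus * h)
}
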