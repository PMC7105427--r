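---
title: "Haemodynamic and mechanical performance metrics for arteriovenous grafts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haemodynamic and mechanical performance metrics for arteriovenous grafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftmetrics)
```

## Scope and model

Arteriovenous grafts (AVGs) for haemodialysis access fail predominantly
through venous neointimal hyperplasia at the graft–vein anastomosis, a
response associated with disturbed flow, non-physiological wall shear stress
(WSS) and pulsatile overloading of the venous wall. Fluid–structure
interaction (FSI) simulations of an AVG produce time-resolved WSS, velocity,
pressure, stress and displacement fields on unstructured meshes;
`graftmetrics` implements the post-processing layer that turns those fields
into the comparative performance metrics used to judge graft designs —
without itself solving any flow or mechanics problem.

All metrics are evaluated over one analysed cardiac cycle
$[t_0, t_0 + T]$ (`cycle_window()`). Sample times may be non-uniform, since
FSI solvers commonly refine their stepping through systole; every time
integral in the package is the trapezoidal rule on the actual sample times.

### Wall shear stress metrics

For the WSS vector $\tau(t,\mathbf{x})$ on the luminal surface:

* **TAWSS** $= \frac{1}{T}\int_0^T \lVert\tau\rVert\,dt$ — cycle-averaged
  magnitude; values below 0.1 Pa are flagged as non-physiologically low.
* **WSS\_max** $= \max_t \lVert\tau\rVert$ — the sampled time-maximum (no
  sub-sample interpolation: at typical solver stepping of $10^{-4}$ s the
  difference is negligible and the sampled maximum is reproducible).
  Thresholds of 7 Pa (high) and 40 Pa (endothelial damage) apply.
* **OSI** $= \frac{1}{2}\left(1 -
  \frac{\lVert\int_0^T\tau\,dt\rVert}{\int_0^T\lVert\tau\rVert\,dt}\right)
  \in [0, 0.5]$ — 0 for steady unidirectional shear, 0.5 for perfectly
  oscillatory shear; OSI > 0.25 marks highly oscillatory exposure. The
  $0/0$ case (identically zero shear) is reported as 0 — no oscillation is
  the physically conservative reading — and flagged rather than erroring.
  The magnitude floor defaults to $10^{-12}$ Pa.

Exposure is reported as **area fractions**: the percentage of a region's
area whose elements satisfy a strict inequality at the bound (matching the
printed operators "OSI > 0.25", "TAWSS < 0.1", "WSS > 7", "WSS > 40"; the
boundary set has measure zero, so the choice of strictness is a convention,
documented here once).

Regional maxima use an **artefact-robust rule**: elements are sorted by
value descending and the minimal prefix holding 1% of the region's area is
omitted before taking the maximum, so isolated numerical artefacts (a few
spuriously extreme elements) cannot dominate reported maxima, while genuine
hot spots covering more than 1% of the region survive. Ties break by element
id, making the statistic deterministic.

Medians are **area-weighted** (the value at which cumulative sorted area
first reaches half the region area). Whether medians of this kind should be
area-weighted or element-counted is genuinely open; area weighting was
chosen because element-count medians change under mesh refinement with no
change in the field, which is indefensible for comparing cases meshed
differently. A count-based median stays available behind
`region_median(..., weighted = FALSE)`.

### Flow disturbance

Velocity disturbance is quantified by Reynolds decomposition of the velocity
magnitude $u(t,\mathbf{x}) = \bar{u} + \tilde{u}$ and the cycle RMS of
$\tilde{u}$. The trend $\bar{u}$ is the Fourier reconstruction retaining
cardiac harmonics $0..k$ of frequency $1/T$ (default $k = 10$). This
estimator was an open design choice: no separation method is canonical, and
the absolute RMS depends on the cutoff. Fourier truncation was chosen
because it is parameter-light, reproducible, exactly additive
($u = \bar{u} + \tilde{u}$ at every sample by construction) and exactly
orthogonal on uniform samples, so an injected high-frequency component is
recovered to round-off. Every disturbance table therefore carries its
cutoff. Non-uniform input is linearly resampled onto $2^k$ uniform points
(spacing no larger than the smallest input spacing) before the transform,
and the trend is evaluated back at the original times from its harmonic
coefficients.

Cross-sectional statistics collect mesh nodes whose projection onto the
local centreline tangent lies within a slab of half-width 1 mm (default;
the appropriate width is not derivable from first principles — 1 mm spans a
few node layers of a typical vein mesh without mixing distinct stations) and
report the plain median. The centreline pressure profile time-averages the
nodal pressure and samples it by barycentric interpolation in the containing
tetrahedron, with a nearest-node fallback (warned) for points that escape
the mesh.

### Wall mechanics

Von Mises stress $\sigma_M = \sqrt{\tfrac{3}{2}\,\mathrm{tr}(\sigma_d
\sigma_d)}$ is computed from the deviatoric part of the Cauchy stress; it is
invariant under hydrostatic shifts and rotations (both fuzz-tested). Wall
strain uses the area-based engineering measure
$\varepsilon = \sqrt{(A_n - A_0)/A_0}$ per surface element, which lumps
circumferential and longitudinal stretch. For transiently compressed
elements ($A_n < A_0$) the root has no real value; the package substitutes
the signed extension $-\sqrt{(A_0-A_n)/A_0}$ and flags the samples, keeping
maps total instead of failing mid-pipeline. **Pulsatility** is the
per-element cycle range (max − min). The mechanics table reports, per region
and quantity: area-weighted median of the time-averaged map, median
pulsatility, robust maximum and robust maximum of pulsatility — stress in
kPa, strain in %.

### Regions of interest

The anastomotic region is the set of surface elements whose centroid lies
strictly inside a sphere (default radius 1.2 cm) centred on the junction;
centroid membership is unambiguous and consistent with area-weighted
statistics ("any vertex inside" would double-count boundary elements).
The sphere centre is a required input and is recorded in every report; the
idealised anastomosis generator supplies its junction point as the default.
Graft/vein segmentation assigns each element to the nearest point of a
centreline polyline carrying a `transition` landmark. Within roughly one
vein radius of the junction this assignment is intrinsically ambiguous;
that band lies inside the anastomotic sphere, which is why validation
compares labels outside it (where agreement with the generator's ground
truth is exact).

## The synthetic generator as oracle

The study conditions this package targets come from a patient-specific FSI
run that is far beyond desk scale (multi-day, cluster-size meshes), and no
field data are deposited. Validation therefore rests on synthetic fields
with closed-form metric values:

* **Quasi-steady Poiseuille WSS**: $\lVert\tau\rVert = 4\mu Q(t)/(\pi r^3)$
  uniform over a tube wall. Quasi-steady (rather than Womersley) on purpose:
  the oracle's job is exactly known TAWSS/OSI/WSS\_max under any waveform,
  not unsteady-flow realism. With the reference parameters
  ($Q$ = 600 ml/min, $\mu = 4.5\times10^{-3}$ Pa s, $r$ = 3 mm) this gives
  2.122 Pa.
* **Prescribed-OSI signal**: a two-phase reversing signal whose forward
  fraction $f$ fixes $\mathrm{OSI} = \tfrac{1}{2}(1 - |2f-1|)$. Because a
  continuous reversal instant quantises onto the sample grid, the two
  samples bracketing it take intermediate values solved so that the
  trapezoidal OSI on the actual grid equals the target exactly; targets
  needing a reverse phase shorter than one sample interval are rejected.
* **Laplace-law pressurised tube**: hoop $\sigma_\theta = pr/h$, axial
  $\sigma_z = pr/2h$, radial $\approx 0$, rotated into global coordinates
  per element; its von Mises stress is
  $\sqrt{\sigma_\theta^2 + \sigma_z^2 - \sigma_\theta\sigma_z}$, and element
  areas follow the linear hoop strain $pr/(Eh)$ as $A_n = A_0(1+e)$
  (circumferential stretch at fixed length). Thick walls ($h/r > 0.2$) warn
  but compute.
* **Seeded sinusoidal velocity perturbations** at a frequency above the
  trend cutoff, with per-node random phases: the recovered RMS is
  $\varepsilon/\sqrt{2}$.
* **Idealised end-to-side anastomosis**: two straight tubes joined at one
  third of the venous length, used for region/report integration tests; no
  flow realism is claimed for it.

Default generator parameters are the reference study conditions: graft
zero-pressure diameter 6 mm with 0.63 mm wall, vein 7.14 mm with wall
thickness 10% of the pre-operative radius, graft and vein segments 3 cm and
7.5 cm, blood viscosity $4.5\times10^{-3}$ Pa s and density 1000 kg m⁻³,
venous working pressure 50 mmHg, cycle period 1 s with 600 ml/min mean graft
inflow. The inflow waveform is a parametric stand-in (mean flow plus two
decaying harmonics, strictly positive), not a digitisation of a measured
curve — only its mean, period and positivity matter for the closed forms.

What the generator deliberately does **not** emulate: secondary and
recirculating flow, turbulence spectra, spatially heterogeneous WSS on the
patient geometry, bending of the vessel path, and anisotropic or
viscoelastic wall behaviour. Passing tests therefore demonstrate that the
*metric definitions and statistics* are computed correctly, not that any
particular patient-specific field value is reproduced.

## Material model

Vessel and graft walls are summarised by a linear thin-wall (Laplace) tube
law: $d(p) = d_0\,(1 + p\,r_0/(E h))$.

* `linearise_modulus()` maps a working pressure range (default
  30–60 mmHg) to hoop stresses via $\sigma = p r/h$ and returns the
  least-squares slope of a measured stress–strain curve restricted to that
  interval — exactly the slope for an affine curve, the branch slope for a
  bilinear curve probed inside one branch.
* `zero_pressure_diameter()` inverts the law for the reference (zero
  transmural pressure) diameter. The procedure by which the reference
  vein diameter of 7.14 mm was originally reconstructed from pressurised
  ultrasound measurements is not documented in the available sources, so
  that value is shipped as an input constant in the registry and the
  package's inversion is its own declared model: closed form when the wall
  thickness scales with the radius, bisection to $10^{-12}$ m when the
  thickness is fixed (cross-checked against the closed-form root).
* `compliance_per_length()` is the analytic $dA/dp$ of the law. With the
  registry constants (E = 0.445 / 55 / 1.5 MPa for vein / ePTFE / ePU), the
  vein-to-ePTFE compliance ratio exceeds the raw modulus ratio because the
  vein wall is also thinner — the quantitative face of graft–vein
  compliance mismatch.

Pressures are accepted in mmHg at the interface via `mmhg_to_pa()`
(133.322 Pa/mmHg) and handled in Pa internally; all internal units are SI
(m, s, Pa).

## Numerical choices

* Trapezoidal integration everywhere a cycle integral appears; second-order
  convergence is asserted in the tests.
* OSI values are clipped to $[0, 0.5]$ after quadrature (round-off can
  overshoot by $\sim10^{-16}$).
* Tetrahedra are re-oriented to positive volume on load; degenerate
  (zero-area / zero-volume) elements are rejected at construction.
* VTK XML (ASCII) is the canonical file dialect; doubles are written with
  17 significant digits so write→read round trips are exact. A minimal
  legacy ASCII `.vtk` reader covers import. HDF5-backed series are out of
  scope for this implementation.
* Reports use deterministic cell ordering and `write.csv`, so a rerun of
  the same configuration is byte-identical — asserted in the pipeline
  tests.

## Problem sizes

The bundled analysis scripts and tests run on deliberately small meshes
(demo anastomosis ≈ 1000 triangles, tube volumes ≈ 3600 tets, 12–64 time
samples): these sizes already give the closed-form oracles to the asserted
tolerances, and the package's statistics are mesh-size-independent by
construction (area weighting), so nothing is learned from larger synthetic
meshes. All operations scale linearly in elements × time samples except
point location in tetrahedra, which is brute-force per point and intended
for centreline-resolution queries, not volume-dense sampling.

## Demo comparison

```{r, eval = FALSE}
cfg <- make_demo("demo", seed = 7)
res <- run_pipeline(cfg)
head(res$report)
```

The demo pairs a stiff (ePTFE-like, 55 MPa) and a compliant (ePU-like,
1.5 MPa) case on the same geometry and waveform. The contrast between the
cases is produced by the tube law, not by a flow solution: the compliant
graft distends at the 50 mmHg working pressure, so its prescribed
quasi-steady WSS is lower (the $1/r^3$ Poiseuille scaling), and its wall
strain is larger (the $1/E$ hoop-strain scaling); WSS inside the anastomotic
sphere is amplified (impingement) and modulated by a zero-mean cosine so the
oscillatory-shear rows are exercised. These are arithmetic consequences of
the generator's construction and are asserted as such in the tests.

## Known limitations

* No flow or structural solving: stresses, areas and velocities are inputs.
* The Fourier-truncation trend makes absolute perturbation RMS
  cutoff-dependent; compare RMS values only at equal cutoffs.
* The linear tube law loses validity above ~30% hoop strain (warned).
* Strain is computed per surface; inner and outer wall surfaces should be
  supplied as separate meshes and are reported separately, not pooled.
* No additional WSS indices (relative residence time, transWSS); the
  metric-map container and threshold registry are the extension points.
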