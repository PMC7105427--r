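Package: graftmetrics
Title: Haemodynamic and Mechanical Performance Metrics for Arteriovenous Graft Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for time-resolved vascular simulation output on
    unstructured meshes: time-averaged wall shear stress (TAWSS), time-maximum WSS and
    the oscillatory shear index (OSI) with threshold-exceedance area fractions and
    artefact-robust maxima; Reynolds decomposition of pulsatile velocity signals into a
    cardiac-harmonic trend and high-frequency perturbations with RMS disturbance maps;
    von Mises stress, area-based engineering strain and cycle pulsatility on vessel
    walls; spherical anastomotic regions of interest and comparative report assembly;
    thin-wall tube-law material utilities (modulus linearisation, pressure-diameter
    inversion, compliance); and a synthetic-field generator (pulsatile tube flows,
    pressurised-tube wall mechanics, idealised graft-vein anastomosis) with analytically
    known metric values so every stage is verifiable without a fluid-structure
    interaction solver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
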