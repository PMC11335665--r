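Package: eddyrisk
Title: Eddy-Dissipation Cell-Death Risk Assessment for Perfusion Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Links macroscopic flow descriptors in cell-culture flow systems to
    the risk of cell death from turbulent eddy dissipation. Implements the
    Kolmogorov-microscale energy-cascade scaling (smallest eddy = largest eddy
    / Re^(3/4)) with a configurable cell-diameter danger threshold, a critical
    eddy-size curve, and a desk-scale 2-D incompressible laminar finite-volume
    flow solver for parameterized baffled bioreactor geometries. Post-processing
    detects recirculation zones from streamfunction topology, measures the
    largest wall-attached eddies, and extracts wall-shear-stress profiles, so
    that a full design-by-flow-rate condition matrix can be screened for
    cell-lethal shear or cell-scale eddy dissipation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
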