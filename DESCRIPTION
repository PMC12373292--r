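Package: lumenoid
Title: Multicellular Phase-Field Simulation of Organoid Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of organoids as a collection of coupled
    phase fields: one field per cell plus a shared lumen field, advanced by
    forced Allen-Cahn dynamics on a regular grid. Cell division is gated by
    minimum-volume and minimum-age criteria, with the division plane set by
    relaxed spindle-pole positions and a micro-lumen nucleated between the
    daughter cells. The package also provides the morphometric layer used to
    characterize simulated (or segmented) organoids: lumen occupancy, stable
    lumen counts, sphericity, the lumen index, trend statistics, and a
    seven-class phenotype assignment; parameter-sweep drivers for phase
    diagrams; a reduced continuum theory of lumen growth (critical radius,
    osmotic pressure, water-permeation dynamics, hydrostatic-pressure
    fitting); and conversion between dimensionless model units and physical
    units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
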