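Package: retinOS
Title: Orientation Selectivity Analysis for Gap-Junction-Coupled Retinal
    Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing orientation selectivity (OS) in OFF OS
    retinal ganglion cells that inherit their tuning through electrical
    (gap-junction) synapses. Implements the vector-sum orientation and
    direction selectivity indices, cycle averaging and F1 amplitudes for
    drifting-grating responses, peri-stimulus time histogram statistics and
    OFF OS cell classification, circular-statistics tests (Hodges-Ajne,
    Hartigan dip), dendritic-arbor morphometrics (centre-of-mass vectors and
    the dendritic orientation index), voltage-clamp current analysis
    (IV curves, reversal-potential estimation, electrical-versus-chemical
    classification, conductance conversion, spike removal), a
    conductance-based leaky integrate-and-fire model driven by cycle-averaged
    synaptic currents, and the current-shuffling bootstrap that isolates the
    gap-junction contribution to model tuning. A synthetic-data module
    generates all inputs with the statistical structure of the recordings so
    the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
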