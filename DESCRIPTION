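Package: torsodft
Title: Defibrillation Field Simulation in Synthetic Torso Phantoms
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for predicting defibrillation efficacy of
    implantable cardioverter-defibrillator (ICD) electrode configurations.
    Generates a cohort of parametric torso phantoms with healthy,
    hypertrophic, dilated and ischaemic cardiomyopathy heart variants,
    voxelizes them into region-labelled tetrahedral meshes with rule-based
    myocardial fibre orientations, solves the quasi-static shock-field
    Laplace problem with heterogeneous anisotropic conductivities by the
    finite element method, and derives defibrillation thresholds via the
    critical-mass criterion, shock energies, impedances and mean electric
    fields, with paired nonparametric cohort statistics. Reads and writes
    openCARP text meshes and legacy VTK unstructured grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
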