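Package: rfasim
Title: Desk-Scale Simulation of Radiofrequency Ablation of Liver Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CPU-only simulator for percutaneous radiofrequency ablation
    (RFA) of hepatic tumors. Generates synthetic patient phantoms (liver
    region of interest, tumor, vessels, per-voxel tissue properties),
    represents simple and umbrella-shaped RFA probes, solves the Pennes
    bioheat equation on a regular voxel grid with a Gaussian power
    deposition and vessel heat sinks, couples it to a three-state
    (alive/vulnerable/dead) thermal cell-death model, and extracts the
    predicted coagulation zone. Supports landmark-based rigid registration,
    parameter-space ensemble sampling with contour-boxplot summaries
    (band depth, median, bands, outliers), lesion overlap and
    surface-distance validation metrics, and a safety-margin classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
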