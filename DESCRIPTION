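Package: lipidfcs
Title: Simulation and Fluctuation Analysis of Lipid Diffusion in Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying nanoscale lipid diffusion in membranes with
    fluorescence correlation spectroscopy (FCS). Provides a particle-based
    Monte Carlo simulator of free, transiently trapped, and meshwork-hindered
    (hop) diffusion in a two-dimensional membrane probed by a Gaussian
    observation spot; a multi-tau autocorrelator with a brute-force reference;
    analytic two-dimensional FCS models with nonlinear fitting, anomalous
    subdiffusion and triplet terms, transit-time to diffusion-coefficient
    conversion and molecular brightness (counts per molecule); a scanning-FCS
    carpet pipeline with cropping, photobleaching correction and per-pixel
    fitting; log-normal and double log-normal maximum-likelihood analysis of
    pooled transit times with Bayesian Information Criterion model selection;
    and quantification of liquid-ordered phase partitioning (%Lo) from line
    profiles across phase-separated vesicle images. Seeded synthetic-data
    generators with recorded ground truth cover every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
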