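Package: raftreg
Title: Nanoscale Lipid Domain Sizing, Mobility, and Leaflet Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers true diameters of nanoscale ordered and disordered lipid
    domains from their lateral mobility using a generalized Saffman-Delbruck
    diffusion law with a constant apparent-diameter offset, estimates
    per-domain diffusion coefficients from single-particle trajectories via
    mean-squared-displacement analysis with a simple-diffusion filter, backs
    out membrane viscosities from the fitted hydrodynamic parameters,
    cross-validates single-lipid mobilities against two-dimensional
    fluorescence correlation spectroscopy fits, quantifies interleaflet domain
    registration from paired channel images as a Jaccard overlap index, and
    evaluates the registration energetics (line-tension rim energy versus
    undulation-mediated area coupling) that set the critical crossover
    diameter. A synthetic-data module generates trajectories, image pairs, and
    autocorrelation curves with the statistical structure the analysis
    assumes, so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
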