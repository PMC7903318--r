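Package: rootCT
Title: Semiautomatic Root Segmentation and Trait Extraction from X-Ray CT
    Volumes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments plant root systems from 3D X-ray computed tomography
    volumes of soil-grown plants and derives architectural traits. Two
    parallel detection branches are fused: a multiscale Hessian-based
    vesselness filter for fine, tubular roots and a local 3D-variance
    homogeneity filter for thick storage roots. The fused binary mask is
    cleaned (median filter, minimum-volume component filter), thinned to a
    curve skeleton, and converted into a directed root graph from which
    root volume, root length, biomass depth quantiles, convex-hull form
    fraction, root angles, densities and tip counts are computed. Root
    architectures are exported as RSML. A synthetic root-phantom generator
    with full ground truth supports validation without CT scans, and a
    batch mode processes time series with one shared parameter set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    igraph,
    xml2,
    jsonlite,
    yaml,
    rlang,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Segmentation, Visualization, Phenotyping
RoxygenNote: 7.3.3
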