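Package: ckflux
Title: Cytokinin Membrane-Transport Kinetics from Radiotracer Accumulation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and fits the kinetics of cytokinin membrane transport in
    plant cell suspensions from radiotracer accumulation time courses. Provides
    a closed-form compartmental accumulation model with first-order influx and
    efflux rate constants and a surface-adsorption term, bounded nonlinear
    least-squares fitting per assay or jointly across assays with shared efflux
    and adsorption parameters, piecewise fits for mid-assay inhibitor
    treatments, saturation (dose-response) modelling of influx constants versus
    competitor concentration with IC50 estimation, top-view shoot-area
    segmentation of RGB scans in CIELAB space, qPCR relative-expression
    computation against two reference genes, and seeded synthetic-data
    generators with ground-truth records for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
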