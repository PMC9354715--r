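Package: melaninTA
Title: Pump-Probe Transient-Absorption Analysis of Eumelanin and Pheomelanin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free discrimination of eumelanin and pheomelanin in
    pigmented tissue from femtosecond pump-probe (transient-absorption)
    microscopy delay stacks. Provides signed-exponential transient-absorption
    models with instrument-response convolution, per-pixel multiexponential
    decay fitting with multistart nonlinear least squares, two-delay pigment
    unmixing with DC transmission normalization, tumor-margin segmentation
    scored by Dice overlap and boundary distances, and a seeded synthetic
    tissue-phantom generator that renders ground-truthed delay stacks for
    validation. Stacks, phantoms and pigment maps are stored as multi-page
    32-bit float TIFF with JSON metadata sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    minpack.lm,
    pracma,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
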