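Package: ColonyKinetics
Title: Growth Kinetics of Arrayed Microbial Colonies from Time-Lapse Plate
    Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the growth of high-density arrayed microbial colonies
    (384/1536 format) from time-lapse transmitted-light plate scans. Colony
    growth is measured as integrated pixel absorbance over the whole colony
    region (mass) or over a fixed-diameter center disc (mass*), a metric
    resistant to growth suppression by neighboring colonies. Time series are
    fitted to the Gompertz model to derive lag time (LTG), maximum growth
    rate (MGR) and saturation point (SPG); plate, row/column and spatial
    biases are removed by median-ratio normalization; the growth-rate
    dependence of lag and yield is subtracted using theoretical
    lag/maintenance-energy models fitted by least trimmed squares; and
    growth-defective strains are selected with a rank-product permutation
    test with permutation-based false discovery control. A synthetic-data
    module generates plate image stacks and screen tables with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
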