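Package: roscav
Title: Antioxidant Capacity Analysis for Reactive Oxygen Species Scavenging Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for in-vitro reactive oxygen species (ROS)
    scavenging assays: percent-inhibition and IC50 estimation (with censored
    "no effect" outcomes) for endpoint assays such as ABTS radical cation
    decolorization, hypochlorous acid capture, superoxide/NBT and hydrogen
    peroxide/TNB readouts; competitive-kinetics treatment of the crocin
    bleaching assay (bleaching-rate extraction, ka/kc slope regression,
    Trolox equivalents); IC50-proportioned mixture design with Loewe-additive
    projection and an additivity index; and a deterministic synthetic
    assay-data generator so every stage of the pipeline can be exercised
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
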