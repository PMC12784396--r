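Package: hemoscape
Title: Multi-Readout Integration of Hemoglobin and Heme Toxicity in
    Brain-Slice Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for hemoglobin/heme toxicity
    experiments in organotypic brain-slice cultures. Provides seeded
    synthetic-data generators (per-condition readout pools, two-channel
    fluorescence images, negative-binomial count matrices),
    pseudocytometric neuronal-death classification (Otsu segmentation
    plus k-means intensity clustering), biochemical unit conversions
    (TBARS absorbance to malondialdehyde equivalents, LDH
    percent-of-lysis), gene-set stress and adaptation scoring on
    variance-stabilized expression, and a bootstrap pseudoslice
    principal-component analysis that integrates five destructive
    readouts into an oxidative-toxicity versus metabolic-adaptation map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    fgsea,
    graphics,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
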