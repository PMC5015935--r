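Package: screenerr
Title: Error Models and Diagnostics for Pooled Genetic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of systematic error sources in pooled
    retroviral and lentiviral genetic screens. Models reverse-transcriptase
    template switching between co-packaged viral genomes, which uncouples DNA
    barcodes from their library elements, with the homozygous-virion
    correction for undetected recombination events; residual packaging-plasmid
    carryover into transduced-cell DNA and its dilution across population
    doublings, including copy-number arithmetic and a qPCR relative-signal
    model; and GC-dependent multi-template PCR amplification under reagent
    saturation, the mechanism by which template overabundance in reference
    samples produces artifactual depletion of GC-rich elements. Includes
    count normalization, log2 fold-change, barcode concordance, subpool
    distortion and GC-bias diagnostics, plus reproducible synthetic screen
    generators for each scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
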