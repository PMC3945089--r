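Package: thermolocus
Title: Thermodynamic Modeling of Gene Expression from an Intergenic Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a two-tiered, statistical-thermodynamics model of spatial
    gene expression from the DNA sequence of a gene's intergenic locus.
    Binding-site occupancy of transcription factors within candidate
    sequence windows is summed over all non-overlapping binding
    configurations (Shea-Ackers ensemble) to predict each window's
    expression readout along a one-dimensional spatial axis; the locus
    readout is a learned non-negative weighted sum of window readouts.
    Includes the weighted Pattern Generating Potential score for
    comparing spatial expression profiles, Metropolis-Hastings sampling
    of regulatory architectures, in-silico transcription-factor
    knockdowns for regulatory-network inference, enhancer cross-talk
    analysis, and synthetic-data generators with planted enhancers for
    validation and negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
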