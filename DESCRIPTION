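Package: omprofiler
Title: Outer-Membrane Proteome Inference from Label-Free Quantitative
    Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the outer-membrane (OM) protein complement of a
    Gram-negative bacterium from subcellular-fractionation label-free
    quantification (LFQ) proteomics. Provides LFQ missing-value imputation
    at a configurable offset below the per-sample detection minimum,
    compartment-composition and enrichment-factor analysis of membrane
    fractions, a multi-predictor consensus rule assigning OM, periplasmic
    and other localizations, condition fold-change and exclusivity calls,
    a heuristic PEP-CTERM sorting-signal scanner based on sliding-window
    hydropathy, and a fully-labelled synthetic data generator emulating a
    fractionation study so that every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
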