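Package: sigrefit
Title: Mutational Signature Refitting for Individual Tumor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the contribution ("exposure") of each signature in a
    given set of mutational signatures to the somatic single-nucleotide
    variants of an individual tumor, by quadratic programming constrained to
    the probability simplex. Supports both the 96-category trinucleotide
    (Alexandrov-type) signature model and the independent-feature
    (Shiraishi-type) model, including featurization of SNVs from VCF/MPF
    files against a reference genome with optional transcription-strand
    annotation, conversion and downgrading between signature models,
    signature distances and set mappings, explained-variance based subset
    selection, and simulation of tumor genomes from known exposures for
    method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
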