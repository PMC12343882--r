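Package: clonalniche
Title: Clonal T-Cell Expansion, Spatial Niche, and Transgene Detection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for distinguishing a transgene-derived T-cell
    malignancy from a clonal but possibly reactive T-cell expansion in
    single-nucleus spatial transcriptomic and whole-genome sequencing data.
    Provides a closed-form Poisson power model for detecting an integrated
    CAR construct in WGS together with a MAPQ-filtered construct read
    counter; radius-based spatial neighborhood enrichment with a
    label-permutation null and Z-score matrix; per-UMI consensus genotyping
    of a somatic variant from read-level allele calls; TCR clonotype
    grouping with biallelic-rearrangement flagging and exact CDR3
    amino-acid matching against public TCR references; nonnegative
    least-squares scoring of predefined T-cell gene-expression programs and
    expression-matched control gene-set signature scoring; and a synthetic
    lymph-node generator that emulates a clonally expanded, spatially
    clustered CD4+CD8+ double-positive population so the full pipeline is
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rsamtools,
    igraph,
    jsonlite,
    methods,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
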