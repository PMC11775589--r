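Package: xnafidelity
Title: XNA Polymerase Fidelity from Watermarked Clone Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for polymerase fidelity assays in which a
    DNA template is replicated through a xeno nucleic acid (XNA) intermediate
    (DNA -> XNA -> DNA), the cDNA product is cloned and Sanger sequenced, and
    per-substitution error rates and an aggregate fidelity score are computed
    from clones carrying engineered primer-binding-site watermarks. Provides
    the assay-design data model, FASTA input/output, a deterministic
    affine-gap global aligner with indel left-normalization, watermark-based
    contaminant filtering, mutation calling, error-rate statistics with exact
    Poisson intervals, and a seedable synthetic clone generator with a
    composable two-step substitution/indel error model for end-to-end
    verification without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
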