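Package: radsweep
Title: Similarity-Threshold Sensitivity of De Novo RAD-Seq Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how the sequence-similarity threshold used for de
    novo assembly of fixed-length RAD-Seq/GBS reads distorts downstream
    population-genetic inference. Provides a two-population isolation-model
    coalescent simulator that emits short reads with known per-read truth, a
    deterministic re-implementation of threshold clustering into alleles and
    catalog loci, diagnostics for over-splitting (divergent alleles split
    into separate loci) and under-splitting (paralogs merged into one
    locus), per-locus genetic distances, Hudson Fst, diversity estimators, a
    moment estimator of ancestral theta and divergence time under the
    isolation model, neighbor-joining gene-tree depths, and an orchestrated
    sweep over thresholds that reports how each statistic responds.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
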