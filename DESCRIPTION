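Package: snfmap
Title: Compound Activity Mapping by Similarity Network Fusion of Phenotypic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates two orthogonal phenotypic screening platforms (a
    gene-signature reporter assay and an image-based cytological profiling
    assay) into a single fused similarity network using a k-swept, aggregated
    adaptation of Similarity Network Fusion; clusters the fused network with
    deterministic hierarchical affinity propagation; benchmarks
    mechanism-of-action recovery with in-class Kolmogorov-Smirnov tests and
    hypergeometric cluster enrichment; and scores untargeted-metabolomics
    features ("baskets") by the coherence of the fused phenotypes of the
    natural-product fractions that contain them (the SNF score), producing
    bipartite Compound Activity Maps that link extracts to candidate
    bioactive features. Includes a synthetic two-platform screen and
    metabolome generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
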