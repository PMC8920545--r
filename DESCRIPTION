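Package: osteoscreen
Title: Discovery of Osteogenic Differentiation Candidate Genes from
    Multi-Batch Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for screening candidate regulators of
    osteogenic differentiation in bone marrow-derived mesenchymal stem
    cells from merged log2 expression time courses. Covers probe-to-gene
    collapsing, parametric empirical-Bayes batch adjustment, moderated
    two-group differential expression with asymmetric log-fold-change
    gates, single-sample gene set enrichment scoring of osteoblast
    pathway activity, gene-pathway association, threshold-swept
    co-expression networks with frequency-consensus hub calling,
    protein-protein interaction degree hubs, hypergeometric
    over-representation analysis, pre-ranked gene set enrichment with a
    permutation null, and an evidence-integration ranking with a novelty
    filter. Ships a deterministic synthetic multi-batch time-course
    generator with planted ground truth so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
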