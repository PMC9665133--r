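Package: lriscape
Title: Downstream Analysis of Long-Range Promoter Capture Hi-C Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of significant promoter
    Capture Hi-C (pCHi-C) interaction calls across a differentiation time
    course. Classifies interactions into short-range (< 1 Mb) and
    long-range (1-2 Mb) classes, measures replicate concordance in 50-kb
    distance bins and sharing across time points, annotates topologically
    associating domains (TADs) by their long-range interaction content and
    chromHMM state coverage, calls A/B compartments from binned chromatin
    accessibility via a correlation-matrix eigenvector, tests feature
    enrichment in LRI TADs by permutation and hypergeometric tests,
    stratifies gene expression by interaction class, and maps long-range
    cis-eQTLs restricted to physically interacting SNP-gene pairs with
    LD-pruned Bonferroni correction. Ships a synthetic-study generator
    with planted ground truth so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
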