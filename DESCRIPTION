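Package: melprog
Title: Co-Expression Modules, Survival Signatures and Histone PTM
    Dynamics in a Cellular Model of Melanoma Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stepwise tumour-progression cell-line panels
    (melan-a, 4C, 4C11-, 4C11+). Builds unsigned weighted gene co-expression
    networks with soft thresholding and topological overlap, detects and merges
    co-expression modules, computes module eigengenes and intramodular
    connectivity, and correlates modules with ordinal/binary phenotype
    encodings (tumour state, progression, EMT, metastasis). Ranks hub genes and
    extracts weighted hub subnetworks; performs hypergeometric gene-set
    enrichment with ortholog mapping; runs median-split Kaplan-Meier/log-rank
    and Cox proportional-hazards screens for single genes and multi-gene hub
    signatures. Quantifies histone post-translational modifications from
    peptide-area tables (relative abundances, global and single-mark levels,
    replicate correlations, ANOVA with Tukey contrasts), clusters combinatorial
    PTM profiles by fuzzy c-means with automatic fuzzifier and cluster-number
    estimation, and assigns marks to progression, EMT and metastasis phenotypes
    by rule-based significance patterns. A synthetic-data generator with
    planted ground truth exercises every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust,
    jsonlite
Config/testthat/edition: 3
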