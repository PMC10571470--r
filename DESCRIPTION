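Package: cafscape
Title: Spatial Proximity, Rank Aggregation and Specificity Scoring for
    Cancer-Associated Fibroblast Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for pan-cancer spatial single-cell studies of
    cancer-associated fibroblasts (CAFs). Implements per-cell spatial k-distance
    to a reference cell type with per-slice proximity rankings, robust rank
    aggregation (RRA) of ranked lists via order-statistic beta scores,
    proximal/distal enrichment testing with paired t-tests, the Jensen-Shannon
    regulon specificity score (RSS), transcriptional-homogeneity measurement by
    normalized mutual information over discretized profiles, cancer-preference
    odds ratios with Fisher tests, and a gene-set scoring suite (ssGSEA,
    AUCell-style recovery-curve AUC, geometric-mean, mean and weighted-sum
    scores). Ships synthetic-data generators with planted spatial attraction,
    marker genes, specific regulons, consensus items and bulk group effects so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    fgsea,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
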