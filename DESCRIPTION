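Package: screenra
Title: Rank Aggregation Meta-Analysis of Genetic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combines candidate tables from independent genetic screens with
    heterogeneous genome coverage into a single aggregated candidate ranking.
    Each screen is converted to a base ranker (significant genes ranked 1..k,
    tested non-significant genes at rank k+1) and base rankers are aggregated
    by geometric-mean Borda scoring over a fixed gene space. Includes simple
    cross-screen overlap analysis with driver-gene filtering, hypergeometric
    overrepresentation analysis against GMT gene-set collections, novelty
    annotation against a known-target list, preranked gene set enrichment
    analysis (weighted running-sum statistic with permutation nulls), a
    minimal two-group rank-sum differential expression routine, and a
    synthetic-data generator that plants ground truth so the whole pipeline
    can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
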