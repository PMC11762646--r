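Package: mirgold
Title: Gold-Standard microRNA-mRNA Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates microRNA-mRNA interaction records from heterogeneous
    database exports into an evidence-filtered "gold standard" bipartite
    network, and provides the statistics used to characterise such networks:
    degree-class abundance tables, maximum-likelihood fitting of discrete
    abundance models (zeta power law, log-series, geometric) with AIC model
    selection, plug-in mutual information with bootstrap confidence intervals
    and permutation significance, hypergeometric over-representation analysis
    of hub genes, target-set overlaps, and 3'UTR-length correlation analysis.
    A seeded synthetic-data generator emulates every input format with known
    ground truth so the full pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
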