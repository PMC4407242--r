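Package: associome
Title: Comorbidity Analysis of Disease-Gene Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how strongly pairs of diseases share associated
    genes and how tightly those shared genes interact in a molecular
    network. Implements three set-overlap relation indices (intersection,
    Jaccard, Meet/Min) with empirical p-values from a random-disease-pair
    permutation null, a degree-matched random-network null for the
    connectivity of comorbid gene sets, Gene Ontology overrepresentation
    re-ranked by a network connectivity rate (CR), and enumeration of
    disease-to-disease molecular pathways matching a node-class pattern.
    Ships a synthetic knowledge-base generator with planted comorbidity
    and enrichment structure so the whole pipeline is testable without
    proprietary interaction databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
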