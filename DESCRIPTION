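Package: litdisc
Title: Literature-Based Discovery of Hidden Biomedical Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for literature-based discovery over dated abstract corpora.
    Tags biomedical concepts (genes, diseases, drugs, pathways, biological
    processes) in abstracts with cleaned keyword thesauri, scores pairwise
    co-occurrence with a 1-100 rescaled log10 mutual-information ratio, and
    performs open and closed ABC discovery of hidden relationships through
    shared intermediate concepts. Includes a literature-partitioning
    validation framework (ROC/AUC, FPR-bounded score cutoffs, publication
    time-lag statistics) and a seeded synthetic-corpus generator that plants
    ground-truth co-occurrences and hidden relationships for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    xml2,
    ggplot2,
    jsonlite,
    generics,
    lubridate,
    withr,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
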