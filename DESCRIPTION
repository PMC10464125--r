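Package: micrometab
Title: Infer Disease-Metabolite Associations from Gut Microbe Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers quantitative disease-metabolite associations from two
    curated gut-microbiome tables: directed disease-microbe associations at
    the genus level and presence-only microbe-metabolite production links at
    the strain level. Genus-level directions are propagated to strains via an
    NCBI-style taxonomy lineage, and every disease-metabolite pair is scored
    with an association strength score S_as = m/M - n/N and a confidence
    score S_ac = (m+n)*|S_as|, then filtered with meaningfulness thresholds
    and classified as marker-like or drug-like. Includes harmonization
    (deduplication, contradiction removal), direction-consistency validation
    against experimental labels, a seeded synthetic-data generator with
    planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
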