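Package: gexpoconnect
Title: Semantic Connectors for Integrating Gene Expression Analysis Tools
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ontology-driven data connectors for moving bulk gene expression
    data between analysis tools. Bundles a reference gene-expression ontology
    as a queryable concept graph, a connector engine with four serial
    functional blocks (data input, lifting, lowering, data output) and
    machine-validated concept equivalence tables, and six concrete connectors
    covering two-color microarray merging and KEGG color-list export, SAM/GFF
    read-to-gene counting with library-size normalization, and virtual
    two-color ratio construction from one-color intensities with
    significance filtering. Deterministic synthetic-data generators emulate
    each input shape so every transformation is testable offline.
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
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
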