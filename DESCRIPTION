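Package: sdrfkit
Title: SDRF-Proteomics Metadata Annotation Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A headless engine for annotating mass-spectrometry proteomics
    experiments in the SDRF-Proteomics tab-delimited standard. Parses OBO
    controlled vocabularies into gzipped JSON artifacts (flat element
    lists, nested label trees, select-widget node trees) with autocomplete
    search and ancestor queries; generates species-based SDRF templates;
    maps local metadata tables into SDRF columns with ontology
    canonicalization; expands rows over isobaric and metabolic label
    channels (TMT, iTRAQ, SILAC); validates structure, required columns,
    key=value cells and term compliance; and stamps a canonical SHA-256
    submission hash. Includes deterministic fixture generators and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
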