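Package: ontovalid
Title: Ontology-Aware JSON Schema Validation for Life-Science Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validates JSON metadata documents against JSON Schema (draft-07)
    checklists extended with four custom keywords for semantic validation:
    isValidTerm, isChildTermOf, isValidTaxonomy and graph_restriction. Ontology
    content is loaded from OBO flat files and taxonomy content from NCBI-style
    nodes/names dumps into a local graph backend that answers term-existence
    and subsumption queries, so whole checklists (e.g. MIAPPE-style sample
    metadata) can be validated offline. Validation runs as a library call, a
    one-shot command-line script, or an HTTP service with single and batch
    endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    httpuv,
    curl
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
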