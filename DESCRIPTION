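Package: ontoview
Title: Validate Expert Term Hierarchies Against Reference Ontologies and
    Build Simplified Ontology Views
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for checking expert-curated anatomical and cell-type
    hierarchies (ASCT+B-style tables) against the structure of reference
    ontologies such as Uberon and the Cell Ontology, and for deriving
    simplified, grouping-safe ontology views. Includes a rule-based
    materializer of asserted and inferred existential relationships (the
    "redundant graph": subClassOf transitivity, property hierarchies,
    transitive properties, subclass propagation and property chains), an
    ordered relation-validation procedure with most-specific fallback
    suggestions, minimal view extraction with entailment-preserving
    transitive reduction, readers and writers for OBO Graphs JSON and edge
    TSV, and graphical (DOT) and tabular (CSV) reporting. Ships mini-ontology
    fixtures and a seeded random-ontology generator so every stage is
    testable offline.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
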