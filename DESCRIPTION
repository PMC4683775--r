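Package: studyframes
Title: Frame-Based Representation and Management of Clinical Study Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, frame-based model for clinical and epidemiological
    study metadata. Study elements (items, modules, pages, codelists) are
    instances of an ontology of categories with slots and facets, built on a
    bootstrapped task ontology. The package manages the study structure as an
    ordered containment forest validated against declarative hierarchy rules,
    imports and exports metadata through configurable mappings for ODM-style
    XML and delimited tables, annotates element/value combinations with
    concepts from external ontologies loaded from OBO flat files, and
    evaluates typed rule expressions over study elements. Includes fixture
    generators, JSON project persistence, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
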