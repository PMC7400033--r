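Package: adronto
Title: Build and Analyse Adverse-Drug-Reaction Ontologies from Package Inserts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts semi-structured drug package inserts into a formally
    organised adverse-drug-reaction (ADR) ontology. Provides a nine-dimension
    class schema with eight semantic relation types, CIOMS occurrence-frequency
    classification, CTCAE severity grading, dictionary-based named entity
    recognition over titled insert sections, section-title relation extraction
    into provenance-annotated semantic triples and composite drug-ADR knowledge
    units, machine-executable biocuration rules, deterministic ontology
    assembly with Turtle/OWL-XML/JSON serialisation, structural quality
    evaluation, and the bioinformatic summary reports (triple-type
    distributions, per-ingredient tables, ADR category tables, top-ranked ADRs
    and contraindicated populations). A seeded synthetic-corpus generator with
    a ground-truth manifest makes the whole pipeline testable without access
    to licensed vocabularies or regulator corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    stringr,
    stringi,
    jsonlite,
    xml2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
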