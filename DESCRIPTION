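Package: ehr2omop
Title: Dual-Model EHR Standardization: EN/ISO 13606 Extracts to OMOP CDM via Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tooling for converting raw hospital relational data into
    EN/ISO 13606-normalized electronic health record (EHR) extracts,
    representing the archetyped concepts in a three-layer ontology
    (archetype concept classes, EN/ISO 13606 reference-model mapping,
    OMOP Common Data Model mapping), loading patient data as ontology
    instances, and exporting pseudonymized OMOP CDM clinical tables
    through generated graph queries. Ships a library of twelve
    entry-level archetypes, toy terminology mapping tables
    (ICD-10-CM, LOINC, SNOMED CT) and a deterministic synthetic
    hospital-source generator so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
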