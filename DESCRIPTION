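Package: dbsdata
Title: Patient-Centric Data Management for Deep Brain Stimulation Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated research data store for deep brain stimulation
    (DBS) cohorts. Provides a patient-centric relational schema in a
    single-file SQLite database, ingestion of REDCap-style longitudinal CSV
    exports through declarative mapping files with regex cleaning and field
    validation, a BIDS raw/derivatives image layout with cross-space
    filename derivation, file provenance and spatial-transformation lineage
    tracking, a unified query layer for group analyses, and a seeded
    synthetic-cohort generator so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    RNifti,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
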