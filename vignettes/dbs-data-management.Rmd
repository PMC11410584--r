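---
title: "Managing DBS cohort data: schema, layout and provenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing DBS cohort data: schema, layout and provenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsdata)
```

## The problem

A deep brain stimulation (DBS) study produces three intertwined data
streams. Clinical data — demographics, medication schedules, pre- and
post-operative scoring-scale evaluations, targeting coordinates,
microelectrode-recording summaries, stimulation-test outcomes, implanted
electrode positions, chronic stimulation settings — is captured on
structured forms in an EDC system and exported as longitudinal CSV.
Imaging data arrives as NIfTI volumes across pre- and post-operative
sessions. Group analysis then generates a third stream: segmentations,
patient-to-atlas warps, images resampled into common atlas spaces,
simulated volumes of tissue activated. `dbsdata` gives all three a single
coordinated home: an embedded relational database for tabular data and
file references, a BIDS raw/derivatives tree for the files themselves,
and ingestion pipelines that keep the two synchronized.

## The relational schema

The schema is patient-centric: 28 tables with 230 columns and 33
foreign-key links, shipped as one canonical plain-text DDL
(`inst/sql/schema.sql`) that is the single source of truth.
`schema_stats()` always introspects the live catalog
(`sqlite_master`, `PRAGMA table_info`, `PRAGMA foreign_key_list`) rather
than echoing constants, which turns the structural claim into a checkable
property of the artifact. Tables are organized in content groups
(`table_groups()`); every group except Electrodes contains at least one
table with a direct foreign key to `Patients`. Electrode models are
study-level reference data and instead link into `Files`, pointing at
their simulation model files.

Design choices worth stating explicitly:

* **Surrogate integer keys everywhere**, with `study_code` as the
  patient's unique natural identifier. Joins stay stable regardless of
  site identifier conventions; record ids from different centers cannot
  collide because the fixture generator (and the recommended site
  convention) prefixes center codes.
* **Enumerations as constrained text columns** (`disease` in
  `{ET, PD, other}`, `sex`, BIDS subject types) via `CHECK` constraints,
  keeping the database file portable with no engine-specific types.
* **Referential integrity switched on per connection**
  (`PRAGMA foreign_keys = ON` in `connect_db()`/`init_db()`), because the
  engine's default leaves it off.
* **Package-of-origin detection via the SQLite header**
  (`PRAGMA application_id` / `user_version`) rather than a meta table, so
  the user-table count stays exactly the declared 28. `init_db()` refuses
  to touch files that are not databases of this schema and is idempotent
  on ones that are.
* The column total counts *every* column of every user table, including
  primary and foreign keys; the relationship total counts foreign-key
  columns, and the schema uses exactly one FK column per table-pair link
  so the two readings coincide.

## REDCap ingestion

`ingest_redcap()` consumes the raw longitudinal export dialect
(`record_id`, `redcap_event_name`, `redcap_repeat_instrument`,
`redcap_repeat_instance` plus one column per field; non-repeating
instruments share the record's base row). Routing is fully declarative: a
YAML mapping file lists entries of (instrument, field, target table,
target column, cleaning rule, validation rule, required flag), validated
against the canonical schema before any data is touched.

Cleaning rules are deliberately small: `identity`, `regex-substitute`,
`decimal-normalize` (decimal commas, as produced by some European
keyboards), `date-normalize` (site format to ISO 8601), and
`code-to-label` for coded categorical fields. Validation restricts type,
range (for example targeting coordinates to ±100 mm) and choice sets.
A failing value produces a *rejection object*, never an exception: the
rejection granularity is the whole target row (a half-valid clinical row
is worse than a missing one), dependent child rows of a rejected parent
are rejected with it, and all valid sibling rows still ingest. Structural
problems — the mapping naming a table or column absent from the live
database — abort before any write.

Idempotence comes from a natural key: each target row stores
`record id|event|instrument|instance` in its `redcap_key` column
(patients upsert on `study_code`). Re-running an identical export inserts
and updates nothing; an edited export updates exactly the changed rows,
which is how clinician corrections propagate. Iteration follows a fixed
sorted order (records, then non-repeating rows first), making surrogate
key allocation deterministic for identical inputs. Rows are linked to
parents created from the same instrument row (e.g. stimulation effects to
their stimulation) by that shared key; patient and electrode references
resolve by get-or-create, so ingestion order cannot break foreign keys.

## BIDS layout and cross-space naming

Filenames follow the BIDS entity grammar. Two deliberate deviations from
canonical BIDS are part of the design:

* **Entity order**: names are emitted as `sub`, `space`, `ses`, `acq` —
  the space label directly after the subject — because that is the
  convention the layout standardizes on for transformed images. The
  parser accepts entities in any order, so canonical-BIDS input is read
  fine.
* **Derivatives grouping**: derivative files live directly at
  `derivatives/sub-<id>/<Category>/` with no intermediate subject-type
  directory. Subject type (Patient / Atlas / Electrode) is recorded in
  the database and encoded by reserved id conventions: atlas subjects are
  always `ATLAS` (with the atlas *version* as their session label, and as
  the `space-` label on files transformed into that atlas), electrode ids
  start with `ELEC`.

Content categories group derivatives by *what they are*, not by the
pipeline step that made them: `Segmentations`, `PatientInAtlas`,
`AtlasInPatient`, `Trajectories`, `VTA`, `Conductivity`, `Transforms`,
`ElectrodeModel`, plus `anat-raw` for raw acquisitions (which live
outside `derivatives/` for patients, and under `derivatives/sub-ATLAS/anat/`
for atlas templates, since nothing about an atlas is a raw acquisition).
The first three names are fixed vocabulary; the rest cover the analysis
products a DBS workflow generates and can be extended.

`derive_transformed_name()` encodes the cross-space rule: a native-space
image gains exactly a `space-` entity (the atlas version going
patient-to-atlas, the patient id going atlas-to-patient) and is filed
under the patient's `PatientInAtlas` or `AtlasInPatient` folder; a source
already carrying a `space-` entity is refused. All other entities are
preserved unchanged.

`ingest_images()` copies (never moves, never links — source data in
clinical contexts is not to be touched) manifest files into their
canonical `resolve_path()` locations and registers them. Images are
opaque payloads: only JSON sidecars are read, for acquisition metadata
and for electrode contact geometry. `validate_tree()` is the
corresponding linter: parseable names, canonical placement, dataset
descriptions present, and bidirectional file/database agreement, returned
as data rather than raised.

## Provenance and querying

`Files.source_id` points from any derived file to its origin;
`Files.transformation_id` points at the `Transformations` row pairing the
warp file with the target-space image that defines the output space.
Acyclicity is enforced at write time (`set_file_source()` walks the
ancestry before accepting an update; inserts of fresh ids cannot create
cycles), so `lineage()` always terminates, returning the origin-to-query
chain with each step's transformation. Files with registered descendants
are protected from deletion unless explicitly cascaded.

`select_files()` is the group-analysis entry point: conjunctive
predicates over the join of files, BIDS entities, label structures and
patient attributes, with a stable (subject, path) ordering under binary
collation. Its contract is tested against an independently materialized
full join filtered by plain subsetting, across random criteria and
fixture seeds.

## The synthetic cohort generator

`generate_cohort()` emulates a two-center ET/PD cohort: the study
conditions are a 50/50 ET/PD mixture over centers `BSL` and `CLF`, ten
clinical instruments per patient (the set enumerated above, with chronic
stimulation settings carried on the post-op screening form), targeting
coordinates inside the validated ±100 mm range, and six image files per
patient by default — pre-op T1w (`acq-ppp`, the planning acquisition),
pre- and post-op CT, one STN label, one warp to atlas `v1` and the
atlas-space T1w derivative — plus shared artifacts (atlas template and
segmentation, two electrode models with contact geometry sidecars).
Values are drawn uniformly within clinically plausible ranges: the
fixtures exercise plumbing (cleaning, validation, routing, naming,
lineage), not epidemiology. The seed fully determines the output, byte
for byte, and is woven into record ids so cohorts from different seeds
cannot share identifiers. NIfTI payloads are minimal valid 4×4×4 volumes;
nothing ever reads their voxels.

What passing tests on these fixtures shows — and does not show: they
demonstrate that structurally valid data flows through every table and
every layout rule without loss, and that defects of the kinds injected by
`corrupt()` (non-numeric coordinates, duplicate export keys, missing key
columns, lawless filenames) are caught at the intended layer. They do not
demonstrate robustness to the full messiness of real exports (free-text
fields abusing delimiters, site-specific date chaos, partially completed
repeating instruments), nor anything about image content.

Test and verification problem sizes are deliberately modest — cohorts of
two to five patients, five seeds and a hundred-plus random criteria for
the query-oracle property, thirty-step random derivation chains — chosen
so the whole suite re-runs in well under a minute while still touching
all 28 tables and every rule branch.

## Numerical and degenerate-input choices

* Coordinates and doses are stored as SQLite `REAL`; cleaning parses them
  with R's standard numeric parser after normalization, and validation
  bounds are inclusive.
* Empty cells are missing markers (`NA`/`NULL`), never rejections, unless
  the mapping marks the field required.
* An empty cohort (`n_patients = 0`) yields a header-only export and a
  manifest containing only shared (atlas, electrode) artifacts; an empty
  mapping is valid and ingests nothing.
* Ties in ingest ordering are broken by the sorted longitudinal key, so
  surrogate ids are reproducible for identical inputs.
* `corrupt()` introduces exactly one deterministic defect per call and
  never touches the original artifact.

## Known limitations

* Live EDC API pulls are out of scope; the package consumes the exported
  CSV dialect (the export is lossless, so nothing is lost at desk scale).
* DICOM conversion is assumed done upstream; inputs are NIfTI plus
  sidecars.
* The package records transformations and lineage but never executes
  them: no resampling, registration or VTA simulation.
* Schema migration between versions is not supported; the schema version
  is stamped in the database header for forward compatibility.
* Cross-center merging policy for colliding record ids is left to site
  conventions (the generator's center-prefixed ids avoid the problem).
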