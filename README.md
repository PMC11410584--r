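# dbsdata

Patient-centric research data management for Deep Brain Stimulation (DBS)
cohorts.

DBS studies accumulate deeply heterogeneous data: demographics and clinical
scores captured in an EDC system such as REDCap, pre- and post-operative CT
and MRI volumes, intra-operative microelectrode recordings and stimulation
tests, targeting plans with millimetre coordinates, and a growing tail of
analysis products — segmented structures, warps between patient and atlas
spaces, simulated volumes of tissue activated (VTA). `dbsdata` integrates
these into three coordinated layers:

1. **A relational store.** A single-file SQLite database holding a
   patient-centric schema of 28 tables, 230 columns and 33 foreign-key
   links, organized in content groups (Clinical Data, Imaging Data,
   Stimulation Configuration Evaluations, Microelectrode Recordings,
   Targeting, Chronic Stimulation Configuration, Implanted Position,
   Electrodes). Every group except Electrodes links directly to the
   central patient table.
2. **A BIDS raw/derivatives image layout.** Raw anatomical acquisitions
   live at `sub-<id>/ses-<ses>/anat/`; every analysis product lives under
   `derivatives/sub-<id>/<Category>/`, grouped by content (Segmentations,
   PatientInAtlas, AtlasInPatient, Transforms, VTA, ...). Images moved
   between reference spaces carry a `space-` entity: transforming
   `sub-P001_ses-pre_acq-ppp_T1w.nii.gz` into atlas version `v1` yields
   `sub-P001_space-v1_ses-pre_acq-ppp_T1w.nii.gz` under
   `derivatives/sub-P001/PatientInAtlas/`.
3. **Automated ingestion with provenance.** REDCap-style longitudinal CSV
   exports are routed into the schema by declarative mapping files (regex
   cleaning + field validation); image manifests are copied into the BIDS
   tree and registered. Derived files carry `source_id` and
   `transformation_id` pointers, so the full lineage of any file — back to
   the original acquisition, with the warp applied at each step — is one
   query away.

A seeded synthetic-cohort generator produces complete fake studies
(exports, mapping, NIfTI files, sidecars) so the entire pipeline is
testable without clinical data.

## Worked example

```r
library(dbsdata)

dir <- tempfile(); dir.create(dir)

# a synthetic 3-patient, 2-center cohort
fx <- generate_cohort(cohort_config(n_patients = 3, seed = 7),
                      file.path(dir, "cohort"))

con  <- init_db(file.path(dir, "study.db"))
schema_stats(con)
#> tables           28
#> fields           230
#> relationships    33

ingest_redcap(parse_redcap_export(fx$export), load_mapping(fx$mapping), con)
#> inserted 78, updated 0, rejected 0

root <- file.path(dir, "bids")
ingest_images(fx$manifest, con, root)
#> inserted 22, updated 0, rejected 0

nrow(validate_tree(root, con))   # layout + database cross-check
#> [1] 0

# group analysis: every patient image already in atlas space v1
sel <- select_files(con, query_criteria(space = "v1"))
sel$path
#> [1] "derivatives/sub-BSLs7p001/PatientInAtlas/sub-BSLs7p001_space-v1_ses-pre_acq-ppp_T1w.nii.gz"
#> [2] "derivatives/sub-BSLs7p003/PatientInAtlas/sub-BSLs7p003_space-v1_ses-pre_acq-ppp_T1w.nii.gz"
#> [3] "derivatives/sub-CLFs7p002/PatientInAtlas/sub-CLFs7p002_space-v1_ses-pre_acq-ppp_T1w.nii.gz"

lineage(con, sel$file_id[1])
#> lineage chain of 2 steps
#>   1. [5] sub-BSLs7p001/ses-pre/anat/sub-BSLs7p001_ses-pre_acq-ppp_T1w.nii.gz
#>   2. [10] derivatives/sub-BSLs7p001/PatientInAtlas/sub-BSLs7p001_space-v1_ses-pre_acq-ppp_T1w.nii.gz  (via transformation 1)
```

`ingest_redcap` reports 78 target rows routed from the export (0 rejected);
`ingest_images` registers 22 files (raw scans, STN labels, warps, an atlas
template, electrode models and one atlas-space derivative per patient).
The `select_files` call is the single-step file selection used to feed
disease-specific atlas construction or probabilistic stimulation maps, and
`lineage` shows each returned image's derivation history.

The same operations are available from a shell through the bundled CLI
(`exec/dbsdata`): `init-db`, `stats`, `ingest-redcap`, `ingest-images`,
`validate`, `query`, `lineage`, `register-transform`, `derive`, `fixture`.

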