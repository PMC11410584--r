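# A small hand-built imaging set for lineage mechanics: one patient with a
# raw scan, a warp to the atlas, and the atlas template.
lineage_fixture <- function() {
  con <- fresh_db()
  pid <- DBI::dbGetQuery(con, {
    DBI::dbExecute(con,
      "INSERT INTO Patients (study_code, disease) VALUES ('P001', 'PD')")
    "SELECT last_insert_rowid() AS id"
  })$id
  raw <- register_file(con, "sub-P001/ses-pre/anat/sub-P001_ses-pre_acq-ppp_T1w.nii.gz",
                       patient_id = pid, file_type = "anat")
  DBI::dbExecute(con, paste(
    "INSERT INTO Bids (file_id, subject_type, subject_label, session,",
    "acquisition, suffix, extension, category) VALUES",
    "(?, 'Patient', 'P001', 'pre', 'ppp', 'T1w', '.nii.gz', 'anat-raw')"),
    params = list(raw))
  tmpl <- register_file(con, "derivatives/sub-ATLAS/anat/sub-ATLAS_ses-v1_T1w.nii.gz",
                        file_type = "anat")
  DBI::dbExecute(con, paste(
    "INSERT INTO Bids (file_id, subject_type, subject_label, session,",
    "suffix, extension, category) VALUES",
    "(?, 'Atlas', 'ATLAS', 'v1', 'T1w', '.nii.gz', 'anat-raw')"),
    params = list(tmpl))
  warp <- register_file(con, "derivatives/sub-P001/Transforms/sub-P001_ses-pre_xfm.txt",
                        patient_id = pid, file_type = "warp")
  list(con = con, pid = pid, raw = raw, tmpl = tmpl, warp = warp)
}

test_that("file registration is idempotent on path and integrity-checked", {
  fx <- lineage_fixture()
  con <- fx$con
  on.exit(DBI::dbDisconnect(con))
  expect_gt(fx$raw, 0)
  again <- register_file(con, "sub-P001/ses-pre/anat/sub-P001_ses-pre_acq-ppp_T1w.nii.gz",
                         patient_id = fx$pid, file_type = "anat")
  expect_identical(again, fx$raw)
  expect_equal(table_count(con, "Files"), 3)
  expect_error(register_file(con, "x.nii.gz", file_type = "bogus"),
               "file_type")
  expect_error(register_file(con, "y.nii.gz", source_id = 999999),
               "integrity")
  expect_error(register_file(con, "sub-P001/ses-pre/anat/sub-P001_ses-pre_acq-ppp_T1w.nii.gz",
                             file_type = "ct"), "conflict")
})

test_that("transformations pair a warp with a target and deduplicate", {
  fx <- lineage_fixture()
  con <- fx$con
  on.exit(DBI::dbDisconnect(con))
  t1 <- register_transformation(con, fx$warp, fx$tmpl)
  expect_gt(t1, 0)
  expect_identical(register_transformation(con, fx$warp, fx$tmpl), t1)
  expect_equal(table_count(con, "Transformations"), 1)
  expect_error(register_transformation(con, fx$warp, fx$warp), "differ")
  expect_error(register_transformation(con, fx$warp, 999999), "integrity")
})

test_that("derived images carry lineage and the worked-example path", {
  fx <- lineage_fixture()
  con <- fx$con
  on.exit(DBI::dbDisconnect(con))
  tid <- register_transformation(con, fx$warp, fx$tmpl)
  fid <- register_derived_image(con, fx$raw, tid, "PatientToAtlas")
  path <- fetch_file_path(con, fid)
  expect_equal(path,
    "derivatives/sub-P001/PatientInAtlas/sub-P001_space-v1_ses-pre_acq-ppp_T1w.nii.gz")
  ch <- lineage(con, fid)
  expect_equal(nrow(ch$files), 2)
  expect_equal(ch$files$file_id, c(fx$raw, fid))
  expect_equal(ch$transformations[[2]]$transformation_id, tid)
  # origin of a raw file is itself
  ch0 <- lineage(con, fx$raw)
  expect_equal(nrow(ch0$files), 1)
  expect_error(lineage(con, 424242), "not found")
})

test_that("derivation chains stay acyclic and bounded", {
  fx <- lineage_fixture()
  con <- fx$con
  on.exit(DBI::dbDisconnect(con))
  tid <- register_transformation(con, fx$warp, fx$tmpl)
  # randomized chains: each new file derives from a uniformly chosen one
  set.seed(5)
  ids <- c(fx$raw)
  for (k in 1:25) {
    src <- sample(ids, 1)
    fid <- register_file(con, sprintf("derivatives/sub-P001/VTA/sub-P001_acq-c%d_vta.nii.gz", k),
                         patient_id = fx$pid, file_type = "vta",
                         source_id = src, transformation_id = tid)
    ids <- c(ids, fid)
  }
  n_files <- table_count(con, "Files")
  for (id in ids) {
    expect_lte(nrow(lineage(con, id)$files), n_files)
  }
  # re-pointing a source to its own descendant is rejected at write
  expect_error(set_file_source(con, fx$raw, ids[length(ids)]), "cycle")
  expect_error(set_file_source(con, ids[2], ids[2]), "cycle")
})

test_that("files with descendants are protected from deletion", {
  fx <- lineage_fixture()
  con <- fx$con
  on.exit(DBI::dbDisconnect(con))
  tid <- register_transformation(con, fx$warp, fx$tmpl)
  fid <- register_derived_image(con, fx$raw, tid, "PatientToAtlas")
  expect_error(delete_file(con, fx$raw), "cascade")
  expect_gt(table_count(con, "Files"), 0)
  delete_file(con, fx$raw, cascade = TRUE)
  expect_equal(nrow(fetch_file_row(con, fid)), 0)
})

test_that("select_files filters match a brute-force join filter", {
  env <- populated_db()
  con <- env$con
  on.exit(DBI::dbDisconnect(con))
  join <- brute_force_join(con)

  all_files <- select_files(con)
  expect_equal(nrow(all_files), nrow(join))

  got <- select_files(con, query_criteria(disease = "ET", space = "v1"))
  want <- brute_force_filter(join, list(disease = "ET", space = "v1"))
  expect_equal(got$path, want$path)
  expect_true(all(got$disease == "ET"))
  expect_true(all(got$space == "v1"))

  # a disease with zero patients yields an empty set
  diseases <- DBI::dbGetQuery(con, "SELECT DISTINCT disease FROM Patients")
  missing <- setdiff(c("ET", "PD", "other"), diseases$disease)
  if (length(missing) > 0) {
    expect_equal(nrow(select_files(con,
                                   query_criteria(disease = missing[1]))), 0)
  }
  expect_error(query_criteria(disease = "XX"), "criteria error")
  expect_error(query_criteria(file_type = "sandwich"), "criteria error")
})

test_that("patient bundles agree with direct per-table counts", {
  env <- populated_db()
  con <- env$con
  on.exit(DBI::dbDisconnect(con))
  code <- env$fx$record_ids[1]
  b <- patient_bundle(con, code)
  pid <- b$patient$patient_id[1]
  direct <- function(t) DBI::dbGetQuery(con,
    sprintf("SELECT COUNT(*) n FROM %s WHERE patient_id = ?", t),
    params = list(pid))$n
  expect_equal(nrow(b$files), direct("Files"))
  expect_equal(nrow(b$targeting), direct("TargetingPlans"))
  expect_equal(nrow(b$stimulations), direct("Stimulations"))
  expect_equal(nrow(b$medications), direct("Medications"))
  expect_error(patient_bundle(con, "nobody"), "not found")

  # a patient with no images keeps clinical sections intact
  DBI::dbExecute(con,
    "INSERT INTO Patients (study_code, disease) VALUES ('lonely', 'PD')")
  b2 <- patient_bundle(con, "lonely")
  expect_equal(nrow(b2$files), 0)
  expect_equal(nrow(b2$patient), 1)
})
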