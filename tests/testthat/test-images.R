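test_that("image ingest registers Files, Bids and Labels rows", {
  env <- populated_db()
  con <- env$con
  on.exit(DBI::dbDisconnect(con))
  expect_equal(env$img$rejected, 0)
  n_manifest <- nrow(read_manifest(env$fx$manifest))
  expect_equal(table_count(con, "Files"), n_manifest)
  expect_equal(table_count(con, "Bids"), n_manifest)
  # one STN label per patient plus the atlas segmentation
  labels <- DBI::dbGetQuery(con, "SELECT structure FROM Labels")
  expect_equal(nrow(labels), length(env$fx$record_ids) + 1)
  expect_true(all(labels$structure == "STN"))
  # electrode models land as electrode-linked files with contact geometry
  expect_equal(table_count(con, "Electrodes"), 2)
  expect_gt(table_count(con, "ElectrodeContacts"), 0)
  ne <- DBI::dbGetQuery(con,
    "SELECT n_contacts, manufacturer FROM Electrodes")
  expect_true(all(!is.na(ne$n_contacts)))
})

test_that("re-ingesting the same manifest adds zero rows", {
  env <- populated_db()
  con <- env$con
  on.exit(DBI::dbDisconnect(con))
  before <- vapply(canonical_tables(), function(t) table_count(con, t),
                   numeric(1))
  rep2 <- ingest_images(env$fx$manifest, con, env$root)
  expect_equal(rep2$inserted, 0)
  expect_equal(rep2$rejected, 0)
  after <- vapply(canonical_tables(), function(t) table_count(con, t),
                  numeric(1))
  expect_identical(before, after)
})

test_that("manifest entries without required metadata are skipped, not fatal", {
  fx <- make_cohort()
  man <- read_manifest(fx$manifest)
  man$suffix[3] <- ""
  con <- fresh_db()
  on.exit(DBI::dbDisconnect(con))
  root <- tempfile("root")
  rep <- ingest_images(man, con, root)
  expect_equal(rep$rejected, 1)
  expect_match(rep$rejections$reason[1], "metadata")
  expect_equal(table_count(con, "Files"), nrow(man) - 1)
})

test_that("a freshly ingested tree validates clean", {
  env <- populated_db()
  on.exit(DBI::dbDisconnect(env$con))
  v <- validate_tree(env$root, env$con)
  expect_equal(nrow(v[v$severity == "error", ]), 0)
  expect_true(file.exists(file.path(env$root, "dataset_description.json")))
  expect_true(file.exists(file.path(env$root, "derivatives",
                                    "dataset_description.json")))
})

test_that("each corrupt mode triggers exactly its intended failure", {
  fx <- make_cohort()

  # duplicate-key: parser refuses the export, citing the line
  dup <- tempfile(fileext = ".csv")
  corrupt(fx$export, "duplicate-key", dup)
  expect_error(parse_redcap_export(dup), "duplicate key")

  # missing-column: format error
  mc <- tempfile(fileext = ".csv")
  corrupt(fx$export, "missing-column", mc)
  expect_error(parse_redcap_export(mc), "record_id")

  # originals untouched
  expect_error(parse_redcap_export(fx$export), NA)

  # bad-filename: renamed image yields a naming violation and a dangling row
  env <- populated_db()
  on.exit(DBI::dbDisconnect(env$con))
  bad_root <- tempfile("badroot")
  corrupt(env$root, "bad-filename", bad_root)
  v <- validate_tree(bad_root, env$con)
  expect_true(any(grepl("unparsable", v$rule) &
                    grepl("scan1.nii.gz", v$path, fixed = TRUE)))
  expect_true(any(grepl("missing file", v$rule)))
  # the pristine root still validates clean
  expect_equal(sum(validate_tree(env$root, env$con)$severity == "error"), 0)

  expect_error(corrupt(fx$export, "frobnicate", tempfile()), "arg")
})

test_that("a database row whose file was deleted is reported dangling", {
  env <- populated_db()
  on.exit(DBI::dbDisconnect(env$con))
  root2 <- tempfile("root2")
  dir.create(root2)
  file.copy(list.files(env$root, full.names = TRUE), root2, recursive = TRUE)
  one <- DBI::dbGetQuery(env$con, "SELECT path FROM Files LIMIT 1")$path
  unlink(file.path(root2, one))
  v <- validate_tree(root2, env$con)
  expect_true(any(v$rule == "database row references missing file" &
                    v$path == one))
})
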