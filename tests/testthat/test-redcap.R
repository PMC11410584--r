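test_that("clean_value normalizes, validates and rejects deterministically", {
  # decimal comma -> dot, oracle: replace then float parse
  res <- clean_value("12,5", cleaning_rule("decimal-normalize"),
                     list(type = "numeric"))
  expect_true(res$ok)
  expect_equal(res$value, as.numeric(sub(",", ".", "12,5")))

  # invalid coordinate input is a rejection, not an error
  res <- clean_value("abc", cleaning_rule("identity"),
                     list(type = "numeric", min = -100, max = 100))
  expect_false(res$ok)
  expect_match(res$reason, "not numeric")

  # out-of-range coordinates are restricted
  expect_false(clean_value("250", validate = list(type = "numeric",
                                                  min = -100, max = 100))$ok)

  # empty optional value -> missing marker, empty required -> rejection
  res <- clean_value("", cleaning_rule("identity"), NULL)
  expect_true(res$ok)
  expect_true(is.na(res$value))
  expect_false(clean_value("", required = TRUE)$ok)

  # regex substitution and code maps
  res <- clean_value("ca. 42 mm", cleaning_rule("regex-substitute",
                                                pattern = "[^0-9]"),
                     list(type = "numeric"))
  expect_equal(res$value, 42)
  res <- clean_value("2", cleaning_rule("code-to-label",
                                        codes = list("1" = "M", "2" = "F")))
  expect_equal(res$value, "F")
  expect_false(clean_value("9", cleaning_rule("code-to-label",
                                              codes = list("1" = "M")))$ok)

  # date normalization to ISO
  res <- clean_value("24.12.2023",
                     cleaning_rule("date-normalize", format = "%d.%m.%Y"))
  expect_equal(res$value, "2023-12-24")
  expect_false(clean_value("2023-31-31",
                           cleaning_rule("date-normalize"))$ok)

  # malformed rules fail at construction, not at batch time
  expect_error(cleaning_rule("regex-substitute", pattern = "("), "compile")
  expect_error(cleaning_rule("code-to-label",
                             codes = list(a = "x", b = "x")), "injective")
})

test_that("mapping files are validated against the canonical schema", {
  fx <- make_cohort()
  spec <- load_mapping(fx$mapping)
  expect_s3_class(spec, "mapping_spec")
  expect_length(spec$instruments, 10)
  tp <- Filter(function(e) e$field == "plan_x", spec$entries)[[1]]
  expect_equal(tp$table, "TargetingPlans")
  expect_equal(tp$column, "x_mm")
  expect_equal(tp$validate$min, -100)
  expect_true(tp$required)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("instruments:", "  - name: f1", "entries:",
               "  - {instrument: f1, field: a, table: Foo, column: x}"), bad)
  expect_error(load_mapping(bad), "Foo")
  writeLines(c("instruments:", "  - name: f1", "entries:",
               "  - {instrument: f1, field: a, table: Patients, column: nope}"),
              bad)
  expect_error(load_mapping(bad), "nope")
  writeLines(c("instruments:", "  - name: f1", "entries:",
               "  - {instrument: f1, field: a, table: Patients, column: note}",
               "  - {instrument: f1, field: a, table: Visits, column: note}"),
              bad)
  expect_error(load_mapping(bad), "duplicate source")

  # empty entry list is a valid spec and ingest is a no-op
  writeLines(c("instruments: []", "entries: []"), bad)
  empty <- load_mapping(bad)
  con <- fresh_db()
  on.exit(DBI::dbDisconnect(con))
  rep <- ingest_redcap(parse_redcap_export(fx$export), empty, con)
  expect_equal(rep$inserted, 0)
})

test_that("the export parser preserves longitudinal keys and flags defects", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,redcap_event_name,redcap_repeat_instrument,redcap_repeat_instance,f1,f2,f3",
    "P1,ev1,,,a,b,c",
    "P1,ev1,inst1,1,d,e,f"), csv)
  rs <- parse_redcap_export(csv)
  expect_s3_class(rs, "record_set")
  expect_equal(nrow(rs), 2)
  expect_equal(rs$f1, c("a", "d"))

  # classic non-repeating export without repeat columns is tolerated
  writeLines(c("record_id,f1", "P1,a"), csv)
  rs <- parse_redcap_export(csv)
  expect_equal(rs$redcap_repeat_instrument, "")

  # header-only export
  writeLines("record_id,redcap_event_name,f1", csv)
  expect_equal(nrow(parse_redcap_export(csv)), 0)

  writeLines(c("foo,bar", "1,2"), csv)
  expect_error(parse_redcap_export(csv), "record_id")

  writeLines(c("record_id,redcap_event_name,f1", "P1,ev1,a", "P1,ev1,b"), csv)
  expect_error(parse_redcap_export(csv), "duplicate key")
})

test_that("ingest is idempotent and conserves rows per table", {
  fx <- make_cohort()
  con <- fresh_db()
  on.exit(DBI::dbDisconnect(con))
  records <- parse_redcap_export(fx$export)
  mapping <- load_mapping(fx$mapping)
  rep1 <- ingest_redcap(records, mapping, con)
  expect_equal(rep1$rejected, 0)
  expect_gt(rep1$inserted, 0)
  counts1 <- vapply(canonical_tables(), function(t) table_count(con, t),
                    numeric(1))
  rep2 <- ingest_redcap(records, mapping, con)
  expect_equal(rep2$inserted, 0)
  expect_equal(rep2$updated, 0)
  counts2 <- vapply(canonical_tables(), function(t) table_count(con, t),
                    numeric(1))
  expect_identical(counts1, counts2)
})

test_that("identity-mapped cells equal a direct CSV read, cell by cell", {
  fx <- make_cohort()
  con <- fresh_db()
  on.exit(DBI::dbDisconnect(con))
  records <- parse_redcap_export(fx$export)
  mapping <- load_mapping(fx$mapping)
  ingest_redcap(records, mapping, con)
  # oracle: brute-force read of the raw CSV
  raw <- utils::read.csv(fx$export, colClasses = "character",
                         na.strings = NULL)
  raw <- raw[raw$redcap_repeat_instrument == "medications", ]
  raw <- raw[order(raw$record_id), ]
  db <- DBI::dbGetQuery(con, paste(
    "SELECT p.study_code, m.drug_name FROM Medications m",
    "JOIN Patients p ON p.patient_id = m.patient_id",
    "ORDER BY p.study_code"))
  expect_equal(db$study_code, raw$record_id)
  expect_equal(db$drug_name, raw$drug_name)
})

test_that("a bad coordinate rejects only its own row; siblings ingest", {
  fx <- make_cohort()
  bad_csv <- tempfile(fileext = ".csv")
  corrupt(fx$export, "bad-coordinate", bad_csv)
  con <- fresh_db()
  on.exit(DBI::dbDisconnect(con))
  mapping <- load_mapping(fx$mapping)
  rep <- ingest_redcap(parse_redcap_export(bad_csv), mapping, con)
  # the TargetingPlans row and its dependent arc/entry rows are withheld
  expect_gte(rep$rejected, 1)
  expect_true(any(rep$rejections$field == "plan_x" &
                    grepl("not numeric", rep$rejections$reason)))
  # reference: the same export without the defect, redcap ingest only
  ref <- fresh_db()
  on.exit(DBI::dbDisconnect(ref), add = TRUE)
  ingest_redcap(parse_redcap_export(fx$export), mapping, ref)
  expect_equal(table_count(con, "TargetingPlans"),
               table_count(ref, "TargetingPlans") - 1)
  # every other table is untouched by the rejection
  for (t in setdiff(canonical_tables(),
                    c("TargetingPlans", "ArcSettings", "EntryPoints"))) {
    expect_equal(table_count(con, t), table_count(ref, t), info = t)
  }
})

test_that("rows attempted minus rejections equals rows present", {
  fx <- make_cohort()
  bad_csv <- tempfile(fileext = ".csv")
  corrupt(fx$export, "bad-coordinate", bad_csv)
  con <- fresh_db()
  on.exit(DBI::dbDisconnect(con))
  rep <- ingest_redcap(parse_redcap_export(bad_csv),
                       load_mapping(fx$mapping), con)
  total_rows <- sum(vapply(canonical_tables(), function(t)
    table_count(con, t), numeric(1)))
  # Centers and Electrodes rows come from get-or-create resolution,
  # not from mapped target rows
  side_rows <- table_count(con, "Centers") + table_count(con, "Electrodes")
  expect_equal(total_rows - side_rows, rep$inserted)
})

test_that("a mapping targeting a dropped column aborts before any write", {
  fx <- make_cohort()
  con <- fresh_db()
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA foreign_keys = OFF")
  DBI::dbExecute(con, "DROP TABLE ArcSettings")
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  expect_error(
    ingest_redcap(parse_redcap_export(fx$export),
                  load_mapping(fx$mapping), con),
    "schema mismatch")
  expect_equal(table_count(con, "Patients"), 0)
})
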