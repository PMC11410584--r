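# Shared fixture plumbing. Generated cohorts are cached per (n, seed) for
# the session so several test files can reuse the same artifacts.

.cohort_cache <- new.env(parent = emptyenv())

make_cohort <- function(n = 3, seed = 7) {
  key <- sprintf("n%d_s%d", n, seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  out <- file.path(tempdir(), paste0("cohort_", key))
  unlink(out, recursive = TRUE)
  fx <- generate_cohort(cohort_config(n_patients = n, seed = seed), out)
  .cohort_cache[[key]] <- fx
  fx
}

fresh_db <- function() {
  path <- tempfile(fileext = ".db")
  con <- init_db(path)
  attr(con, "db_path") <- path
  con
}

# Full pipeline: redcap + images into a fresh database and BIDS root.
populated_db <- function(n = 3, seed = 7) {
  fx <- make_cohort(n, seed)
  con <- fresh_db()
  root <- file.path(tempdir(),
                    paste0("root_", basename(tempfile(pattern = ""))))
  records <- parse_redcap_export(fx$export)
  mapping <- load_mapping(fx$mapping)
  red <- ingest_redcap(records, mapping, con)
  img <- ingest_images(fx$manifest, con, root)
  list(con = con, root = root, fx = fx, records = records,
       mapping = mapping, red = red, img = img)
}

fetch_file_row <- function(con, id) {
  DBI::dbGetQuery(con, "SELECT * FROM Files WHERE file_id = ?",
                  params = list(id))
}

fetch_file_path <- function(con, id) fetch_file_row(con, id)$path

table_count <- function(con, table) {
  DBI::dbGetQuery(con, sprintf("SELECT COUNT(*) AS n FROM %s", table))$n
}

# Independent full-join oracle for select_files: read the base tables and
# merge them in R, then filter with plain subsetting.
brute_force_join <- function(con) {
  f <- DBI::dbReadTable(con, "Files")
  b <- DBI::dbReadTable(con, "Bids")
  l <- DBI::dbReadTable(con, "Labels")
  p <- DBI::dbReadTable(con, "Patients")
  ce <- DBI::dbReadTable(con, "Centers")
  out <- merge(f, b, by = "file_id", all.x = TRUE)
  out <- merge(out, l[, c("file_id", "structure")], by = "file_id",
               all.x = TRUE)
  out <- merge(out,
               p[, c("patient_id", "study_code", "disease", "center_id")],
               by = "patient_id", all.x = TRUE)
  out <- merge(out, data.frame(center_id = ce$center_id, center = ce$code),
               by = "center_id", all.x = TRUE)
  # radix = C-locale collation, matching the database's binary ordering
  out[order(out$subject_label, out$path, method = "radix"), ]
}

brute_force_filter <- function(join, criteria) {
  keep <- rep(TRUE, nrow(join))
  pred <- function(col, vals) {
    if (is.null(vals)) return()
    keep <<- keep & !is.na(join[[col]]) & join[[col]] %in% vals
  }
  pred("disease", criteria$disease)
  pred("center", criteria$center)
  pred("subject_label", criteria$subject)
  pred("space", criteria$space)
  pred("file_type", criteria$file_type)
  pred("suffix", criteria$suffix)
  pred("session", criteria$session)
  pred("category", criteria$category)
  join[keep, ]
}

random_criteria <- function(join) {
  pools <- list(
    disease = c("ET", "PD"),
    center = unique(stats::na.omit(join$center)),
    space = unique(stats::na.omit(join$space)),
    file_type = unique(stats::na.omit(join$file_type)),
    suffix = unique(stats::na.omit(join$suffix)),
    session = unique(stats::na.omit(join$session)),
    category = unique(stats::na.omit(join$category)),
    subject = unique(stats::na.omit(join$subject_label)))
  fields <- sample(names(pools), sample(0:3, 1))
  args <- lapply(pools[fields], function(pool) {
    if (length(pool) == 0) return(NULL)
    sample(pool, sample(seq_len(min(2, length(pool))), 1))
  })
  do.call(query_criteria, args[!vapply(args, is.null, logical(1))])
}
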