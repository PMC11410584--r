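#' @importFrom DBI dbConnect dbDisconnect dbExecute dbGetQuery dbWriteTable
#'   dbListTables dbWithTransaction dbQuoteIdentifier dbQuoteString
NULL

# Magic numbers stamped into the SQLite header so a database file can be
# recognized as one of ours without relying on a meta table.
.dbs_application_id <- 0x44425331L  # "DBS1"
.dbs_schema_version <- 1L

#' Table groups of the patient-centric schema
#'
#' Every user table belongs to exactly one information-content group.
#' All groups except `Electrodes` contain at least one table with a direct
#' foreign key to the central `Patients` table.
#'
#' @return Named list mapping group name to member table names.
#' @export
table_groups <- function() {
  list(
    Central = c("Centers", "Patients", "Visits"),
    ClinicalData = c("ClinicalDataGeneral", "Medications", "PreopEvaluations",
                     "PostopEvaluations", "PostopScreenings"),
    ImagingData = c("Files", "Bids", "Labels", "Transformations"),
    StimulationConfigurationEvaluation = c("Stimulations", "StimulationEffects",
                                           "StimulationSideEffects",
                                           "StimulationProtocols"),
    MicroelectrodeRecordings = c("MerSessions", "MerTracks", "MerRecordings"),
    Targeting = c("TargetingPlans", "ArcSettings", "EntryPoints"),
    ChronicStimulationConfiguration = c("ChronicSettings", "ChronicContacts"),
    ImplantedPosition = c("ImplantedPositions", "ImplantedLeads"),
    Electrodes = c("Electrodes", "ElectrodeContacts")
  )
}

#' Canonical table names, in DDL order
#' @return Character vector of the 28 user table names.
#' @export
canonical_tables <- function() {
  unname(unlist(table_groups(), use.names = FALSE))
}

schema_ddl_path <- function() {
  system.file("sql", "schema.sql", package = "dbsdata", mustWork = TRUE)
}

# Split a DDL script into executable statements (";" at end of line,
# comments stripped). SQLite's dbExecute runs one statement at a time.
read_ddl_statements <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("--.*$", "", lines)
  text <- paste(lines, collapse = "\n")
  stmts <- strsplit(text, ";", fixed = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts[nzchar(stmts)]
}

#' Open a connection to a study database
#'
#' Opens the SQLite file and switches referential-integrity enforcement on
#' for this connection (SQLite leaves it off by default).
#'
#' @param path Path to the database file.
#' @param must_exist Error if `path` does not already hold an initialized
#'   database of this package's schema.
#' @return A `DBIConnection`.
#' @export
connect_db <- function(path, must_exist = TRUE) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  if (must_exist && !is_dbs_database(con)) {
    DBI::dbDisconnect(con)
    stop("schema mismatch: '", path,
         "' is not a database created by dbsdata::init_db()", call. = FALSE)
  }
  con
}

is_dbs_database <- function(con) {
  app <- DBI::dbGetQuery(con, "PRAGMA application_id")[[1]]
  ver <- DBI::dbGetQuery(con, "PRAGMA user_version")[[1]]
  identical(as.integer(app), .dbs_application_id) &&
    as.integer(ver) >= 1L
}

#' Initialize (or open) a study database
#'
#' Creates all user tables, columns and foreign-key relationships from the
#' canonical DDL shipped with the package. The operation is idempotent: on a
#' file already initialized by this package it changes nothing and returns a
#' live connection.
#'
#' @param path Filesystem location of the single-file database.
#' @return An open `DBIConnection` with foreign-key enforcement on.
#' @export
#' @examples
#' con <- init_db(tempfile(fileext = ".db"))
#' schema_stats(con)
#' DBI::dbDisconnect(con)
init_db <- function(path) {
  exists_before <- file.exists(path) && file.size(path) > 0
  if (exists_before) {
    # Refuse to touch files that are not SQLite or not our schema.
    hdr <- readBin(path, "raw", n = 16L)
    if (!identical(rawToChar(hdr[1:15]), "SQLite format 3")) {
      stop("schema mismatch: '", path, "' exists and is not an SQLite database",
           call. = FALSE)
    }
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
    if (!is_dbs_database(con)) {
      DBI::dbDisconnect(con)
      stop("schema mismatch: '", path,
           "' is an SQLite database but not this package's schema", call. = FALSE)
    }
    return(con)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit(if (!ok) { DBI::dbDisconnect(con); unlink(path) })
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  for (stmt in read_ddl_statements(schema_ddl_path())) {
    DBI::dbExecute(con, stmt)
  }
  DBI::dbExecute(con, sprintf("PRAGMA application_id = %d", .dbs_application_id))
  DBI::dbExecute(con, sprintf("PRAGMA user_version = %d", .dbs_schema_version))
  ok <- TRUE
  on.exit()
  con
}

user_tables <- function(con) {
  DBI::dbGetQuery(con, paste(
    "SELECT name FROM sqlite_master",
    "WHERE type = 'table' AND name NOT LIKE 'sqlite_%'",
    "ORDER BY name"))$name
}

#' Structural statistics of a study database
#'
#' Counts tables, columns and foreign-key links by catalog introspection
#' (`sqlite_master`, `PRAGMA table_info`, `PRAGMA foreign_key_list`).
#'
#' @param con Connection from [init_db()] or [connect_db()].
#' @return Object of class `schema_stats` with elements `n_tables`,
#'   `n_fields`, `n_relationships`.
#' @export
schema_stats <- function(con) {
  if (!is_dbs_database(con)) {
    stop("schema mismatch: connection is not an initialized dbsdata database",
         call. = FALSE)
  }
  tabs <- user_tables(con)
  n_fields <- 0L
  n_rel <- 0L
  for (t in tabs) {
    qt <- DBI::dbQuoteIdentifier(con, t)
    n_fields <- n_fields +
      nrow(DBI::dbGetQuery(con, sprintf("PRAGMA table_info(%s)", qt)))
    n_rel <- n_rel +
      nrow(DBI::dbGetQuery(con, sprintf("PRAGMA foreign_key_list(%s)", qt)))
  }
  structure(
    list(n_tables = length(tabs), n_fields = n_fields, n_relationships = n_rel),
    class = "schema_stats")
}

#' @export
print.schema_stats <- function(x, ...) {
  cat(sprintf("%-16s %d\n", "tables", x$n_tables))
  cat(sprintf("%-16s %d\n", "fields", x$n_fields))
  cat(sprintf("%-16s %d\n", "relationships", x$n_relationships))
  invisible(x)
}

#' Compare a live database against the canonical schema
#'
#' @param con Database connection.
#' @return List with `missing_tables`, `unexpected_tables` and logical `ok`.
#' @export
schema_integrity <- function(con) {
  have <- user_tables(con)
  want <- canonical_tables()
  out <- list(missing_tables = setdiff(want, have),
              unexpected_tables = setdiff(have, want))
  out$ok <- length(out$missing_tables) == 0 && length(out$unexpected_tables) == 0
  out
}

#' Tables of the imaging-data group
#'
#' Imaging data is managed through four tables: `Files` (path, subject link,
#' general file type, lineage pointers), `Bids` (filename entities and
#' acquisition metadata), `Labels` (anatomical structure represented by a
#' label file) and `Transformations` (warp file paired with its target-space
#' image). `Bids` and `Labels` share their primary key with `Files`.
#'
#' @param con Database connection.
#' @return Character vector of the imaging-group table names present.
#' @export
imaging_tables <- function(con) {
  if (!is_dbs_database(con)) {
    stop("schema mismatch: connection is not an initialized dbsdata database",
         call. = FALSE)
  }
  intersect(table_groups()$ImagingData, user_tables(con))
}

table_columns <- function(con, table) {
  qt <- DBI::dbQuoteIdentifier(con, table)
  DBI::dbGetQuery(con, sprintf("PRAGMA table_info(%s)", qt))$name
}

table_fks <- function(con, table) {
  qt <- DBI::dbQuoteIdentifier(con, table)
  DBI::dbGetQuery(con, sprintf("PRAGMA foreign_key_list(%s)", qt))
}
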