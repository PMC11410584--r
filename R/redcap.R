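#' @title REDCap export ingestion
#' @description
#' Longitudinal REDCap CSV exports (raw dialect: `record_id`,
#' `redcap_event_name`, `redcap_repeat_instrument`, `redcap_repeat_instance`
#' plus instrument fields) are routed into the relational schema through a
#' declarative mapping file. Each mapping entry names a source instrument
#' and field, a target table and column, a cleaning rule and a validation
#' rule. Values failing validation are collected in a report and never
#' abort the batch; the rejection granularity is the whole target row.
#' @name redcap-ingest
NULL

.redcap_key_cols <- c("record_id", "redcap_event_name",
                      "redcap_repeat_instrument", "redcap_repeat_instance")

.clean_kinds <- c("identity", "regex-substitute", "decimal-normalize",
                  "date-normalize", "code-to-label")

# Columns of the canonical schema, introspected once from the shipped DDL
# via a throwaway in-memory database.
canonical_schema_columns <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
    on.exit(DBI::dbDisconnect(con))
    for (stmt in read_ddl_statements(schema_ddl_path())) {
      DBI::dbExecute(con, stmt)
    }
    cols <- lapply(user_tables(con), function(t) table_columns(con, t))
    names(cols) <- user_tables(con)
    cache <<- cols
    cols
  }
})

#' Build a cleaning rule
#'
#' @param kind One of `identity`, `regex-substitute` (`pattern`,
#'   `replacement`), `decimal-normalize` (decimal comma to dot),
#'   `date-normalize` (`format` as in [strptime()], output ISO 8601),
#'   `code-to-label` (`codes`: named injective map).
#' @param ... Rule parameters.
#' @return Object of class `cleaning_rule`.
#' @export
cleaning_rule <- function(kind = "identity", ...) {
  kind <- match.arg(kind, .clean_kinds)
  params <- list(...)
  if (kind == "regex-substitute") {
    if (is.null(params$pattern))
      stop("regex-substitute needs a 'pattern'", call. = FALSE)
    ok <- tryCatch({ suppressWarnings(grepl(params$pattern, "x")); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("regex pattern '", params$pattern, "' does not compile",
                  call. = FALSE)
    if (is.null(params$replacement)) params$replacement <- ""
  }
  if (kind == "date-normalize" && is.null(params$format))
    params$format <- "%Y-%m-%d"
  if (kind == "code-to-label") {
    codes <- unlist(params$codes)
    if (is.null(codes) || anyDuplicated(codes) || anyDuplicated(names(codes)))
      stop("code-to-label needs an injective 'codes' map", call. = FALSE)
    params$codes <- codes
  }
  structure(list(kind = kind, params = params), class = "cleaning_rule")
}

rejection <- function(reason) {
  structure(list(ok = FALSE, reason = reason), class = "value_rejection")
}

#' Clean and validate one raw export value
#'
#' Applies the cleaning rule, then the validation rule. Deterministic;
#' failures come back as rejection objects, never as conditions, so one bad
#' cell cannot abort a batch.
#'
#' @param raw Raw text value from the export.
#' @param rule A [cleaning_rule()] (default identity).
#' @param validate Optional validation rule: a list with any of `type`
#'   (`"numeric"`, `"integer"`, `"text"`, `"date"`), `min`, `max`, `choices`.
#' @param required If `TRUE`, an empty value is a rejection instead of a
#'   missing marker.
#' @return `list(ok = TRUE, value = ...)` (value is `NA` for missing) or
#'   `list(ok = FALSE, reason = ...)`.
#' @export
#' @examples
#' clean_value("12,5", cleaning_rule("decimal-normalize"),
#'             list(type = "numeric"))
clean_value <- function(raw, rule = cleaning_rule("identity"),
                        validate = NULL, required = FALSE) {
  if (is.null(rule)) rule <- cleaning_rule("identity")
  stopifnot(inherits(rule, "cleaning_rule"))
  raw <- if (is.null(raw) || is.na(raw)) "" else trimws(as.character(raw))
  if (!nzchar(raw)) {
    if (required) return(rejection("required value is missing"))
    return(list(ok = TRUE, value = NA, missing = TRUE))
  }
  val <- switch(rule$kind,
    "identity" = raw,
    "regex-substitute" = gsub(rule$params$pattern, rule$params$replacement, raw),
    "decimal-normalize" = gsub(",", ".", gsub("[ ']", "", raw), fixed = TRUE),
    "date-normalize" = {
      d <- as.Date(raw, format = rule$params$format)
      if (is.na(d)) return(rejection(paste0(
        "not a date in format '", rule$params$format, "': '", raw, "'")))
      format(d, "%Y-%m-%d")
    },
    "code-to-label" = {
      if (!raw %in% names(rule$params$codes))
        return(rejection(paste0("unknown code '", raw, "'")))
      unname(rule$params$codes[[raw]])
    })
  if (is.null(validate)) return(list(ok = TRUE, value = val, missing = FALSE))
  type <- validate$type %||% "text"
  if (type %in% c("numeric", "integer")) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) return(rejection(paste0("not numeric: '", val, "'")))
    if (type == "integer") {
      if (num != round(num))
        return(rejection(paste0("not an integer: '", val, "'")))
      num <- as.integer(round(num))
    }
    if (!is.null(validate$min) && num < validate$min)
      return(rejection(paste0("value ", num, " below minimum ", validate$min)))
    if (!is.null(validate$max) && num > validate$max)
      return(rejection(paste0("value ", num, " above maximum ", validate$max)))
    val <- num
  } else if (type == "date") {
    if (is.na(as.Date(val, format = "%Y-%m-%d")))
      return(rejection(paste0("not an ISO date: '", val, "'")))
  }
  if (!is.null(validate$choices) && !val %in% unlist(validate$choices))
    return(rejection(paste0("'", val, "' not in {",
                            paste(unlist(validate$choices), collapse = ", "),
                            "}")))
  list(ok = TRUE, value = val, missing = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a mapping file
#'
#' Mapping files are YAML with an `instruments` registry and an `entries`
#' list (`instrument`, `field`, `table`, `column`, optional `clean`,
#' `validate`, `required`). Every target table/column is verified against
#' the canonical schema before any data is touched.
#'
#' @param path Path to the YAML mapping file.
#' @return Object of class `mapping_spec`.
#' @export
load_mapping <- function(path) {
  spec <- yaml::read_yaml(path)
  instruments <- spec$instruments
  if (is.null(instruments)) instruments <- list()
  inst_names <- vapply(instruments, function(i) i$name, character(1))
  if (anyDuplicated(inst_names))
    stop("mapping error: duplicate instrument name(s): ",
         paste(unique(inst_names[duplicated(inst_names)]), collapse = ", "),
         call. = FALSE)
  repeating <- vapply(instruments, function(i) isTRUE(i$repeating), logical(1))
  names(repeating) <- inst_names

  schema_cols <- canonical_schema_columns()
  entries <- spec$entries %||% list()
  seen <- character(0)
  entries <- lapply(entries, function(e) {
    for (fld in c("instrument", "field", "table", "column")) {
      if (is.null(e[[fld]]))
        stop("mapping error: entry missing '", fld, "'", call. = FALSE)
    }
    if (!e$instrument %in% inst_names)
      stop("mapping error: entry for field '", e$field,
           "' references unregistered instrument '", e$instrument, "'",
           call. = FALSE)
    if (!e$table %in% names(schema_cols))
      stop("mapping error: unknown target table '", e$table,
           "' (entry for field '", e$field, "')", call. = FALSE)
    if (!e$column %in% schema_cols[[e$table]])
      stop("mapping error: unknown column '", e$column, "' in table '",
           e$table, "' (entry for field '", e$field, "')", call. = FALSE)
    key <- paste(e$instrument, e$field, sep = "\r")
    if (key %in% seen)
      stop("mapping error: duplicate source (", e$instrument, ", ", e$field,
           ")", call. = FALSE)
    seen <<- c(seen, key)
    clean <- if (is.null(e$clean)) cleaning_rule("identity") else
      do.call(cleaning_rule, c(list(kind = e$clean$kind %||% "identity"),
                               e$clean[setdiff(names(e$clean), "kind")]))
    list(instrument = e$instrument, field = e$field, table = e$table,
         column = e$column, clean = clean, validate = e$validate,
         required = isTRUE(e$required))
  })
  structure(list(instruments = inst_names, repeating = repeating,
                 entries = entries),
            class = "mapping_spec")
}

#' @export
print.mapping_spec <- function(x, ...) {
  cat("mapping spec:", length(x$instruments), "instruments,",
      length(x$entries), "entries\n")
  invisible(x)
}

#' Parse a REDCap-style longitudinal CSV export
#'
#' Keeps every cell as raw text; the longitudinal key is the tuple
#' (record id, event name, repeat instrument, repeat instance). Missing
#' repeat columns are tolerated (classic non-repeating export).
#'
#' @param path Path to the export CSV (UTF-8, header row).
#' @return Object of class `record_set`: a data frame of raw text cells
#'   plus the four key columns (filled with `""` where absent).
#' @export
parse_redcap_export <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (!"record_id" %in% names(df))
    stop("format error: export has no 'record_id' column", call. = FALSE)
  for (k in .redcap_key_cols) {
    if (!k %in% names(df)) df[[k]] <- rep("", nrow(df))
  }
  if (nrow(df) > 0 && any(!nzchar(df$record_id)))
    stop("format error: empty record_id in data row(s) ",
         paste(which(!nzchar(df$record_id)), collapse = ", "), call. = FALSE)
  keys <- do.call(paste, c(df[.redcap_key_cols], sep = "\r"))
  if (anyDuplicated(keys)) {
    stop("format error: duplicate key tuple at data line(s) ",
         paste(which(duplicated(keys)), collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("record_set", "data.frame"))
}

#' @export
print.record_set <- function(x, ...) {
  cat("record set:", nrow(x), "rows,",
      length(unique(x$record_id)), "records\n")
  invisible(x)
}

ingest_report <- function(inserted, updated, rejected, rejections) {
  structure(list(inserted = inserted, updated = updated, rejected = rejected,
                 rejections = rejections),
            class = "ingest_report")
}

#' @export
print.ingest_report <- function(x, ...) {
  cat(sprintf("inserted %d, updated %d, rejected %d\n",
              x$inserted, x$updated, x$rejected))
  if (nrow(x$rejections) > 0) {
    cat("rejections:\n")
    print(x$rejections, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize an ingest report to JSON
#' @param report An `ingest_report`.
#' @param path Optional file to write to.
#' @return JSON string, invisibly if `path` given.
#' @export
report_json <- function(report, path = NULL) {
  out <- jsonlite::toJSON(
    list(inserted = report$inserted, updated = report$updated,
         rejected = report$rejected,
         rejections = report$rejections),
    auto_unbox = TRUE, dataframe = "rows", na = "null")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# get-or-create helpers for enumerated side tables ---------------------------

resolve_center <- function(con, code) {
  row <- DBI::dbGetQuery(con, "SELECT center_id FROM Centers WHERE code = ?",
                         params = list(code))
  if (nrow(row) > 0) return(row$center_id[1])
  DBI::dbExecute(con, "INSERT INTO Centers (code) VALUES (?)",
                 params = list(code))
  DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1]
}

resolve_electrode <- function(con, model_name) {
  row <- DBI::dbGetQuery(
    con, "SELECT electrode_id FROM Electrodes WHERE model_name = ?",
    params = list(model_name))
  if (nrow(row) > 0) return(row$electrode_id[1])
  DBI::dbExecute(con, "INSERT INTO Electrodes (model_name) VALUES (?)",
                 params = list(model_name))
  DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1]
}

resolve_patient <- function(con, study_code) {
  row <- DBI::dbGetQuery(
    con, "SELECT patient_id FROM Patients WHERE study_code = ?",
    params = list(study_code))
  if (nrow(row) > 0) return(row$patient_id[1])
  DBI::dbExecute(con, "INSERT INTO Patients (study_code) VALUES (?)",
                 params = list(study_code))
  DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1]
}

# Order target tables parents-first using the schema's foreign-key graph.
order_tables_by_fk <- function(con, tables) {
  remaining <- tables
  ordered <- character(0)
  while (length(remaining) > 0) {
    progressed <- FALSE
    for (t in remaining) {
      fks <- table_fks(con, t)
      deps <- intersect(setdiff(fks$table, t), remaining)
      if (length(deps) == 0) {
        ordered <- c(ordered, t)
        remaining <- setdiff(remaining, t)
        progressed <- TRUE
      }
    }
    if (!progressed) { # cycle among targets; fall back to given order
      ordered <- c(ordered, remaining)
      break
    }
  }
  ordered
}

upsert_row <- function(con, table, key_col, key_val, values) {
  qt <- DBI::dbQuoteIdentifier(con, table)
  qk <- DBI::dbQuoteIdentifier(con, key_col)
  existing <- DBI::dbGetQuery(
    con, sprintf("SELECT * FROM %s WHERE %s = ?", qt, qk),
    params = list(key_val))
  if (nrow(existing) == 0) {
    cols <- c(key_col, names(values))
    qcols <- vapply(cols, function(cn)
      as.character(DBI::dbQuoteIdentifier(con, cn)), character(1))
    sql <- sprintf("INSERT INTO %s (%s) VALUES (%s)", qt,
                   paste(qcols, collapse = ", "),
                   paste(rep("?", length(cols)), collapse = ", "))
    DBI::dbExecute(con, sql, params = c(list(key_val), unname(values)))
    return(list(status = "inserted",
                id = DBI::dbGetQuery(con,
                  "SELECT last_insert_rowid() AS id")$id[1]))
  }
  pk <- table_columns(con, table)[1]
  same <- vapply(names(values), function(cn) {
    old <- existing[[cn]][1]
    new <- values[[cn]]
    (is.na(old) && is.na(new)) ||
      (!is.na(old) && !is.na(new) && as.character(old) == as.character(new))
  }, logical(1))
  id <- existing[[pk]][1]
  if (all(same)) return(list(status = "unchanged", id = id))
  sets <- paste(vapply(names(values), function(cn)
    sprintf("%s = ?", DBI::dbQuoteIdentifier(con, cn)), character(1)),
    collapse = ", ")
  sql <- sprintf("UPDATE %s SET %s WHERE %s = ?", qt, sets, qk)
  DBI::dbExecute(con, sql, params = c(unname(values), list(key_val)))
  list(status = "updated", id = id)
}

#' Ingest a parsed REDCap export into the database
#'
#' Each mapped field is cleaned, validated and routed to its target table;
#' target rows are upserted on a natural key derived from the export key
#' tuple, so re-running the same input inserts nothing. Rows with any
#' rejected value are skipped whole (their valid siblings still ingest) and
#' listed in the report. Structural problems (mapping vs live schema)
#' abort before any write.
#'
#' @param records A [parse_redcap_export()] result.
#' @param mapping A [load_mapping()] result.
#' @param con Database connection from [init_db()]/[connect_db()].
#' @return An `ingest_report`.
#' @export
ingest_redcap <- function(records, mapping, con) {
  stopifnot(inherits(records, "record_set"), inherits(mapping, "mapping_spec"))
  if (!is_dbs_database(con))
    stop("schema mismatch: connection is not an initialized dbsdata database",
         call. = FALSE)

  # structural pre-flight: every target column must exist in the live schema
  live <- user_tables(con)
  for (e in mapping$entries) {
    if (!e$table %in% live || !e$column %in% table_columns(con, e$table))
      stop("schema mismatch: mapping targets ", e$table, ".", e$column,
           " which is absent from the live database; nothing ingested",
           call. = FALSE)
  }

  entries_by_it <- split(mapping$entries, vapply(mapping$entries, function(e)
    paste(e$instrument, e$table, sep = "\r"), character(1)))

  inserted <- 0L; updated <- 0L; rejected <- 0L
  rejections <- list()
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  # fixed iteration order: per record, non-repeating rows (which carry the
  # demographics that create the Patients row) before repeating instruments
  ord <- order(df$record_id, nzchar(df$redcap_repeat_instrument),
               df$redcap_event_name, df$redcap_repeat_instrument,
               df$redcap_repeat_instance)
  df <- df[ord, , drop = FALSE]

  DBI::dbWithTransaction(con, {
    for (i in seq_len(nrow(df))) {
      row <- df[i, , drop = FALSE]
      rep_inst <- row$redcap_repeat_instrument
      row_insts <- if (nzchar(rep_inst)) rep_inst else
        mapping$instruments[!mapping$repeating[mapping$instruments]]
      for (inst in row_insts) {
        tables <- unique(vapply(
          Filter(function(e) e$instrument == inst, mapping$entries),
          function(e) e$table, character(1)))
        if (length(tables) == 0) next
        tables <- order_tables_by_fk(con, tables)
        rkey <- paste(row$record_id, row$redcap_event_name, inst,
                      row$redcap_repeat_instance, sep = "|")
        parent_ids <- list()  # table -> surrogate id, for same-row children
        for (tbl in tables) {
          ents <- entries_by_it[[paste(inst, tbl, sep = "\r")]]
          values <- list(); bad <- list(); any_present <- FALSE
          for (e in ents) {
            raw <- if (e$field %in% names(row)) row[[e$field]] else ""
            res <- clean_value(raw, e$clean, e$validate, e$required)
            if (!res$ok) {
              bad[[length(bad) + 1L]] <- data.frame(
                record_id = row$record_id, event = row$redcap_event_name,
                instrument = inst, instance = row$redcap_repeat_instance,
                field = e$field, reason = res$reason,
                stringsAsFactors = FALSE)
              next
            }
            if (!isTRUE(res$missing)) any_present <- TRUE
            val <- res$value
            # enumerated side-table resolution
            if (e$column == "center_id" && !is.na(val))
              val <- resolve_center(con, val)
            if (e$column == "electrode_id" && !is.na(val))
              val <- resolve_electrode(con, val)
            values[[e$column]] <- val
          }
          if (length(bad) > 0) {
            rejected <- rejected + 1L
            rejections <- c(rejections, bad)
            next
          }
          if (!any_present) next
          # relationship columns filled from context
          cols <- table_columns(con, tbl)
          fks <- table_fks(con, tbl)
          if ("patient_id" %in% cols &&
              "Patients" %in% fks$table && tbl != "Patients") {
            values$patient_id <- resolve_patient(con, row$record_id)
          }
          for (k in seq_len(nrow(fks))) {
            parent <- fks$table[k]; fkcol <- fks$from[k]
            if (parent %in% names(parent_ids) && is.null(values[[fkcol]]))
              values[[fkcol]] <- parent_ids[[parent]]
          }
          # a child row whose parent was rejected is itself rejected
          info <- DBI::dbGetQuery(con, sprintf("PRAGMA table_info(%s)",
                    DBI::dbQuoteIdentifier(con, tbl)))
          notnull_fk <- intersect(fks$from, info$name[info$notnull == 1])
          unresolved <- notnull_fk[vapply(notnull_fk, function(cn)
            is.null(values[[cn]]) || is.na(values[[cn]]), logical(1))]
          if (length(unresolved) > 0) {
            rejected <- rejected + 1L
            rejections[[length(rejections) + 1L]] <- data.frame(
              record_id = row$record_id, event = row$redcap_event_name,
              instrument = inst, instance = row$redcap_repeat_instance,
              field = unresolved[1],
              reason = "parent row unavailable (rejected or missing)",
              stringsAsFactors = FALSE)
            next
          }
          if (tbl == "Patients") {
            res <- upsert_row(con, "Patients", "study_code",
                              row$record_id, values)
          } else {
            res <- upsert_row(con, tbl, "redcap_key", rkey, values)
          }
          parent_ids[[tbl]] <- res$id
          if (res$status == "inserted") inserted <- inserted + 1L
          if (res$status == "updated") updated <- updated + 1L
        }
      }
    }
  })
  rej_df <- if (length(rejections) > 0) do.call(rbind, rejections) else
    data.frame(record_id = character(0), event = character(0),
               instrument = character(0), instance = character(0),
               field = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  ingest_report(inserted, updated, rejected, rej_df)
}
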