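#' @title File provenance and the unified query layer
#' @description
#' Every managed file is one row of `Files`. A file derived from another
#' file points back to it through `source_id`; the spatial transformation
#' that produced it is recorded in `Transformations` (warp file paired with
#' the target-space image) and referenced through `transformation_id`.
#' The induced derivation graph is kept acyclic at write time, so the full
#' history of any file — the lineage chain — is always recoverable.
#' @name provenance
NULL

#' File-type vocabulary
#' @return Character vector of general file types.
#' @export
file_types <- function() {
  c("anat", "ct", "label", "warp", "trajectory", "vta", "conductivity",
    "electrode-model", "other")
}

fetch_file <- function(con, file_id) {
  DBI::dbGetQuery(con, "SELECT * FROM Files WHERE file_id = ?",
                  params = list(file_id))
}

#' Register a managed file
#'
#' Idempotent on `path`: registering an identical path with identical
#' metadata returns the existing id; a path collision with different
#' metadata is a conflict error.
#'
#' @param con Database connection.
#' @param path Relative path under the BIDS root (unique).
#' @param patient_id,electrode_id Optional subject link (surrogate keys).
#' @param file_type One of [file_types()].
#' @param source_id Optional id of the originating file.
#' @param transformation_id Optional id of the transformation that produced
#'   the file (requires `source_id`).
#' @param checksum Optional content checksum.
#' @return The `file_id` (integer).
#' @export
register_file <- function(con, path, patient_id = NULL, electrode_id = NULL,
                          file_type = "other", source_id = NULL,
                          transformation_id = NULL, checksum = NULL) {
  if (!file_type %in% file_types())
    stop("unknown file_type '", file_type, "'", call. = FALSE)
  existing <- DBI::dbGetQuery(con, "SELECT * FROM Files WHERE path = ?",
                              params = list(path))
  norm <- function(x) if (is.null(x)) NA else x
  if (nrow(existing) > 0) {
    meta_same <-
      ((is.null(patient_id) && is.na(existing$patient_id[1])) ||
         isTRUE(norm(patient_id) == existing$patient_id[1])) &&
      ((is.null(electrode_id) && is.na(existing$electrode_id[1])) ||
         isTRUE(norm(electrode_id) == existing$electrode_id[1])) &&
      identical(file_type, existing$file_type[1]) &&
      # a NULL source_id means "unspecified", not "must be absent":
      # lineage pointers may have been attached after first registration
      (is.null(source_id) || isTRUE(norm(source_id) == existing$source_id[1]))
    if (!meta_same)
      stop("conflict: path '", path,
           "' is already registered with different metadata", call. = FALSE)
    return(existing$file_id[1])
  }
  if (!is.null(source_id) && nrow(fetch_file(con, source_id)) == 0)
    stop("integrity error: source_id ", source_id, " does not exist",
         call. = FALSE)
  if (!is.null(transformation_id)) {
    if (is.null(source_id))
      stop("transformation_id requires source_id", call. = FALSE)
    tr <- DBI::dbGetQuery(con,
      "SELECT * FROM Transformations WHERE transformation_id = ?",
      params = list(transformation_id))
    if (nrow(tr) == 0)
      stop("integrity error: transformation_id ", transformation_id,
           " does not exist", call. = FALSE)
  }
  DBI::dbExecute(con, paste(
    "INSERT INTO Files (patient_id, electrode_id, path, file_type,",
    " source_id, transformation_id, checksum, registered_at)",
    "VALUES (?, ?, ?, ?, ?, ?, ?, ?)"),
    params = list(norm(patient_id), norm(electrode_id), path, file_type,
                  norm(source_id), norm(transformation_id), norm(checksum),
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1]
}

#' Record a spatial transformation
#'
#' Pairs a warp file with the image defining the target space of the
#' transformation output. Registering an identical pair again returns the
#' existing id.
#'
#' @param con Database connection.
#' @param transform_id `file_id` of the warp/transform file.
#' @param target_id `file_id` of the target-space image.
#' @param method Optional free-text registration method.
#' @return The `transformation_id`.
#' @export
register_transformation <- function(con, transform_id, target_id,
                                    method = NULL) {
  if (identical(transform_id, target_id))
    stop("transform_id and target_id must differ", call. = FALSE)
  for (id in c(transform_id, target_id)) {
    if (nrow(fetch_file(con, id)) == 0)
      stop("integrity error: file ", id, " does not exist", call. = FALSE)
  }
  existing <- DBI::dbGetQuery(con, paste(
    "SELECT transformation_id FROM Transformations",
    "WHERE transform_id = ? AND target_id = ?"),
    params = list(transform_id, target_id))
  if (nrow(existing) > 0) return(existing$transformation_id[1])
  DBI::dbExecute(con, paste(
    "INSERT INTO Transformations (transform_id, target_id, method)",
    "VALUES (?, ?, ?)"),
    params = list(transform_id, target_id,
                  if (is.null(method)) NA else method))
  DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1]
}

file_bids <- function(con, file_id) {
  DBI::dbGetQuery(con, "SELECT * FROM Bids WHERE file_id = ?",
                  params = list(file_id))
}

bids_row_to_name <- function(b) {
  nul <- function(x) if (is.na(x) || !nzchar(x)) NULL else x
  bids_name(subject = b$subject_label, suffix = b$suffix,
            session = nul(b$session), acquisition = nul(b$acquisition),
            space = nul(b$space), extension = b$extension)
}

insert_bids_row <- function(con, file_id, subject_type, name, category,
                            modality = NA, acq_time = NA, json_path = NA) {
  norm <- function(x) if (is.null(x)) NA else x
  DBI::dbExecute(con, paste(
    "INSERT INTO Bids (file_id, subject_type, subject_label, session,",
    " acquisition, space, suffix, extension, modality, category,",
    " acq_time, json_path) VALUES (?,?,?,?,?,?,?,?,?,?,?,?)"),
    params = list(file_id, subject_type, name$subject, norm(name$session),
                  norm(name$acquisition), norm(name$space), name$suffix,
                  name$extension, norm(modality), category, norm(acq_time),
                  norm(json_path)))
}

#' Register an image derived by a spatial transformation
#'
#' Computes the output name and category with [derive_transformed_name()]
#' (the target of the transformation fixes the destination space label),
#' registers the Files row with `source_id` and `transformation_id` set,
#' and creates the matching Bids row. No resampling is performed: this
#' records the product of an external transformation step.
#'
#' @param con Database connection.
#' @param source_id `file_id` of the native-space image.
#' @param transformation_id Transformation whose target defines the
#'   destination space.
#' @param direction `"PatientToAtlas"` or `"AtlasToPatient"`.
#' @return `file_id` of the derived image.
#' @export
register_derived_image <- function(con, source_id, transformation_id,
                                   direction) {
  src <- fetch_file(con, source_id)
  if (nrow(src) == 0)
    stop("integrity error: source file ", source_id, " does not exist",
         call. = FALSE)
  srcb <- file_bids(con, source_id)
  if (nrow(srcb) == 0)
    stop("source file ", source_id, " has no Bids row: not an image",
         call. = FALSE)
  tr <- DBI::dbGetQuery(con,
    "SELECT * FROM Transformations WHERE transformation_id = ?",
    params = list(transformation_id))
  if (nrow(tr) == 0)
    stop("integrity error: transformation ", transformation_id,
         " does not exist", call. = FALSE)
  tgtb <- file_bids(con, tr$target_id[1])
  if (nrow(tgtb) == 0)
    stop("transformation target has no Bids row", call. = FALSE)

  direction <- match.arg(direction, c("PatientToAtlas", "AtlasToPatient"))
  src_name <- bids_row_to_name(srcb)
  target_ref <- if (direction == "PatientToAtlas") {
    # target image is an atlas template: its session label is the version
    subject_ref("Atlas", atlas_version = tgtb$session[1])
  } else {
    subject_ref("Patient", tgtb$subject_label[1])
  }
  derived <- derive_transformed_name(src_name, target_ref, direction)
  # the derived file stays filed under the patient subject
  patient_subject <- if (direction == "PatientToAtlas") {
    subject_ref("Patient", src_name$subject)
  } else {
    target_ref
  }
  out_name <- derived$name
  out_name$subject <- patient_subject$subject_id
  rel <- resolve_path(out_name, patient_subject, derived$category)
  fid <- register_file(con, rel,
                       patient_id = if (is.na(src$patient_id[1])) NULL else
                         src$patient_id[1],
                       file_type = src$file_type[1],
                       source_id = source_id,
                       transformation_id = transformation_id)
  if (nrow(file_bids(con, fid)) == 0) {
    insert_bids_row(con, fid, srcb$subject_type[1], out_name,
                    derived$category, modality = srcb$modality[1])
  }
  fid
}

ancestors_of <- function(con, file_id) {
  chain <- integer(0)
  cur <- file_id
  repeat {
    row <- fetch_file(con, cur)
    if (nrow(row) == 0 || is.na(row$source_id[1])) break
    cur <- row$source_id[1]
    if (cur %in% chain || cur == file_id) break
    chain <- c(chain, cur)
  }
  chain
}

#' Re-point the source of a file
#'
#' Rejects updates that would make the derivation graph cyclic.
#'
#' @param con Database connection.
#' @param file_id File to update.
#' @param source_id New originating file id.
#' @return `file_id`, invisibly.
#' @export
set_file_source <- function(con, file_id, source_id) {
  if (identical(file_id, source_id))
    stop("cycle rejected: a file cannot be its own source", call. = FALSE)
  if (nrow(fetch_file(con, source_id)) == 0)
    stop("integrity error: source_id ", source_id, " does not exist",
         call. = FALSE)
  if (file_id %in% ancestors_of(con, source_id))
    stop("cycle rejected: file ", file_id, " is an ancestor of ", source_id,
         call. = FALSE)
  DBI::dbExecute(con, "UPDATE Files SET source_id = ? WHERE file_id = ?",
                 params = list(source_id, file_id))
  invisible(file_id)
}

#' History of a file: its lineage chain
#'
#' Walks `source_id` links from the queried file back to its original raw
#' file and returns the chain in origin-to-query order, with the
#' transformation applied at each step attached.
#'
#' @param con Database connection.
#' @param file_id File to trace.
#' @return Object of class `lineage_chain`: list with `files` (data frame,
#'   origin first) and `transformations` (data frame aligned to `files`;
#'   the transformation recorded on each derived step, `NA` rows for the
#'   origin).
#' @export
lineage <- function(con, file_id) {
  if (nrow(fetch_file(con, file_id)) == 0)
    stop("not found: file ", file_id, call. = FALSE)
  ids <- c(rev(ancestors_of(con, file_id)), file_id)
  files <- do.call(rbind, lapply(ids, function(id) fetch_file(con, id)))
  trs <- lapply(files$transformation_id, function(tid) {
    if (is.na(tid)) return(NULL)
    DBI::dbGetQuery(con,
      "SELECT * FROM Transformations WHERE transformation_id = ?",
      params = list(tid))
  })
  structure(list(files = files, transformations = trs),
            class = "lineage_chain")
}

#' @export
print.lineage_chain <- function(x, ...) {
  n <- nrow(x$files)
  cat("lineage chain of", n, if (n == 1) "step\n" else "steps\n")
  for (i in seq_len(n)) {
    tr <- x$transformations[[i]]
    cat(sprintf("  %d. [%d] %s%s\n", i, x$files$file_id[i], x$files$path[i],
                if (!is.null(tr))
                  sprintf("  (via transformation %d)", tr$transformation_id[1])
                else ""))
  }
  invisible(x)
}

#' Delete a managed file row
#'
#' A file with registered descendants (or referenced by a transformation)
#' is protected: deletion requires an explicit cascade.
#'
#' @param con Database connection.
#' @param file_id File to delete.
#' @param cascade Also delete descendants and dependent rows.
#' @return Number of Files rows deleted.
#' @export
delete_file <- function(con, file_id, cascade = FALSE) {
  kids <- DBI::dbGetQuery(con,
    "SELECT file_id FROM Files WHERE source_id = ?", params = list(file_id))
  used <- DBI::dbGetQuery(con, paste(
    "SELECT transformation_id FROM Transformations",
    "WHERE transform_id = ? OR target_id = ?"),
    params = list(file_id, file_id))
  if ((nrow(kids) > 0 || nrow(used) > 0) && !cascade)
    stop("file ", file_id, " has registered descendants or transformation ",
         "references; pass cascade = TRUE to delete them too", call. = FALSE)
  n <- 0L
  if (cascade) {
    for (k in kids$file_id) n <- n + delete_file(con, k, cascade = TRUE)
    for (t in used$transformation_id) {
      DBI::dbExecute(con,
        "UPDATE Files SET transformation_id = NULL WHERE transformation_id = ?",
        params = list(t))
      DBI::dbExecute(con,
        "DELETE FROM Transformations WHERE transformation_id = ?",
        params = list(t))
    }
  }
  DBI::dbExecute(con, "DELETE FROM Bids WHERE file_id = ?",
                 params = list(file_id))
  DBI::dbExecute(con, "DELETE FROM Labels WHERE file_id = ?",
                 params = list(file_id))
  n + DBI::dbExecute(con, "DELETE FROM Files WHERE file_id = ?",
                     params = list(file_id))
}

.criteria_fields <- c("disease", "center", "subject", "space", "file_type",
                      "suffix", "session", "category")

#' Query criteria for file selection
#'
#' All predicates are optional and conjunctive; empty criteria match every
#' file.
#'
#' @param disease Disease code(s) (`ET`, `PD`, `other`).
#' @param center Center code(s).
#' @param subject Subject label(s) (study codes, `ATLAS`, electrode ids).
#' @param space Space label(s) of transformed images.
#' @param file_type General file type(s), see [file_types()].
#' @param suffix BIDS suffix(es), e.g. `T1w`, `CT`, `dseg`.
#' @param session Session label(s).
#' @param category Content categories, see [content_categories()].
#' @return Object of class `query_criteria`.
#' @export
query_criteria <- function(disease = NULL, center = NULL, subject = NULL,
                           space = NULL, file_type = NULL, suffix = NULL,
                           session = NULL, category = NULL) {
  if (!is.null(disease) && !all(disease %in% c("ET", "PD", "other")))
    stop("criteria error: unknown disease value(s): ",
         paste(setdiff(disease, c("ET", "PD", "other")), collapse = ", "),
         call. = FALSE)
  if (!is.null(file_type) && !all(file_type %in% file_types()))
    stop("criteria error: unknown file_type value(s): ",
         paste(setdiff(file_type, file_types()), collapse = ", "),
         call. = FALSE)
  if (!is.null(category) && !all(category %in% content_categories()))
    stop("criteria error: unknown category value(s): ",
         paste(setdiff(category, content_categories()), collapse = ", "),
         call. = FALSE)
  structure(list(disease = disease, center = center, subject = subject,
                 space = space, file_type = file_type, suffix = suffix,
                 session = session, category = category),
            class = "query_criteria")
}

#' Fully materialized file join
#'
#' One row per Files row, joined with its Bids entities, Label structure
#' and the owning patient's demographics. This is the relation that
#' [select_files()] filters.
#'
#' @param con Database connection.
#' @return Data frame ordered by (subject label, path).
#' @export
files_join <- function(con) {
  DBI::dbGetQuery(con, paste(
    "SELECT f.file_id, f.path, f.file_type, f.source_id, f.transformation_id,",
    " b.subject_type, b.subject_label, b.session, b.acquisition, b.space,",
    " b.suffix, b.extension, b.modality, b.category,",
    " l.structure, p.study_code, p.disease, c.code AS center",
    "FROM Files f",
    "LEFT JOIN Bids b ON b.file_id = f.file_id",
    "LEFT JOIN Labels l ON l.file_id = f.file_id",
    "LEFT JOIN Patients p ON p.patient_id = f.patient_id",
    "LEFT JOIN Centers c ON c.center_id = p.center_id",
    "ORDER BY b.subject_label, f.path"))
}

#' Select files for an analysis workflow
#'
#' The streamlined single-step selection behind group analyses: files are
#' filtered by clinical attributes (disease, center) joined with their
#' imaging attributes (space, suffix, session, category, file type).
#'
#' @param con Database connection.
#' @param criteria A [query_criteria()] object.
#' @return Data frame of matching files (stable order: subject, path).
#' @export
#' @examples
#' \dontrun{
#' select_files(con, query_criteria(disease = "ET", space = "v1"))
#' }
select_files <- function(con, criteria = query_criteria()) {
  stopifnot(inherits(criteria, "query_criteria"))
  clauses <- character(0); params <- list()
  add <- function(col, vals) {
    if (is.null(vals)) return()
    clauses <<- c(clauses, sprintf("%s IN (%s)", col,
      paste(rep("?", length(vals)), collapse = ", ")))
    params <<- c(params, as.list(vals))
  }
  add("p.disease", criteria$disease)
  add("c.code", criteria$center)
  add("b.subject_label", criteria$subject)
  add("b.space", criteria$space)
  add("f.file_type", criteria$file_type)
  add("b.suffix", criteria$suffix)
  add("b.session", criteria$session)
  add("b.category", criteria$category)
  sql <- paste(
    "SELECT f.file_id, f.path, f.file_type, f.source_id, f.transformation_id,",
    " b.subject_type, b.subject_label, b.session, b.acquisition, b.space,",
    " b.suffix, b.extension, b.modality, b.category,",
    " l.structure, p.study_code, p.disease, c.code AS center",
    "FROM Files f",
    "LEFT JOIN Bids b ON b.file_id = f.file_id",
    "LEFT JOIN Labels l ON l.file_id = f.file_id",
    "LEFT JOIN Patients p ON p.patient_id = f.patient_id",
    "LEFT JOIN Centers c ON c.center_id = p.center_id")
  if (length(clauses) > 0)
    sql <- paste(sql, "WHERE", paste(clauses, collapse = " AND "))
  sql <- paste(sql, "ORDER BY b.subject_label, f.path")
  if (length(params) == 0) return(DBI::dbGetQuery(con, sql))
  DBI::dbGetQuery(con, sql, params = params)
}

#' Everything the database knows about one patient
#'
#' @param con Database connection.
#' @param study_code The patient's study code.
#' @return Object of class `patient_bundle`: named list of data frames
#'   (`patient`, `targeting`, `stimulations`, `stimulation_effects`,
#'   `chronic_settings`, `implanted_positions`, `mer_sessions`,
#'   `evaluations_preop`, `evaluations_postop`, `medications`, `files`).
#' @export
patient_bundle <- function(con, study_code) {
  p <- DBI::dbGetQuery(con, "SELECT * FROM Patients WHERE study_code = ?",
                       params = list(study_code))
  if (nrow(p) == 0)
    stop("not found: no patient with study code '", study_code, "'",
         call. = FALSE)
  pid <- p$patient_id[1]
  by_pid <- function(tbl) {
    DBI::dbGetQuery(con, sprintf("SELECT * FROM %s WHERE patient_id = ?", tbl),
                    params = list(pid))
  }
  stim_effects <- DBI::dbGetQuery(con, paste(
    "SELECT e.* FROM StimulationEffects e",
    "JOIN Stimulations s ON s.stimulation_id = e.stimulation_id",
    "WHERE s.patient_id = ?"), params = list(pid))
  structure(list(
    patient = p,
    targeting = by_pid("TargetingPlans"),
    stimulations = by_pid("Stimulations"),
    stimulation_effects = stim_effects,
    chronic_settings = by_pid("ChronicSettings"),
    implanted_positions = by_pid("ImplantedPositions"),
    mer_sessions = by_pid("MerSessions"),
    evaluations_preop = by_pid("PreopEvaluations"),
    evaluations_postop = by_pid("PostopEvaluations"),
    medications = by_pid("Medications"),
    files = by_pid("Files")
  ), class = "patient_bundle")
}

#' @export
print.patient_bundle <- function(x, ...) {
  cat("patient", x$patient$study_code[1],
      sprintf("(%s, center %s)\n", x$patient$disease[1],
              x$patient$center_id[1]))
  for (nm in setdiff(names(x), "patient"))
    cat(sprintf("  %-22s %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
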