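#' @title Image ingestion into the BIDS tree and database
#' @description
#' Images enter the system through a manifest: one row per file with
#' enough metadata (subject, subject type, session, acquisition, suffix,
#' content category, optional structure label and space) to compute the
#' BIDS name and canonical path. Files are copied — never moved — into the
#' layout, and each one becomes a `Files` row, a `Bids` row, and (for
#' labeled structures) a `Labels` row. Voxel data is never interpreted:
#' images are opaque payloads, only sidecars are read for metadata.
#' @name image-ingest
NULL

manifest_columns <- c("source_path", "subject", "subject_type", "session",
                      "acquisition", "suffix", "extension", "category",
                      "structure", "space", "transform_file", "target_file",
                      "source_file")

#' Read an image manifest
#'
#' @param path CSV or JSON manifest file.
#' @return Data frame with the manifest columns (missing optional columns
#'   filled with `""`).
#' @export
read_manifest <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  }
  for (cn in manifest_columns) {
    if (!cn %in% names(df)) df[[cn]] <- rep("", nrow(df))
    df[[cn]] <- as.character(df[[cn]])
    df[[cn]][is.na(df[[cn]])] <- ""
  }
  df[manifest_columns]
}

category_file_type <- function(category, suffix) {
  switch(category,
    "Segmentations" = "label",
    "Transforms" = "warp",
    "VTA" = "vta",
    "Conductivity" = "conductivity",
    "Trajectories" = "trajectory",
    "ElectrodeModel" = "electrode-model",
    if (identical(toupper(suffix), "CT")) "ct"
    else if (identical(suffix, "dseg")) "label"
    else "anat")
}

manifest_entry_name <- function(entry) {
  opt <- function(x) if (nzchar(x)) x else NULL
  ext <- if (nzchar(entry$extension)) entry$extension else {
    split_extension(entry$source_path)$extension
  }
  bids_name(subject = entry$subject, suffix = entry$suffix,
            session = opt(entry$session), acquisition = opt(entry$acquisition),
            space = opt(entry$space), extension = ext)
}

manifest_entry_subject <- function(entry, name) {
  if (entry$subject_type == "Atlas") {
    subject_ref("Atlas", entry$subject, atlas_version = name$session)
  } else {
    subject_ref(entry$subject_type, entry$subject)
  }
}

read_sidecar <- function(source_path) {
  sc <- paste0(split_extension(source_path)$stem, ".json")
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

# Electrode model registration: sidecar carries contact geometry.
apply_electrode_sidecar <- function(con, electrode_id, file_id, meta) {
  sets <- list(file_id = file_id)
  if (!is.null(meta$Manufacturer)) sets$manufacturer <- meta$Manufacturer
  if (!is.null(meta$NContacts)) sets$n_contacts <- meta$NContacts
  if (!is.null(meta$ContactLengthMm)) sets$contact_length_mm <- meta$ContactLengthMm
  if (!is.null(meta$ContactSpacingMm)) sets$contact_spacing_mm <- meta$ContactSpacingMm
  if (!is.null(meta$DiameterMm)) sets$diameter_mm <- meta$DiameterMm
  assign_sql <- paste(vapply(names(sets), function(cn)
    sprintf("%s = ?", DBI::dbQuoteIdentifier(con, cn)), character(1)),
    collapse = ", ")
  DBI::dbExecute(con,
    sprintf("UPDATE Electrodes SET %s WHERE electrode_id = ?", assign_sql),
    params = c(unname(sets), list(electrode_id)))
  contacts <- meta$Contacts
  if (!is.null(contacts)) {
    have <- DBI::dbGetQuery(con,
      "SELECT COUNT(*) AS n FROM ElectrodeContacts WHERE electrode_id = ?",
      params = list(electrode_id))$n[1]
    if (have == 0) {
      contacts <- as.data.frame(contacts)
      for (i in seq_len(nrow(contacts))) {
        DBI::dbExecute(con, paste(
          "INSERT INTO ElectrodeContacts",
          "(electrode_id, contact_index, length_mm, position_mm, surface_mm2)",
          "VALUES (?, ?, ?, ?, ?)"),
          params = list(electrode_id, contacts$ContactIndex[i],
                        contacts$LengthMm[i], contacts$PositionMm[i],
                        contacts$SurfaceMm2[i]))
      }
    }
  }
}

#' Ingest images from a manifest into a BIDS root and the database
#'
#' Copies each manifest file to its canonical location under `root`,
#' together with its JSON sidecar when one sits next to the source, and
#' registers Files/Bids/Labels rows. Transform entries that name a
#' `target_file` create a Transformations row; entries carrying a `space`
#' label and naming `source_file`/`transform_file` get their lineage
#' pointers set. Re-ingesting identical input adds zero rows.
#'
#' @param manifest Data frame (see [read_manifest()]) or path to one.
#' @param con Database connection.
#' @param root BIDS root directory (created if needed).
#' @return An `ingest_report`.
#' @export
ingest_images <- function(manifest, con, root) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is_dbs_database(con))
    stop("schema mismatch: connection is not an initialized dbsdata database",
         call. = FALSE)
  init_bids_root(root)
  inserted <- 0L; updated <- 0L; rejected <- 0L
  rejections <- list()
  reject <- function(entry, reason) {
    rejected <<- rejected + 1L
    rejections[[length(rejections) + 1L]] <<- data.frame(
      item = entry$source_path, reason = reason, stringsAsFactors = FALSE)
  }
  resolved <- character(0)  # formatted filename -> file_id

  for (i in seq_len(nrow(manifest))) {
    entry <- as.list(manifest[i, , drop = FALSE])
    if (!nzchar(entry$subject) || !nzchar(entry$suffix) ||
        !nzchar(entry$subject_type) || !nzchar(entry$category)) {
      reject(entry, "missing required metadata (subject/subject_type/suffix/category)")
      next
    }
    if (!entry$subject_type %in% c("Patient", "Atlas", "Electrode")) {
      reject(entry, paste0("unknown subject_type '", entry$subject_type, "'"))
      next
    }
    res <- tryCatch({
      name <- manifest_entry_name(entry)
      subj <- manifest_entry_subject(entry, name)
      rel <- resolve_path(name, subj, entry$category)
      list(name = name, subj = subj, rel = rel)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) { reject(entry, res); next }
    if (!file.exists(entry$source_path)) {
      reject(entry, "source file does not exist")
      next
    }
    dest <- file.path(root, res$rel)
    src_md5 <- unname(tools::md5sum(entry$source_path))
    if (file.exists(dest)) {
      if (!identical(unname(tools::md5sum(dest)), src_md5))
        stop("path collision: '", res$rel,
             "' already exists with different content", call. = FALSE)
    } else {
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      file.copy(entry$source_path, dest)
    }
    sidecar <- read_sidecar(entry$source_path)
    json_rel <- NA
    if (!is.null(sidecar)) {
      json_rel <- paste0(split_extension(res$rel)$stem, ".json")
      jdest <- file.path(root, json_rel)
      if (!file.exists(jdest))
        file.copy(paste0(split_extension(entry$source_path)$stem, ".json"),
                  jdest)
    }

    patient_id <- NULL; electrode_id <- NULL
    if (entry$subject_type == "Patient")
      patient_id <- resolve_patient(con, entry$subject)
    if (entry$subject_type == "Electrode")
      electrode_id <- resolve_electrode(con, entry$subject)

    pre_existing <- DBI::dbGetQuery(con,
      "SELECT file_id FROM Files WHERE path = ?", params = list(res$rel))
    fid <- register_file(con, res$rel, patient_id = patient_id,
                         electrode_id = electrode_id,
                         file_type = category_file_type(entry$category,
                                                        entry$suffix),
                         checksum = src_md5)
    if (nrow(pre_existing) == 0) inserted <- inserted + 1L
    if (nrow(file_bids(con, fid)) == 0) {
      insert_bids_row(con, fid, entry$subject_type, res$name, entry$category,
                      modality = sidecar$Modality %||% res$name$suffix,
                      acq_time = sidecar$AcquisitionTime %||% NA,
                      json_path = json_rel)
    }
    if (nzchar(entry$structure)) {
      have <- DBI::dbGetQuery(con,
        "SELECT file_id FROM Labels WHERE file_id = ?", params = list(fid))
      if (nrow(have) == 0) {
        DBI::dbExecute(con,
          "INSERT INTO Labels (file_id, structure) VALUES (?, ?)",
          params = list(fid, entry$structure))
      }
    }
    if (!is.null(electrode_id) && !is.null(sidecar))
      apply_electrode_sidecar(con, electrode_id, fid, sidecar)
    resolved[format_bids_name(res$name)] <- fid
  }

  lookup <- function(fname) {
    if (fname %in% names(resolved)) return(as.integer(resolved[[fname]]))
    row <- DBI::dbGetQuery(con,
      "SELECT file_id FROM Files WHERE path LIKE ?",
      params = list(paste0("%/", fname)))
    if (nrow(row) == 1) row$file_id[1] else NA_integer_
  }

  # second pass: transformations, then lineage pointers on derived images
  for (i in seq_len(nrow(manifest))) {
    entry <- as.list(manifest[i, , drop = FALSE])
    if (entry$category == "Transforms" && nzchar(entry$target_file)) {
      warp_name <- tryCatch(format_bids_name(manifest_entry_name(entry)),
                            error = function(e) NA)
      if (is.na(warp_name)) next
      warp_id <- lookup(warp_name)
      target_id <- lookup(entry$target_file)
      if (is.na(warp_id) || is.na(target_id)) {
        reject(entry, "transform or target file not registered")
        next
      }
      register_transformation(con, warp_id, target_id)
    }
  }
  for (i in seq_len(nrow(manifest))) {
    entry <- as.list(manifest[i, , drop = FALSE])
    if (nzchar(entry$space) && nzchar(entry$source_file)) {
      fname <- tryCatch(format_bids_name(manifest_entry_name(entry)),
                        error = function(e) NA)
      if (is.na(fname)) next
      fid <- lookup(fname)
      src_id <- lookup(entry$source_file)
      if (is.na(fid) || is.na(src_id)) {
        reject(entry, "derived image source not registered")
        next
      }
      tid <- NA_integer_
      if (nzchar(entry$transform_file)) {
        warp_id <- lookup(entry$transform_file)
        if (!is.na(warp_id)) {
          tr <- DBI::dbGetQuery(con,
            "SELECT transformation_id FROM Transformations WHERE transform_id = ?",
            params = list(warp_id))
          if (nrow(tr) > 0) tid <- tr$transformation_id[1]
        }
      }
      cur <- fetch_file(con, fid)
      if (is.na(cur$source_id[1])) {
        set_file_source(con, fid, src_id)
        if (!is.na(tid)) {
          DBI::dbExecute(con,
            "UPDATE Files SET transformation_id = ? WHERE file_id = ?",
            params = list(tid, fid))
        }
      }
    }
  }
  rej_df <- if (length(rejections) > 0) do.call(rbind, rejections) else
    data.frame(item = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  ingest_report(inserted, updated, rejected, rej_df)
}

tree_violation <- function(path, rule, severity) {
  data.frame(path = path, rule = rule, severity = severity,
             stringsAsFactors = FALSE)
}

infer_category_from_path <- function(rel) {
  parts <- strsplit(rel, "/", fixed = TRUE)[[1]]
  if (parts[1] == "derivatives") {
    if (length(parts) < 4) return(NA_character_)
    if (parts[3] == "anat") "anat-raw" else parts[3]
  } else {
    if (length(parts) == 4 && parts[3] == "anat") "anat-raw" else NA_character_
  }
}

#' Validate a BIDS tree against the layout rules and the database
#'
#' Checks that every data file parses as a BIDS name and lies at its
#' canonical location, that dataset descriptions exist at the root and in
#' `derivatives/`, that every database file row resolves to an existing
#' file, and that every on-disk data file is registered. Violations are
#' returned as data, never raised.
#'
#' @param root BIDS root directory.
#' @param con Database connection.
#' @return Data frame with columns `path`, `rule`, `severity`
#'   (`"error"`/`"warning"`); zero rows when the tree is clean.
#' @export
validate_tree <- function(root, con) {
  stopifnot(dir.exists(root))
  out <- list()
  push <- function(v) out[[length(out) + 1L]] <<- v

  for (dd in c(file.path(root, "dataset_description.json"),
               file.path(root, "derivatives", "dataset_description.json"))) {
    if (!file.exists(dd))
      push(tree_violation(dd, "missing dataset_description.json", "error"))
  }

  all_files <- list.files(root, recursive = TRUE, all.files = FALSE)
  data_files <- all_files[!grepl("\\.json$", all_files)]
  db_paths <- DBI::dbGetQuery(con, "SELECT path FROM Files")$path

  for (rel in data_files) {
    parsed <- tryCatch(parse_bids_name(basename(rel)),
                       error = function(e) conditionMessage(e))
    if (is.character(parsed)) {
      push(tree_violation(rel, paste("unparsable BIDS name:", parsed),
                          "error"))
      next
    }
    category <- infer_category_from_path(rel)
    if (is.na(category) || !category %in% content_categories()) {
      push(tree_violation(rel, "file outside any recognized layout location",
                          "error"))
      next
    }
    subject_type <- if (parsed$subject == "ATLAS") "Atlas"
      else if (grepl("^ELEC", parsed$subject)) "Electrode" else "Patient"
    subj <- tryCatch({
      if (subject_type == "Atlas")
        subject_ref("Atlas", parsed$subject, atlas_version = parsed$session)
      else subject_ref(subject_type, parsed$subject)
    }, error = function(e) NULL)
    canon <- if (is.null(subj)) NULL else
      tryCatch(resolve_path(parsed, subj, category),
               error = function(e) NULL)
    if (is.null(canon) || !identical(canon, rel)) {
      push(tree_violation(rel, paste0("file not at canonical location",
        if (!is.null(canon)) paste0(" (expected ", canon, ")") else ""),
        "error"))
    }
    if (!rel %in% db_paths)
      push(tree_violation(rel, "on-disk file has no database row", "error"))
  }

  for (p in db_paths) {
    if (!file.exists(file.path(root, p)))
      push(tree_violation(p, "database row references missing file", "error"))
  }

  if (length(out) == 0) {
    return(data.frame(path = character(0), rule = character(0),
                      severity = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
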