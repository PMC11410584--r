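#' @title BIDS naming for DBS raw and derivative images
#' @description
#' Filenames follow the BIDS entity grammar `key-value` pairs joined by
#' underscores before a suffix and extension. Patient images transformed
#' into another reference space carry a `space-` entity, and the printed
#' entity order used throughout this package is `sub, space, ses, acq`.
#' Atlas-subject files encode the atlas version as their `ses-` label
#' (`sub-ATLAS_ses-<version>`).
#' @name bids-naming
NULL

.bids_extensions <- c(".nii.gz", ".nii", ".json", ".h5", ".txt")
.bids_entity_order <- c("sub", "space", "ses", "acq")

#' Derivative content categories
#'
#' Derivative files are grouped by content, not by processing step: one
#' folder per category under `derivatives/sub-<id>/`. `anat-raw` marks raw
#' anatomical acquisitions, which for patients live outside `derivatives`
#' (`sub-<id>/ses-<ses>/anat/`).
#'
#' @return Character vector of category names.
#' @export
content_categories <- function() {
  c("anat-raw", "Segmentations", "PatientInAtlas", "AtlasInPatient",
    "Trajectories", "VTA", "Conductivity", "Transforms", "ElectrodeModel")
}

#' Construct a BIDS name
#'
#' @param subject Subject label (alphanumeric, no underscore/hyphen).
#' @param suffix File suffix, e.g. `"T1w"`, `"CT"`, `"dseg"`, `"xfm"`.
#' @param session,acquisition,space Optional entity labels.
#' @param extension One of `.nii.gz`, `.nii`, `.json`, `.h5`, `.txt`.
#' @return Object of class `bids_name`.
#' @export
bids_name <- function(subject, suffix, session = NULL, acquisition = NULL,
                      space = NULL, extension = ".nii.gz") {
  x <- structure(
    list(subject = subject, session = session, acquisition = acquisition,
         space = space, suffix = suffix, extension = extension),
    class = "bids_name")
  validate_bids_name(x)
  x
}

valid_label <- function(x) {
  is.character(x) && length(x) == 1 && grepl("^[A-Za-z0-9]+$", x)
}

validate_bids_name <- function(x) {
  if (!valid_label(x$subject))
    stop("invalid subject label '", x$subject,
         "': labels must be alphanumeric (no underscore or hyphen)",
         call. = FALSE)
  if (!valid_label(x$suffix))
    stop("invalid suffix '", x$suffix, "'", call. = FALSE)
  for (ent in c("session", "acquisition", "space")) {
    v <- x[[ent]]
    if (!is.null(v) && !valid_label(v))
      stop("invalid ", ent, " label '", v,
           "': labels must be alphanumeric (no underscore or hyphen)",
           call. = FALSE)
  }
  if (!x$extension %in% .bids_extensions)
    stop("unsupported extension '", x$extension, "'", call. = FALSE)
  invisible(x)
}

#' @export
print.bids_name <- function(x, ...) {
  cat(format_bids_name(x), "\n")
  invisible(x)
}

#' @export
format.bids_name <- function(x, ...) format_bids_name(x)

split_extension <- function(filename) {
  for (ext in .bids_extensions) {
    if (endsWith(filename, ext)) {
      return(list(stem = substr(filename, 1, nchar(filename) - nchar(ext)),
                  extension = ext))
    }
  }
  stop("unsupported or missing extension in '", filename, "'", call. = FALSE)
}

#' Parse a BIDS filename
#'
#' Entities are recognized by key regardless of their order in the name; the
#' final underscore-separated token is the suffix. Unknown entity keys
#' trigger a warning and are dropped.
#'
#' @param filename Filename (no directory components).
#' @return A [bids_name()] object.
#' @export
#' @examples
#' parse_bids_name("sub-P001_ses-pre_acq-ppp_T1w.nii.gz")
parse_bids_name <- function(filename) {
  stopifnot(is.character(filename), length(filename) == 1)
  parts <- split_extension(basename(filename))
  tokens <- strsplit(parts$stem, "_", fixed = TRUE)[[1]]
  if (length(tokens) < 2)
    stop("cannot parse '", filename,
         "': need at least a sub- entity and a suffix", call. = FALSE)
  suffix <- tokens[length(tokens)]
  if (grepl("-", suffix, fixed = TRUE))
    stop("cannot parse '", filename, "': missing suffix (last token '",
         suffix, "' looks like an entity)", call. = FALSE)
  ents <- list()
  for (tok in tokens[-length(tokens)]) {
    m <- regmatches(tok, regexec("^([A-Za-z0-9]+)-(.*)$", tok))[[1]]
    if (length(m) != 3)
      stop("malformed entity token '", tok, "' in '", filename, "'",
           call. = FALSE)
    key <- m[2]; value <- m[3]
    if (!valid_label(value))
      stop("malformed label '", value, "' for entity '", key, "' in '",
           filename, "'", call. = FALSE)
    if (!key %in% .bids_entity_order) {
      warning("unknown entity key '", key, "' in '", filename, "' (dropped)",
              call. = FALSE)
      next
    }
    if (!is.null(ents[[key]]))
      stop("duplicate entity '", key, "' in '", filename, "'", call. = FALSE)
    ents[[key]] <- value
  }
  if (is.null(ents$sub))
    stop("cannot parse '", filename, "': no sub- entity", call. = FALSE)
  bids_name(subject = ents$sub, session = ents$ses,
            acquisition = ents$acq, space = ents$space,
            suffix = suffix, extension = parts$extension)
}

#' Format a BIDS name as a filename
#'
#' Entities are emitted in the fixed order `sub`, `space`, `ses`, `acq`,
#' then the suffix and extension.
#'
#' @param name A [bids_name()] object.
#' @return Filename string.
#' @export
#' @examples
#' format_bids_name(bids_name("P001", "T1w", session = "pre",
#'                            acquisition = "ppp", space = "v1"))
format_bids_name <- function(name) {
  stopifnot(inherits(name, "bids_name"))
  validate_bids_name(name)
  ents <- c(sub = name$subject, space = name$space,
            ses = name$session, acq = name$acquisition)
  ents <- ents[!vapply(ents, is.null, logical(1))]
  ents <- ents[order(match(names(ents), .bids_entity_order))]
  paste0(paste(paste(names(ents), unlist(ents), sep = "-"), collapse = "_"),
         "_", name$suffix, name$extension)
}

#' Reference to a managed subject
#'
#' Three subject types exist: `Patient` (study participants), `Atlas`
#' (common anatomical spaces built from patient groups; `atlas_version`
#' distinguishes atlases built from different data or modalities) and
#' `Electrode` (implantable electrode models).
#'
#' @param subject_type `"Patient"`, `"Atlas"` or `"Electrode"`.
#' @param subject_id Subject label; Atlas subjects always use `"ATLAS"`.
#' @param atlas_version Version label, required iff `subject_type = "Atlas"`.
#' @return Object of class `subject_ref`.
#' @export
subject_ref <- function(subject_type, subject_id = NULL, atlas_version = NULL) {
  subject_type <- match.arg(subject_type, c("Patient", "Atlas", "Electrode"))
  if (subject_type == "Atlas") {
    if (is.null(atlas_version))
      stop("Atlas subjects require an atlas_version", call. = FALSE)
    if (is.null(subject_id)) subject_id <- "ATLAS"
    if (!valid_label(atlas_version))
      stop("invalid atlas version '", atlas_version, "'", call. = FALSE)
  } else {
    if (!is.null(atlas_version))
      stop("atlas_version is only meaningful for Atlas subjects", call. = FALSE)
    if (is.null(subject_id))
      stop("subject_id is required", call. = FALSE)
  }
  if (!valid_label(subject_id))
    stop("invalid subject id '", subject_id, "'", call. = FALSE)
  structure(list(subject_type = subject_type, subject_id = subject_id,
                 atlas_version = atlas_version),
            class = "subject_ref")
}

#' Derive the name of a spatially transformed image
#'
#' When a native-space image is resampled into another reference space, the
#' output keeps every entity of its source and gains a `space-` entity:
#' the atlas version for patient-to-atlas transforms, the patient id for
#' atlas-to-patient transforms. The output is filed under the patient's
#' `PatientInAtlas` or `AtlasInPatient` derivatives folder respectively.
#'
#' @param source A [bids_name()] in its native space (no `space-` entity).
#' @param target A [subject_ref()]: the Atlas (for `PatientToAtlas`) or the
#'   Patient (for `AtlasToPatient`) whose space the image is moved into.
#' @param direction `"PatientToAtlas"` or `"AtlasToPatient"`.
#' @return List with elements `name` (the derived [bids_name()]) and
#'   `category` (the content category).
#' @export
#' @examples
#' src <- parse_bids_name("sub-P001_ses-pre_acq-ppp_T1w.nii.gz")
#' derive_transformed_name(src, subject_ref("Atlas", atlas_version = "v1"),
#'                         "PatientToAtlas")
derive_transformed_name <- function(source, target, direction) {
  stopifnot(inherits(source, "bids_name"), inherits(target, "subject_ref"))
  direction <- match.arg(direction, c("PatientToAtlas", "AtlasToPatient"))
  if (!is.null(source$space))
    stop("source already carries a space entity ('space-", source$space,
         "'): it is not in its native space", call. = FALSE)
  out <- source
  if (direction == "PatientToAtlas") {
    if (target$subject_type != "Atlas")
      stop("PatientToAtlas requires an Atlas target", call. = FALSE)
    out$space <- target$atlas_version
    category <- "PatientInAtlas"
  } else {
    if (target$subject_type != "Patient")
      stop("AtlasToPatient requires a Patient target", call. = FALSE)
    out$space <- target$subject_id
    category <- "AtlasInPatient"
  }
  validate_bids_name(out)
  list(name = out, category = category)
}

category_subject_ok <- function(category, subject_type) {
  switch(category,
    "ElectrodeModel" = subject_type == "Electrode",
    "PatientInAtlas" = ,
    "AtlasInPatient" = ,
    "Trajectories" = ,
    "VTA" = ,
    "Conductivity" = subject_type == "Patient",
    TRUE)
}

#' Resolve the canonical relative path of a file
#'
#' Raw patient anatomical images resolve to
#' `sub-<id>/ses-<ses>/anat/<filename>`; every derivative resolves to
#' `derivatives/sub-<id>/<Category>/<filename>`. Atlas subjects (id
#' `ATLAS`) keep all files under `derivatives/`, including their
#' anatomical templates.
#'
#' @param name A [bids_name()].
#' @param subject A [subject_ref()].
#' @param category A content category (see [content_categories()]).
#' @return Relative path (forward slashes) under the BIDS root.
#' @export
resolve_path <- function(name, subject, category) {
  stopifnot(inherits(name, "bids_name"), inherits(subject, "subject_ref"))
  if (!category %in% content_categories())
    stop("unknown content category '", category, "'", call. = FALSE)
  if (!category_subject_ok(category, subject$subject_type))
    stop("category '", category, "' is not valid for subject type '",
         subject$subject_type, "'", call. = FALSE)
  if (!identical(name$subject, subject$subject_id))
    stop("filename subject 'sub-", name$subject,
         "' does not match subject id '", subject$subject_id, "'",
         call. = FALSE)
  fname <- format_bids_name(name)
  subdir <- paste0("sub-", subject$subject_id)
  if (category == "anat-raw" && subject$subject_type == "Patient") {
    if (is.null(name$session))
      stop("raw anatomical images require a ses- entity", call. = FALSE)
    return(file.path(subdir, paste0("ses-", name$session), "anat", fname))
  }
  folder <- if (category == "anat-raw") "anat" else category
  file.path("derivatives", subdir, folder, fname)
}

write_dataset_description <- function(dir, name, dataset_type) {
  path <- file.path(dir, "dataset_description.json")
  if (file.exists(path)) return(invisible(path))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  desc <- list(Name = name, BIDSVersion = "1.9.0", DatasetType = dataset_type)
  jsonlite::write_json(desc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Initialize a BIDS root directory
#'
#' Creates the root and `derivatives/` directories with their
#' `dataset_description.json` files (BIDS v1.9.0).
#'
#' @param root Directory to create.
#' @param name Dataset name recorded in the description files.
#' @return `root`, invisibly.
#' @export
init_bids_root <- function(root, name = "DBS study") {
  write_dataset_description(root, name, "raw")
  write_dataset_description(file.path(root, "derivatives"),
                            paste(name, "derivatives"), "derivative")
  invisible(root)
}
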