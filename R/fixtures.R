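#' @title Synthetic DBS cohort generator
#' @description
#' Generates a complete, seeded synthetic study: a REDCap-style
#' longitudinal CSV export covering ten clinical instruments per patient
#' (patient information, pre- and post-operative clinical evaluations,
#' medications, imaging metadata, targeting plan, microelectrode-recording
#' summaries, stimulation-test evaluations, implanted position, post-op
#' screening), the matching declarative mapping file, and an image manifest
#' with minimal valid NIfTI volumes and JSON sidecars (pre/post CT and MRI,
#' one STN label per patient, a warp to a versioned atlas and the
#' atlas-space derivative). Identical configuration and seed produce
#' byte-identical output. Value distributions are uniform within clinically
#' plausible ranges: the fixtures exercise the plumbing, not the science.
#' @name fixtures
NULL

#' Cohort configuration
#'
#' @param n_patients Number of patients (split round-robin over centers).
#' @param seed Integer seed; fully determines the output (and is woven into
#'   record ids so different seeds cannot collide).
#' @param centers Site codes; defaults to a 2-center study.
#' @param disease_weights Mixture weights over ET and PD (must sum to 1).
#' @param images_per_patient Mean image-file count per patient (minimum 6:
#'   three raw anatomical scans, one STN label, one warp, one atlas-space
#'   derivative; the remainder are extra raw MRI acquisitions).
#' @param sessions Session labels.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 5, seed = 42,
                          centers = c("BSL", "CLF"),
                          disease_weights = c(ET = 0.5, PD = 0.5),
                          images_per_patient = 6,
                          sessions = c("pre", "post")) {
  stopifnot(n_patients >= 0, length(centers) >= 1,
            abs(sum(disease_weights) - 1) < 1e-9, images_per_patient >= 6)
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 centers = centers, disease_weights = disease_weights,
                 images_per_patient = images_per_patient,
                 sessions = sessions),
            class = "cohort_config")
}

fixture_instruments <- function() {
  c("patient_information", "preop_clinical_evaluation",
    "postop_clinical_evaluation", "medications", "imaging_metadata",
    "targeting_plan", "mer_summary", "stimulation_test",
    "implanted_position", "postop_screening")
}

num <- function(x, digits = 1) formatC(x, format = "f", digits = digits)

# One row of the export, as a named character vector over all columns.
blank_row <- function(columns) {
  r <- setNames(rep("", length(columns)), columns)
  r
}

fixture_mapping_yaml <- function() {
  instr <- fixture_instruments()
  rep_flags <- instr != "patient_information"
  lines <- c("version: 1", "instruments:")
  for (i in seq_along(instr)) {
    lines <- c(lines, paste0("  - name: ", instr[i]),
               paste0("    repeating: ", tolower(rep_flags[i])))
  }
  entry <- function(inst, field, table, column, extra = character(0)) {
    c(paste0("  - instrument: ", inst),
      paste0("    field: ", field),
      paste0("    table: ", table),
      paste0("    column: ", column),
      extra)
  }
  coord <- c("    clean: {kind: decimal-normalize}",
             "    validate: {type: numeric, min: -100, max: 100}",
             "    required: true")
  numv <- function(min, max) {
    paste0("    validate: {type: numeric, min: ", min, ", max: ", max, "}")
  }
  lines <- c(lines, "entries:",
    entry("patient_information", "center", "Patients", "center_id",
          "    required: true"),
    entry("patient_information", "disease", "Patients", "disease",
          c("    validate: {choices: [ET, PD, other]}", "    required: true")),
    entry("patient_information", "sex", "Patients", "sex",
          "    clean: {kind: code-to-label, codes: {'1': M, '2': F}}"),
    entry("patient_information", "age_at_surgery", "Patients",
          "age_at_surgery", numv(18, 100)),
    entry("patient_information", "handedness", "Patients", "handedness"),
    entry("patient_information", "medical_history", "Patients",
          "medical_history"),
    entry("patient_information", "height_cm", "ClinicalDataGeneral",
          "height_cm", numv(100, 230)),
    entry("patient_information", "weight_kg", "ClinicalDataGeneral",
          "weight_kg", numv(30, 250)),
    entry("preop_clinical_evaluation", "preop_scale", "PreopEvaluations",
          "scale_name"),
    entry("preop_clinical_evaluation", "preop_score", "PreopEvaluations",
          "score_total", numv(0, 200)),
    entry("preop_clinical_evaluation", "preop_motor", "PreopEvaluations",
          "subscore_motor", numv(0, 120)),
    entry("preop_clinical_evaluation", "preop_med_state", "PreopEvaluations",
          "med_state"),
    entry("preop_clinical_evaluation", "preop_date", "PreopEvaluations",
          "eval_date",
          "    clean: {kind: date-normalize, format: '%d.%m.%Y'}"),
    entry("postop_clinical_evaluation", "postop_scale", "PostopEvaluations",
          "scale_name"),
    entry("postop_clinical_evaluation", "postop_score", "PostopEvaluations",
          "score_total", numv(0, 200)),
    entry("postop_clinical_evaluation", "postop_med_state",
          "PostopEvaluations", "med_state"),
    entry("postop_clinical_evaluation", "postop_stim_state",
          "PostopEvaluations", "stim_state"),
    entry("medications", "drug_name", "Medications", "drug_name",
          "    required: true"),
    entry("medications", "dose_mg", "Medications", "dose_mg",
          c("    clean: {kind: decimal-normalize}", numv(0, 5000))),
    entry("medications", "frequency_per_day", "Medications",
          "frequency_per_day", numv(0, 24)),
    entry("imaging_metadata", "visit_type", "Visits", "visit_type"),
    entry("imaging_metadata", "visit_date", "Visits", "visit_date"),
    entry("imaging_metadata", "visit_note", "Visits", "note"),
    entry("targeting_plan", "plan_hemisphere", "TargetingPlans", "hemisphere",
          "    validate: {choices: [left, right]}"),
    entry("targeting_plan", "target_structure", "TargetingPlans",
          "target_structure"),
    entry("targeting_plan", "plan_x", "TargetingPlans", "x_mm", coord),
    entry("targeting_plan", "plan_y", "TargetingPlans", "y_mm", coord),
    entry("targeting_plan", "plan_z", "TargetingPlans", "z_mm", coord),
    entry("targeting_plan", "ring_angle", "ArcSettings", "ring_angle_deg",
          numv(-180, 180)),
    entry("targeting_plan", "arc_angle", "ArcSettings", "arc_angle_deg",
          numv(-180, 180)),
    entry("targeting_plan", "entry_x", "EntryPoints", "x_mm", coord),
    entry("targeting_plan", "entry_y", "EntryPoints", "y_mm", coord),
    entry("targeting_plan", "entry_z", "EntryPoints", "z_mm", coord),
    entry("mer_summary", "mer_hemisphere", "MerSessions", "hemisphere"),
    entry("mer_summary", "mer_n_tracks", "MerSessions", "n_tracks",
          "    validate: {type: integer, min: 1, max: 5}"),
    entry("mer_summary", "track_label", "MerTracks", "track_label"),
    entry("mer_summary", "track_offset_mm", "MerTracks", "offset_mm",
          numv(-10, 10)),
    entry("mer_summary", "mer_depth_mm", "MerRecordings", "depth_mm",
          numv(-15, 15)),
    entry("mer_summary", "activity_pattern", "MerRecordings",
          "activity_pattern"),
    entry("mer_summary", "rms_uv", "MerRecordings", "rms_amplitude_uv",
          numv(0, 500)),
    entry("stimulation_test", "stim_phase", "Stimulations", "stim_phase",
          "    validate: {choices: [intra-op, post-op]}"),
    entry("stimulation_test", "stim_hemisphere", "Stimulations", "hemisphere"),
    entry("stimulation_test", "stim_contact", "Stimulations", "contact",
          "    validate: {type: integer, min: 0, max: 7}"),
    entry("stimulation_test", "amplitude_ma", "Stimulations", "amplitude_ma",
          c("    clean: {kind: decimal-normalize}", numv(0, 10),
            "    required: true")),
    entry("stimulation_test", "pulse_width_us", "Stimulations",
          "pulse_width_us", numv(10, 500)),
    entry("stimulation_test", "frequency_hz", "Stimulations", "frequency_hz",
          numv(0, 300)),
    entry("stimulation_test", "symptom", "StimulationEffects", "symptom"),
    entry("stimulation_test", "score_before", "StimulationEffects",
          "score_before", numv(0, 10)),
    entry("stimulation_test", "score_during", "StimulationEffects",
          "score_during", numv(0, 10)),
    entry("stimulation_test", "side_effect", "StimulationSideEffects",
          "description"),
    entry("stimulation_test", "side_effect_threshold_ma",
          "StimulationSideEffects", "threshold_ma", numv(0, 10)),
    entry("stimulation_test", "protocol_name", "StimulationProtocols",
          "name"),
    entry("implanted_position", "imp_hemisphere", "ImplantedPositions",
          "hemisphere"),
    entry("implanted_position", "electrode_model", "ImplantedPositions",
          "electrode_id", "    required: true"),
    entry("implanted_position", "imp_x", "ImplantedPositions", "x_mm", coord),
    entry("implanted_position", "imp_y", "ImplantedPositions", "y_mm", coord),
    entry("implanted_position", "imp_z", "ImplantedPositions", "z_mm", coord),
    entry("implanted_position", "lead_serial", "ImplantedLeads",
          "lead_serial"),
    entry("implanted_position", "ipg_model", "ImplantedLeads", "ipg_model"),
    entry("postop_screening", "screening_date", "PostopScreenings",
          "screening_date",
          "    clean: {kind: date-normalize, format: '%d.%m.%Y'}"),
    entry("postop_screening", "impedance_ok", "PostopScreenings",
          "impedance_ok"),
    entry("postop_screening", "wound_status", "PostopScreenings",
          "wound_status"),
    entry("postop_screening", "chronic_amplitude_ma", "ChronicSettings",
          "amplitude_ma", c("    clean: {kind: decimal-normalize}",
                            numv(0, 10))),
    entry("postop_screening", "chronic_pulse_width_us", "ChronicSettings",
          "pulse_width_us", numv(10, 500)),
    entry("postop_screening", "chronic_rate_hz", "ChronicSettings",
          "frequency_hz", numv(0, 300)),
    entry("postop_screening", "chronic_mode", "ChronicSettings", "mode"),
    entry("postop_screening", "chronic_contact", "ChronicContacts",
          "contact", "    validate: {type: integer, min: 0, max: 7}"),
    entry("postop_screening", "chronic_polarity", "ChronicContacts",
          "polarity", "    validate: {choices: [cathode, anode]}"))
  paste(lines, collapse = "\n")
}

fixture_export_columns <- function() {
  c("record_id", "redcap_event_name", "redcap_repeat_instrument",
    "redcap_repeat_instance",
    "center", "disease", "sex", "age_at_surgery", "handedness",
    "medical_history", "height_cm", "weight_kg",
    "preop_scale", "preop_score", "preop_motor", "preop_med_state",
    "preop_date",
    "postop_scale", "postop_score", "postop_med_state", "postop_stim_state",
    "drug_name", "dose_mg", "frequency_per_day",
    "visit_type", "visit_date", "visit_note",
    "plan_hemisphere", "target_structure", "plan_x", "plan_y", "plan_z",
    "ring_angle", "arc_angle", "entry_x", "entry_y", "entry_z",
    "mer_hemisphere", "mer_n_tracks", "track_label", "track_offset_mm",
    "mer_depth_mm", "activity_pattern", "rms_uv",
    "stim_phase", "stim_hemisphere", "stim_contact", "amplitude_ma",
    "pulse_width_us", "frequency_hz", "symptom", "score_before",
    "score_during", "side_effect", "side_effect_threshold_ma",
    "protocol_name",
    "imp_hemisphere", "electrode_model", "imp_x", "imp_y", "imp_z",
    "lead_serial", "ipg_model",
    "screening_date", "impedance_ok", "wound_status",
    "chronic_amplitude_ma", "chronic_pulse_width_us", "chronic_rate_hz",
    "chronic_mode", "chronic_contact", "chronic_polarity")
}

write_tiny_nifti <- function(path, fill) {
  vol <- array(fill + seq_len(64) / 100, dim = c(4, 4, 4))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
}

write_sidecar <- function(img_path, fields) {
  jsonlite::write_json(fields,
                       paste0(split_extension(img_path)$stem, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

fixture_electrodes <- function() {
  list(
    list(id = "ELEC3389", manufacturer = "SynthMed", n_contacts = 4,
         length = 1.5, spacing = 0.5, diameter = 1.27),
    list(id = "ELEC2202", manufacturer = "SynthMed", n_contacts = 8,
         length = 1.5, spacing = 0.5, diameter = 1.3)
  )
}

#' Generate a synthetic cohort
#'
#' Writes `export.csv` (REDCap raw longitudinal dialect), `mapping.yaml`,
#' `manifest.csv` and an `images/` staging tree (NIfTI volumes, JSON
#' sidecars, text warp and electrode-model files) under `out`.
#'
#' @param config A [cohort_config()].
#' @param out Output directory (created; must be writable).
#' @return Named list of produced paths (`export`, `mapping`, `manifest`,
#'   `images_dir`) plus the vector of `record_ids`, invisibly classed as
#'   `cohort_manifest`.
#' @export
generate_cohort <- function(config = cohort_config(), out) {
  stopifnot(inherits(config, "cohort_config"))
  ok <- dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("cannot create output directory '", out, "'",
                             call. = FALSE)
  imgdir <- file.path(out, "images")
  dir.create(imgdir, showWarnings = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  centers <- config$centers[((seq_len(n) - 1) %% length(config$centers)) + 1]
  ids <- if (n > 0) {
    sprintf("%ss%dp%03d", centers, config$seed, seq_len(n))
  } else character(0)
  diseases <- if (n > 0) {
    sample(names(config$disease_weights), n, replace = TRUE,
           prob = config$disease_weights)
  } else character(0)

  cols <- fixture_export_columns()
  rows <- list()
  add_row <- function(r) rows[[length(rows) + 1L]] <<- r
  runifr <- function(min, max, digits = 1) num(stats::runif(1, min, max), digits)
  electrodes <- fixture_electrodes()

  for (i in seq_len(n)) {
    id <- ids[i]
    elec <- electrodes[[((i - 1) %% length(electrodes)) + 1]]$id
    # non-repeating demographics row
    r <- blank_row(cols)
    r["record_id"] <- id
    r["redcap_event_name"] <- "enrollment_arm_1"
    r["center"] <- centers[i]
    r["disease"] <- diseases[i]
    r["sex"] <- sample(c("1", "2"), 1)
    r["age_at_surgery"] <- runifr(40, 80)
    r["handedness"] <- sample(c("right", "left"), 1, prob = c(0.9, 0.1))
    r["medical_history"] <- sprintf("synthetic history %d", i)
    r["height_cm"] <- runifr(150, 195, 0)
    r["weight_kg"] <- runifr(50, 110)
    add_row(r)
    rep_row <- function(inst, event, instance = "1") {
      r <- blank_row(cols)
      r["record_id"] <- id
      r["redcap_event_name"] <- event
      r["redcap_repeat_instrument"] <- inst
      r["redcap_repeat_instance"] <- instance
      r
    }
    r <- rep_row("preop_clinical_evaluation", "baseline_arm_1")
    r["preop_scale"] <- if (diseases[i] == "PD") "UPDRS-III" else "ETRS"
    r["preop_score"] <- runifr(20, 80)
    r["preop_motor"] <- runifr(10, 60)
    r["preop_med_state"] <- sample(c("on", "off"), 1)
    r["preop_date"] <- sprintf("%02d.%02d.2023", sample(28, 1), sample(12, 1))
    add_row(r)
    r <- rep_row("postop_clinical_evaluation", "followup_arm_1")
    r["postop_scale"] <- if (diseases[i] == "PD") "UPDRS-III" else "ETRS"
    r["postop_score"] <- runifr(5, 40)
    r["postop_med_state"] <- sample(c("on", "off"), 1)
    r["postop_stim_state"] <- "on"
    add_row(r)
    r <- rep_row("medications", "baseline_arm_1")
    r["drug_name"] <- if (diseases[i] == "PD") "levodopa" else "propranolol"
    r["dose_mg"] <- runifr(50, 600, 0)
    r["frequency_per_day"] <- as.character(sample(1:4, 1))
    add_row(r)
    for (s in seq_along(config$sessions)) {
      r <- rep_row("imaging_metadata", "surgery_arm_1", as.character(s))
      r["visit_type"] <- paste0(config$sessions[s], "-operative imaging")
      r["visit_date"] <- sprintf("2023-%02d-%02d", sample(12, 1), sample(28, 1))
      r["visit_note"] <- "synthetic acquisition"
      add_row(r)
    }
    r <- rep_row("targeting_plan", "surgery_arm_1")
    r["plan_hemisphere"] <- sample(c("left", "right"), 1)
    r["target_structure"] <- if (diseases[i] == "PD") "STN" else "VIM"
    r["plan_x"] <- runifr(-15, 15)
    r["plan_y"] <- runifr(-10, 10)
    r["plan_z"] <- runifr(-12, 0)
    r["ring_angle"] <- runifr(-30, 30)
    r["arc_angle"] <- runifr(-30, 30)
    r["entry_x"] <- runifr(-40, 40)
    r["entry_y"] <- runifr(20, 60)
    r["entry_z"] <- runifr(40, 70)
    add_row(r)
    r <- rep_row("mer_summary", "surgery_arm_1")
    r["mer_hemisphere"] <- sample(c("left", "right"), 1)
    r["mer_n_tracks"] <- as.character(sample(1:5, 1))
    r["track_label"] <- sample(c("central", "anterior", "lateral"), 1)
    r["track_offset_mm"] <- runifr(-2, 2)
    r["mer_depth_mm"] <- runifr(-10, 5)
    r["activity_pattern"] <- sample(c("bursting", "irregular", "tonic"), 1)
    r["rms_uv"] <- runifr(10, 200)
    add_row(r)
    for (inst in 1:2) {
      r <- rep_row("stimulation_test", "surgery_arm_1", as.character(inst))
      r["stim_phase"] <- if (inst == 1) "intra-op" else "post-op"
      r["stim_hemisphere"] <- sample(c("left", "right"), 1)
      r["stim_contact"] <- as.character(sample(0:3, 1))
      r["amplitude_ma"] <- gsub(".", ",", runifr(0.5, 5), fixed = TRUE)
      r["pulse_width_us"] <- runifr(30, 210, 0)
      r["frequency_hz"] <- runifr(60, 180, 0)
      r["symptom"] <- if (diseases[i] == "PD") "rigidity" else "tremor"
      r["score_before"] <- runifr(4, 10)
      r["score_during"] <- runifr(0, 4)
      r["side_effect"] <- sample(c("none", "paresthesia", "dysarthria"), 1)
      r["side_effect_threshold_ma"] <- runifr(3, 8)
      r["protocol_name"] <- "monopolar review"
      add_row(r)
    }
    r <- rep_row("implanted_position", "surgery_arm_1")
    r["imp_hemisphere"] <- sample(c("left", "right"), 1)
    r["electrode_model"] <- elec
    r["imp_x"] <- runifr(-15, 15)
    r["imp_y"] <- runifr(-10, 10)
    r["imp_z"] <- runifr(-12, 0)
    r["lead_serial"] <- sprintf("SN%05d", sample(99999, 1))
    r["ipg_model"] <- "SynthPulse IPG"
    add_row(r)
    r <- rep_row("postop_screening", "followup_arm_1")
    r["screening_date"] <- sprintf("%02d.%02d.2024", sample(28, 1),
                                   sample(12, 1))
    r["impedance_ok"] <- "yes"
    r["wound_status"] <- "healed"
    r["chronic_amplitude_ma"] <- gsub(".", ",", runifr(1, 4), fixed = TRUE)
    r["chronic_pulse_width_us"] <- runifr(30, 210, 0)
    r["chronic_rate_hz"] <- runifr(100, 180, 0)
    r["chronic_mode"] <- "continuous"
    r["chronic_contact"] <- as.character(sample(0:3, 1))
    r["chronic_polarity"] <- "cathode"
    add_row(r)
  }

  export <- if (length(rows) > 0) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    as.data.frame(matrix(character(0), ncol = length(cols),
                         dimnames = list(NULL, cols)),
                  stringsAsFactors = FALSE)
  }
  export_path <- file.path(out, "export.csv")
  utils::write.csv(export, export_path, row.names = FALSE, quote = TRUE,
                   eol = "\n")

  mapping_path <- file.path(out, "mapping.yaml")
  writeLines(fixture_mapping_yaml(), mapping_path)

  # -------- images: staging files + manifest ------------------------------
  man <- list()
  add_img <- function(entry, writer) {
    src <- file.path(imgdir, entry$file)
    writer(src)
    row <- setNames(rep("", length(manifest_columns)), manifest_columns)
    row["source_path"] <- src
    for (nm in intersect(names(entry), manifest_columns)) {
      row[nm] <- entry[[nm]]
    }
    man[[length(man) + 1L]] <<- row
  }
  atlas_t1 <- "sub-ATLAS_ses-v1_T1w.nii.gz"
  add_img(list(file = atlas_t1, subject = "ATLAS", subject_type = "Atlas",
               session = "v1", suffix = "T1w", extension = ".nii.gz",
               category = "anat-raw"),
          function(p) {
            write_tiny_nifti(p, 100)
            write_sidecar(p, list(Modality = "MR",
                                  Description = "synthetic atlas template"))
          })
  add_img(list(file = "sub-ATLAS_ses-v1_dseg.nii.gz", subject = "ATLAS",
               subject_type = "Atlas", session = "v1", suffix = "dseg",
               extension = ".nii.gz", category = "Segmentations",
               structure = "STN"),
          function(p) write_tiny_nifti(p, 1))
  for (e in fixture_electrodes()) {
    add_img(list(file = paste0("sub-", e$id, "_model.txt"), subject = e$id,
                 subject_type = "Electrode", suffix = "model",
                 extension = ".txt", category = "ElectrodeModel"),
            local({ el <- e; function(p) {
              writeLines(c("synthetic electrode model",
                           paste("model:", el$id)), p)
              write_sidecar(p, list(
                Manufacturer = el$manufacturer, NContacts = el$n_contacts,
                ContactLengthMm = el$length, ContactSpacingMm = el$spacing,
                DiameterMm = el$diameter,
                Contacts = lapply(seq_len(el$n_contacts), function(k)
                  list(ContactIndex = k - 1, LengthMm = el$length,
                       PositionMm = (k - 1) * (el$length + el$spacing),
                       SurfaceMm2 = 6.0))))
            }}))
  }
  n_extra <- max(0L, round(config$images_per_patient) - 6L)
  for (i in seq_len(n)) {
    id <- ids[i]
    t1 <- sprintf("sub-%s_ses-pre_acq-ppp_T1w.nii.gz", id)
    warp <- sprintf("sub-%s_ses-pre_xfm.txt", id)
    add_img(list(file = t1, subject = id, subject_type = "Patient",
                 session = "pre", acquisition = "ppp", suffix = "T1w",
                 extension = ".nii.gz", category = "anat-raw"),
            function(p) {
              write_tiny_nifti(p, i)
              write_sidecar(p, list(Modality = "MR",
                                    AcquisitionTime = "08:30:00"))
            })
    for (ses in config$sessions) {
      add_img(list(file = sprintf("sub-%s_ses-%s_CT.nii.gz", id, ses),
                   subject = id, subject_type = "Patient", session = ses,
                   suffix = "CT", extension = ".nii.gz",
                   category = "anat-raw"),
              function(p) {
                write_tiny_nifti(p, i + 10)
                write_sidecar(p, list(Modality = "CT"))
              })
    }
    add_img(list(file = sprintf("sub-%s_ses-pre_dseg.nii.gz", id),
                 subject = id, subject_type = "Patient", session = "pre",
                 suffix = "dseg", extension = ".nii.gz",
                 category = "Segmentations", structure = "STN"),
            function(p) write_tiny_nifti(p, 0))
    add_img(list(file = warp, subject = id, subject_type = "Patient",
                 session = "pre", suffix = "xfm", extension = ".txt",
                 category = "Transforms", target_file = atlas_t1),
            function(p) writeLines(
              c("synthetic affine transform", "1 0 0 0", "0 1 0 0",
                "0 0 1 0", "0 0 0 1"), p))
    add_img(list(file = sprintf("sub-%s_space-v1_ses-pre_acq-ppp_T1w.nii.gz",
                                id),
                 subject = id, subject_type = "Patient", session = "pre",
                 acquisition = "ppp", suffix = "T1w", extension = ".nii.gz",
                 space = "v1", category = "PatientInAtlas",
                 source_file = t1, transform_file = warp),
            function(p) write_tiny_nifti(p, i + 100))
    for (k in seq_len(n_extra)) {
      add_img(list(file = sprintf("sub-%s_ses-pre_acq-extra%d_T2w.nii.gz",
                                  id, k),
                   subject = id, subject_type = "Patient", session = "pre",
                   acquisition = sprintf("extra%d", k), suffix = "T2w",
                   extension = ".nii.gz", category = "anat-raw"),
              function(p) {
                write_tiny_nifti(p, i + 200 + k)
                write_sidecar(p, list(Modality = "MR"))
              })
    }
  }
  manifest <- as.data.frame(do.call(rbind, man), stringsAsFactors = FALSE)
  manifest_path <- file.path(out, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = TRUE,
                   eol = "\n")

  invisible(structure(
    list(export = export_path, mapping = mapping_path,
         manifest = manifest_path, images_dir = imgdir, record_ids = ids),
    class = "cohort_manifest"))
}

#' Count instruments with data per record in an export
#'
#' An instrument counts for a record when at least one of its mapped fields
#' carries a non-empty value in some row of that record.
#'
#' @param records A [parse_redcap_export()] result.
#' @param mapping A [load_mapping()] result.
#' @return Named integer vector: record id -> number of distinct
#'   instruments with data.
#' @export
count_instruments <- function(records, mapping) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  fields_by_inst <- split(
    vapply(mapping$entries, function(e) e$field, character(1)),
    vapply(mapping$entries, function(e) e$instrument, character(1)))
  out <- integer(0)
  for (id in unique(df$record_id)) {
    sub <- df[df$record_id == id, , drop = FALSE]
    k <- 0L
    for (inst in names(fields_by_inst)) {
      flds <- intersect(fields_by_inst[[inst]], names(sub))
      rows <- if (isTRUE(mapping$repeating[[inst]])) {
        sub[sub$redcap_repeat_instrument == inst, , drop = FALSE]
      } else {
        sub[!nzchar(sub$redcap_repeat_instrument), , drop = FALSE]
      }
      if (nrow(rows) > 0 && any(nzchar(unlist(rows[flds])))) k <- k + 1L
    }
    out[id] <- k
  }
  out
}

#' Introduce exactly one deterministic defect into a generated artifact
#'
#' The original artifact is never touched: the corrupted copy is written to
#' `out`.
#'
#' @param artifact Path to a file produced by [generate_cohort()]
#'   (`export.csv` for the CSV modes) or a directory tree (for
#'   `bad-filename`).
#' @param mode One of `bad-coordinate` (first targeting `plan_x` value
#'   becomes `"abc"`), `missing-column` (drops `record_id`),
#'   `duplicate-key` (duplicates the first data row verbatim),
#'   `bad-filename` (renames the first NIfTI in the tree to
#'   `scan1.nii.gz`).
#' @param out Path for the corrupted copy.
#' @return `out`, invisibly.
#' @export
corrupt <- function(artifact, mode, out) {
  mode <- match.arg(mode, c("bad-coordinate", "missing-column",
                            "duplicate-key", "bad-filename"))
  if (mode == "bad-filename") {
    stopifnot(dir.exists(artifact))
    unlink(out, recursive = TRUE)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    ok <- file.copy(list.files(artifact, full.names = TRUE), out,
                    recursive = TRUE)
    stopifnot(all(ok))
    niftis <- sort(list.files(out, pattern = "\\.nii(\\.gz)?$",
                              recursive = TRUE, full.names = TRUE))
    if (length(niftis) == 0) stop("no NIfTI file to rename", call. = FALSE)
    file.rename(niftis[1], file.path(dirname(niftis[1]), "scan1.nii.gz"))
    return(invisible(out))
  }
  df <- utils::read.csv(artifact, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (mode == "bad-coordinate") {
    hit <- which(nzchar(df$plan_x))
    if (length(hit) == 0) stop("no targeting coordinate to corrupt",
                               call. = FALSE)
    df$plan_x[hit[1]] <- "abc"
  } else if (mode == "missing-column") {
    df$record_id <- NULL
  } else if (mode == "duplicate-key") {
    if (nrow(df) == 0) stop("no row to duplicate", call. = FALSE)
    df <- rbind(df, df[1, , drop = FALSE])
  }
  utils::write.csv(df, out, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(out)
}
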