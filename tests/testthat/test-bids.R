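test_that("parsing extracts entities independent of order", {
  n <- parse_bids_name("sub-P001_ses-pre_acq-ppp_T1w.nii.gz")
  expect_equal(n$subject, "P001")
  expect_equal(n$session, "pre")
  expect_equal(n$acquisition, "ppp")
  expect_null(n$space)
  expect_equal(n$suffix, "T1w")
  expect_equal(n$extension, ".nii.gz")

  # entity order in the input does not matter
  m <- parse_bids_name("acq-ppp_sub-P001_ses-pre_T1w.nii.gz")
  expect_equal(format_bids_name(m), format_bids_name(n))

  expect_error(parse_bids_name("T1w.nii.gz"), "sub- entity")
  expect_error(parse_bids_name("sub-P001_ses-pre.nii.gz"), "suffix")
  expect_error(parse_bids_name("sub-P001_T1w.xyz"), "extension")
  expect_warning(parse_bids_name("sub-P001_run-1_T1w.nii.gz"),
                 "unknown entity")
})

test_that("formatting emits the fixed entity order sub, space, ses, acq", {
  x <- bids_name("P001", "T1w", session = "pre", acquisition = "ppp",
                 space = "v1")
  expect_equal(format_bids_name(x),
               "sub-P001_space-v1_ses-pre_acq-ppp_T1w.nii.gz")
  expect_equal(format_bids_name(bids_name("P001", "T1w")),
               "sub-P001_T1w.nii.gz")
  expect_error(bids_name("P001", "T1w", session = "pre_op"), "alphanumeric")
})

test_that("names round-trip both ways under random generation", {
  set.seed(101)
  labels <- function() paste0(sample(c(LETTERS, letters, 0:9), sample(1:6, 1),
                                     replace = TRUE), collapse = "")
  for (k in 1:200) {
    x <- bids_name(
      subject = labels(), suffix = labels(),
      session = if (runif(1) < 0.5) labels(),
      acquisition = if (runif(1) < 0.5) labels(),
      space = if (runif(1) < 0.5) labels(),
      extension = sample(c(".nii.gz", ".nii", ".json", ".h5", ".txt"), 1))
    # parse(format(x)) == x
    expect_equal(parse_bids_name(format_bids_name(x)), x)
    # format(parse(f)) == f
    f <- format_bids_name(x)
    expect_identical(format_bids_name(parse_bids_name(f)), f)
  }
})

test_that("transformed names gain exactly the space entity", {
  src <- parse_bids_name("sub-P001_ses-pre_acq-ppp_T1w.nii.gz")
  d <- derive_transformed_name(src, subject_ref("Atlas", atlas_version = "v1"),
                               "PatientToAtlas")
  expect_equal(format_bids_name(d$name),
               "sub-P001_space-v1_ses-pre_acq-ppp_T1w.nii.gz")
  expect_equal(d$category, "PatientInAtlas")
  # all other entities preserved, entity by entity
  for (ent in c("subject", "session", "acquisition", "suffix", "extension")) {
    expect_identical(d$name[[ent]], src[[ent]], info = ent)
  }

  atl <- parse_bids_name("sub-ATLAS_ses-v1_dseg.nii.gz")
  d2 <- derive_transformed_name(atl, subject_ref("Patient", "P002"),
                                "AtlasToPatient")
  expect_equal(d2$name$space, "P002")
  expect_equal(d2$category, "AtlasInPatient")

  already <- parse_bids_name("sub-P001_space-v1_ses-pre_T1w.nii.gz")
  expect_error(
    derive_transformed_name(already,
                            subject_ref("Atlas", atlas_version = "v2"),
                            "PatientToAtlas"),
    "already")
})

test_that("paths resolve deterministically by subject type and category", {
  p <- subject_ref("Patient", "P001")
  seg <- parse_bids_name("sub-P001_ses-pre_dseg.nii.gz")
  expect_equal(resolve_path(seg, p, "Segmentations"),
               "derivatives/sub-P001/Segmentations/sub-P001_ses-pre_dseg.nii.gz")
  raw <- parse_bids_name("sub-P001_ses-pre_acq-ppp_T1w.nii.gz")
  expect_equal(resolve_path(raw, p, "anat-raw"),
               "sub-P001/ses-pre/anat/sub-P001_ses-pre_acq-ppp_T1w.nii.gz")
  atlas <- subject_ref("Atlas", atlas_version = "v1")
  tmpl <- parse_bids_name("sub-ATLAS_ses-v1_T1w.nii.gz")
  path <- resolve_path(tmpl, atlas, "anat-raw")
  expect_true(startsWith(path, "derivatives/sub-ATLAS/"))
  expect_match(path, "ses-v1")
  # purity: same inputs, same output
  expect_identical(resolve_path(seg, p, "Segmentations"),
                   resolve_path(seg, p, "Segmentations"))
  expect_error(resolve_path(seg, p, "ElectrodeModel"), "not valid")
  expect_error(resolve_path(seg, subject_ref("Patient", "P999"),
                            "Segmentations"), "does not match")
})
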