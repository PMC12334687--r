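test_that("published example filenames parse to the stated entities", {
  p <- parseMrsFilename(
    "sub-06_ses-02_task-nback_acq-slaser_nuc-1H_voi-dlpfc_svs.nii.gz")
  expect_identical(
    entities(p),
    c(sub = "06", ses = "02", task = "nback", acq = "slaser",
      nuc = "1H", voi = "dlpfc"))
  expect_identical(suffix(p), "svs")
  expect_identical(fileExt(p), ".nii.gz")

  for (nm in c("sub-01_acq-concref_mrsref.nii.gz",
               "sub-01_acq-ecc_mrsref.nii.gz")) {
    q <- parseMrsFilename(nm)
    expect_identical(suffix(q), "mrsref")
    expect_identical(entities(q)[["sub"]], "01")
    expect_true(entities(q)[["acq"]] %in% c("concref", "ecc"))
  }

  minimal <- parseMrsFilename("sub-01_svs.nii")
  expect_identical(entities(minimal), c(sub = "01"))
  expect_identical(fileExt(minimal), ".nii")
})

test_that("each grammar violation raises its own error class", {
  cases <- list(
    list("sub-01_sub-01_svs.nii.gz",        "mrsbids_DuplicateEntity"),
    list("sub-01_foo-bar_svs.nii.gz",       "mrsbids_UnknownEntity"),
    list("sub-01_nuc-1H_acq-slaser_svs.nii", "mrsbids_OrderViolation"),
    list("sub-01_voi-dl.pfc_svs.nii",       "mrsbids_BadLabel"),
    list("sub-01_run-1a_svs.nii",           "mrsbids_BadIndex"),
    list("sub-01_acq-test.nii.gz",          "mrsbids_MissingSuffix"),
    list("sub-01_spectrum.nii.gz",          "mrsbids_UnknownSuffix"),
    list("sub-01_svs.nii.bz2",              "mrsbids_UnknownExtension"),
    list("ses-01_sub-01_svs.nii",           "mrsbids_MissingSubject"),
    list("svs.nii",                         "mrsbids_MissingSubject"))
  for (case in cases)
    expect_error(parseMrsFilename(case[[1]]), class = case[[2]])
})

test_that("minimal edits of a valid name hit exactly the targeted class", {
  valid <- "sub-01_acq-ecc_run-1_svs.nii"
  expect_s4_class(parseMrsFilename(valid), "MrsFilename")
  singleChar <- list(
    list(sub("acq", "aqq", valid),   "mrsbids_UnknownEntity"),
    list(sub("ecc", "e.c", valid),   "mrsbids_BadLabel"),
    list(sub("run-1", "run-x", valid), "mrsbids_BadIndex"),
    list(sub("svs", "s-s", valid),   "mrsbids_MissingSuffix"),
    list(sub("svs", "svz", valid),   "mrsbids_UnknownSuffix"),
    list(sub("nii", "nji", valid),   "mrsbids_UnknownExtension"))
  for (case in singleChar) {
    expect_equal(as.integer(adist(case[[1]], valid)[1, 1]), 1L)
    expect_error(parseMrsFilename(case[[1]]), class = case[[2]])
  }
  # the remaining classes need token-level edits
  expect_error(parseMrsFilename("sub-01_acq-ecc_acq-ecc_run-1_svs.nii"),
               class = "mrsbids_DuplicateEntity")
  expect_error(parseMrsFilename("sub-01_run-1_acq-ecc_svs.nii"),
               class = "mrsbids_OrderViolation")
  expect_error(parseMrsFilename("acq-ecc_run-1_svs.nii"),
               class = "mrsbids_MissingSubject")
})

test_that("build emits canonical order and round-trips through parse", {
  expect_identical(
    buildMrsFilename(c(sub = "01", acq = "ecc"), "mrsref", ".nii.gz"),
    "sub-01_acq-ecc_mrsref.nii.gz")
  # input order is irrelevant
  expect_identical(
    buildMrsFilename(c(voi = "dlpfc", sub = "06", nuc = "1H"), "svs", ".nii"),
    buildMrsFilename(c(sub = "06", nuc = "1H", voi = "dlpfc"), "svs", ".nii"))

  withr::with_seed(421, {
    for (i in 1:200) {
      e <- randomEntitySet(); s <- randomSuffix(); x <- randomExtension()
      name <- buildMrsFilename(e, s, x)
      p <- parseMrsFilename(name)
      expect_identical(entities(p), e[order(match(names(e),
                                                  entityDescriptors()$key))])
      expect_identical(suffix(p), s)
      expect_identical(fileExt(p), x)
      # and the parsed object formats back to the same string
      expect_identical(format(p), name)
    }
  })
})

test_that("leading zeros are preserved verbatim but collide as integers", {
  a <- parseMrsFilename("sub-01_run-01_svs.nii")
  b <- parseMrsFilename("sub-01_run-1_svs.nii")
  expect_identical(entities(a)[["run"]], "01")
  expect_false(identical(entities(a), entities(b)))
  expect_identical(mrsbids:::collisionKey(a), mrsbids:::collisionKey(b))
})

test_that("expected relative paths include the session level only when present", {
  withSes <- parseMrsFilename(
    "sub-06_ses-02_task-nback_acq-slaser_nuc-1H_voi-dlpfc_svs.nii.gz")
  expect_identical(expectedRelativePath(withSes), "sub-06/ses-02/mrs/")
  expect_identical(expectedRelativePath(parseMrsFilename("sub-01_svs.nii")),
                   "sub-01/mrs/")
})

test_that("lenient parsing re-sorts out-of-order entities with a warning", {
  expect_warning(
    p <- parseMrsFilename("sub-01_nuc-1H_acq-slaser_svs.nii", lenient = TRUE),
    class = "mrsbids_OrderViolation")
  expect_identical(names(entities(p)), c("sub", "acq", "nuc"))
})
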