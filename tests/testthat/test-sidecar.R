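test_that("the field catalog covers exactly the documented field set", {
  documented <- c(
    # MRS-relevant, required
    "ResonantNucleus", "SpectrometerFrequency", "SpectralWidth", "EchoTime",
    # recommended
    "WaterSuppression", "NumberOfSpectralPoints", "MixingTime",
    "AcquisitionVoxelSize", "ReferenceSignal", "NumberOfTransients",
    "MatrixSize", "VolumeAffineMatrix", "EncodingTechnique",
    "AnatomicalImage",
    # scanner hardware
    "NumberReceiveCoilActiveElements", "NumberTransmitCoilActiveElements",
    # sequence specifics
    "WaterSuppressionTechnique", "OuterVolumeSuppression",
    "B0ShimmingTechnique", "B1ShimmingTechnique",
    # tissue description
    "BodyPart", "BodyPartDetails", "BodyPartDetailsOntology",
    # further optional fields
    "ChemicalShiftOffset", "ChemicalShiftReference", "EditTarget",
    "EditPulse", "EditCondition", "EchoAcquisition", "PulseSequenceTiming",
    "PulseSequencePulses", "ReceiveGain", "PulseSequenceType")
  expect_setequal(sidecarCatalog()$name, documented)
  expect_false(anyDuplicated(sidecarCatalog()$name) > 0)

  avs <- fieldSpec("AcquisitionVoxelSize")
  expect_identical(avs$value_type, "number_array")
  expect_identical(avs$shape, 3L)
  expect_identical(avs$units, "mm")
  vam <- fieldSpec("VolumeAffineMatrix")
  expect_identical(vam$value_type, "square_matrix")
  expect_identical(vam$shape, 4L)
  expect_identical(fieldSpec("EchoTime")$level, "required")
  expect_identical(fieldSpec("NumberOfTransients")$applicability, "svs,unloc")
})

test_that("a well-typed required set yields warnings only", {
  v <- validateSidecar(docFor(minimalRequired()))
  expect_identical(nrow(errorsOf(v)), 0L)
  # the applicable recommended fields are reported absent
  expect_true(all(warningsOf(v)$rule_id == "MRS202"))
  expect_true("WaterSuppression" %in% warningsOf(v)$location)
  # NumberOfTransients applies to svs, MatrixSize does not
  expect_true("NumberOfTransients" %in% warningsOf(v)$location)
  expect_false("MatrixSize" %in% warningsOf(v)$location)
})

test_that("missing required fields and malformed values are errors", {
  noEcho <- minimalRequired(); noEcho$EchoTime <- NULL
  v <- validateSidecar(docFor(noEcho))
  expect_identical(errorsOf(v)$rule_id, "MRS201")
  expect_identical(errorsOf(v)$location, "EchoTime")

  ws <- c(minimalRequired(), list(WaterSuppression = "yes"))
  expect_identical(errorsOf(validateSidecar(docFor(ws)))$rule_id, "MRS203")

  avs <- c(minimalRequired(), list(AcquisitionVoxelSize = c(20, 20)))
  expect_identical(errorsOf(validateSidecar(docFor(avs)))$rule_id, "MRS204")

  neg <- minimalRequired(); neg$SpectralWidth <- -2000
  expect_identical(errorsOf(validateSidecar(docFor(neg)))$rule_id, "MRS205")

  uri <- c(minimalRequired(), list(BodyPartDetailsOntology = "not a uri"))
  expect_identical(errorsOf(validateSidecar(docFor(uri)))$rule_id, "MRS309")
})

test_that("only the mandated array shapes are accepted", {
  for (len in 2:5) {
    v <- validateSidecar(docFor(c(minimalRequired(),
                                  list(AcquisitionVoxelSize = rep(20, len)))))
    expect_identical(nrow(errorsOf(v)) == 0L, len == 3L)
  }
  mrsiName <- "sub-01_acq-epsi_mrsi.nii.gz"
  for (len in 2:5) {
    v <- validateSidecar(docFor(c(minimalRequired(),
                                  list(MatrixSize = rep(8L, len))),
                                name = mrsiName))
    expect_identical(nrow(errorsOf(v)) == 0L, len == 3L)
  }
  for (n in 2:5) {
    v <- validateSidecar(docFor(c(minimalRequired(),
                                  list(VolumeAffineMatrix = diag(n))),
                                name = mrsiName))
    expect_identical(nrow(errorsOf(v)) == 0L, n == 4L)
  }
})

test_that("unknown keys are notices and absent optional fields are silent", {
  v <- validateSidecar(docFor(c(minimalRequired(),
                                list(MyCustomNote = "hello"))))
  noteRows <- v[v$location == "MyCustomNote", ]
  expect_identical(noteRows$rule_id, "MRS206")
  expect_identical(noteRows$severity, "info")
  # no issue mentions any absent optional field
  expect_false(any(v$location %in% c("BodyPart", "ReceiveGain", "EditTarget")))
})

test_that("entity-conditional requirements follow the mandated severities", {
  voiName <- "sub-01_nuc-1H_voi-dlpfc_svs.nii.gz"
  base <- minimalRequired()

  cc <- checkConditionalRequirements(docFor(base, name = voiName))
  expect_setequal(errorsOf(cc)$rule_id, c("MRS303", "MRS304"))

  ok <- c(base, list(BodyPart = "BRAIN", BodyPartDetails = "dlPFC"))
  expect_identical(nrow(checkConditionalRequirements(docFor(ok, name = voiName))),
                   0L)

  # nuc label vs ResonantNucleus, including the dual-tuned array encoding
  mism <- base; mism$ResonantNucleus <- "31P"
  cc <- checkConditionalRequirements(docFor(mism, "sub-01_nuc-1H_svs.nii.gz"))
  expect_identical(cc$rule_id, "MRS302")
  noRn <- base; noRn$ResonantNucleus <- NULL
  cc <- checkConditionalRequirements(docFor(noRn, "sub-01_nuc-1H_svs.nii.gz"))
  expect_identical(cc$rule_id, "MRS301")
  dual <- base; dual$ResonantNucleus <- c("1H", "13C")
  cc <- checkConditionalRequirements(docFor(dual, "sub-01_nuc-1H13C_svs.nii.gz"))
  expect_identical(nrow(cc), 0L)

  # acq without PulseSequenceType is a warning
  cc <- checkConditionalRequirements(docFor(base,
                                            "sub-01_acq-slaser_svs.nii.gz"))
  expect_identical(cc$rule_id, "MRS305")
  expect_identical(cc$severity, "warning")

  # pulse list must pair with an equal-length timing array
  p3t2 <- c(base, list(PulseSequencePulses = c("a", "b", "c"),
                       PulseSequenceTiming = c(0, 0.01)))
  cc <- checkConditionalRequirements(docFor(p3t2))
  expect_identical(cc$rule_id, "MRS306")
  expect_identical(cc$severity, "error")

  # MRSI recommendations and the transients notice
  mrsiDoc <- docFor(c(base, list(NumberOfTransients = 64)),
                    "sub-01_acq-epsi_mrsi.nii.gz")
  cc <- checkConditionalRequirements(mrsiDoc)
  expect_setequal(cc$rule_id[cc$severity == "warning"],
                  c("MRS305", "MRS307"))
  expect_setequal(cc$location[cc$rule_id == "MRS307"],
                  c("MatrixSize", "VolumeAffineMatrix", "EncodingTechnique"))
  expect_identical(cc$rule_id[cc$severity == "info"], "MRS308")
})

test_that("inheritance merging is specific-wins, deterministic and idempotent", {
  root <- sidecarDocument(list(SpectrometerFrequency = 123.25,
                               EchoTime = 0.02), sourcePaths = "root.json")
  leaf <- sidecarDocument(list(EchoTime = 0.03), sourcePaths = "leaf.json")
  m <- mergeInherited(list(root, leaf))
  expect_identical(sidecarContent(m)$EchoTime, 0.03)
  expect_identical(sidecarContent(m)$SpectrometerFrequency, 123.25)
  expect_identical(m@sourcePaths, c("root.json", "leaf.json"))

  withr::with_seed(99, {
    for (i in 1:25) {
      keys <- sample(sidecarCatalog()$name, 6)
      a <- sidecarDocument(setNames(as.list(runif(4)), sample(keys, 4)))
      b <- sidecarDocument(setNames(as.list(runif(4)), sample(keys, 4)))
      once <- mergeInherited(list(a, b))
      twice <- mergeInherited(list(once, b))
      expect_identical(sidecarContent(twice), sidecarContent(once))
    }
  })
})

test_that("validation output is deterministic for identical input", {
  doc <- docFor(c(minimalRequired(), list(WaterSuppression = TRUE)))
  expect_identical(validateSidecar(doc), validateSidecar(doc))
  expect_identical(checkConditionalRequirements(doc),
                   checkConditionalRequirements(doc))
})

test_that("malformed sidecar files raise a distinct condition", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(readSidecar(bad), class = "mrsbids_MalformedDocument")
})
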