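test_that("a generated dataset is inventoried and passes validation", {
  root <- localDataset(nSubjects = 2, sessionsPerSubject = 1, nPoints = 128,
                       seed = 7)
  inv <- scanDataset(root)
  # 2 subjects x 1 session x (svs + mrsref)
  expect_identical(length(inv@subjects), 2L)
  expect_identical(nrow(dataFiles(inv)), 4L)
  expect_identical(length(inv@sidecars), 4L)
  expect_true(inv@hasDatasetDescription)

  rep <- validateDataset(root)
  expect_true(passed(rep))
  expect_identical(nrow(issues(rep)), 0L)
})

test_that("an empty directory yields an empty inventory", {
  root <- withr::local_tempdir()
  inv <- scanDataset(root)
  expect_identical(nrow(dataFiles(inv)), 0L)
  expect_identical(length(inv@subjects), 0L)
  expect_false(inv@hasDatasetDescription)
  expect_error(scanDataset(tempfile()), class = "mrsbids_NotADirectory")
})

test_that(".bidsignore excludes stray files from the inventory", {
  root <- localDataset(nSubjects = 1, nPoints = 64, seed = 3)
  stray <- file.path(root, "sub-01", "ses-01", "mrs", "notes.nii")
  writeLines("junk", stray)
  # without the ignore entry the stray file draws a grammar issue
  expect_false(passed(validateDataset(root)))
  writeLines("notes.nii", file.path(root, ".bidsignore"))
  inv <- scanDataset(root)
  expect_false(any(grepl("notes", dataFiles(inv)$path)))
  expect_true(passed(validateDataset(root)))
})

test_that("sourcedata and derivatives trees are not validated", {
  root <- localDataset(nSubjects = 1, nPoints = 64, seed = 5)
  dir.create(file.path(root, "sourcedata"), showWarnings = FALSE)
  writeLines("raw vendor dump", file.path(root, "sourcedata", "scan.nii"))
  expect_true(passed(validateDataset(root)))
})

test_that("a file placed outside its entity-implied path is flagged", {
  root <- localDataset(nSubjects = 1, sessionsPerSubject = 1, nPoints = 64,
                       seed = 9)
  rec <- dataFiles(scanDataset(root))[1, ]
  # move the file (and sidecar) up one level: name says ses-01, path does not
  badDir <- file.path(root, rec$subDir, "mrs")
  dir.create(badDir, recursive = TRUE)
  file.rename(file.path(root, rec$path),
              file.path(badDir, basename(rec$path)))
  file.rename(file.path(root, rec$sidecar),
              file.path(badDir, basename(rec$sidecar)))
  rep <- validateDataset(root)
  expect_true("MRS110" %in% issues(rep)$rule_id)
})

test_that("root-level fragments inherit downward but never override the file sidecar", {
  root <- localDataset(nSubjects = 1, nPoints = 64, seed = 13)
  # applies: same suffix, entity subset
  writeLines('{"ChemicalShiftReference": 4.68, "EchoTime": 99}',
             file.path(root, "nuc-1H_svs.json"))
  rep <- validateDataset(root)
  expect_true(passed(rep))  # the fragment adds a valid optional field
  rec <- dataFiles(scanDataset(root))
  svsRec <- rec[grepl("_svs\\.nii\\.gz$", rec$path), ][1, ]
  parsed <- parseMrsFilename(basename(svsRec$path))
  frags <- mrsbids:::inheritanceSources(root, svsRec, parsed)
  merged <- mergeInherited(c(frags, list(readSidecar(
    file.path(root, svsRec$sidecar), context = parsed))))
  expect_identical(sidecarContent(merged)$ChemicalShiftReference, 4.68)
  expect_identical(sidecarContent(merged)$EchoTime, 0.03)  # file level wins

  # a fragment for a different suffix is not merged
  mrsrefRec <- rec[grepl("_mrsref\\.nii\\.gz$", rec$path), ][1, ]
  parsedRef <- parseMrsFilename(basename(mrsrefRec$path))
  fragsRef <- mrsbids:::inheritanceSources(root, mrsrefRec, parsedRef)
  expect_identical(length(fragsRef), 0L)
})

test_that("validation reports are deterministic and survive a tree copy", {
  root <- localDataset(nSubjects = 1, nPoints = 64, seed = 21)
  applyMutation(root, "missing_echotime")
  r1 <- validateDataset(root)
  r2 <- validateDataset(root)
  expect_identical(issues(r1), issues(r2))
  expect_identical(renderReport(r1, "json"), renderReport(r2, "json"))

  copy <- tempfile("copy-")
  withr::defer(unlink(copy, recursive = TRUE))
  dir.create(copy)
  file.copy(list.files(root, full.names = TRUE), copy, recursive = TRUE)
  file.copy(file.path(root, ".bidsignore"), copy)  # may not exist; harmless
  r3 <- validateDataset(copy)
  expect_identical(issues(r3), issues(r1))  # paths are dataset-relative
})

test_that("strict mode errors are a superset of normal-mode errors", {
  root <- localDataset(nSubjects = 1, nPoints = 64, seed = 31)
  # introduce one warning (drop a recommended field) and one error
  applyMutation(root, "missing_echotime")
  rec <- dataFiles(scanDataset(root))[1, ]
  mrsbids:::editSidecar(root, rec$sidecar,
                        function(x) { x$WaterSuppression <- NULL; x })
  normal <- validateDataset(root)
  strict <- validateDataset(root, strict = TRUE)
  normErr <- with(issues(normal), paste(rule_id, file, location)[severity == "error"])
  strictErr <- with(issues(strict), paste(rule_id, file, location)[severity == "error"])
  expect_true(all(normErr %in% strictErr))
  expect_gt(length(strictErr), length(normErr))
})

test_that("rule ids can be disabled via configuration", {
  root <- localDataset(nSubjects = 1, nPoints = 64, seed = 41)
  applyMutation(root, "missing_echotime")
  expect_false(passed(validateDataset(root)))
  expect_true(passed(validateDataset(root, disabledRules = "MRS201")))
})

test_that("orphan sidecars draw a warning, not an error", {
  root <- localDataset(nSubjects = 1, nPoints = 64, seed = 51)
  rec <- dataFiles(scanDataset(root))[1, ]
  orphan <- file.path(root, dirname(rec$path), "sub-01_run-9_svs.json")
  writeLines('{"EchoTime": 0.03}', orphan)
  rep <- validateDataset(root)
  expect_true(passed(rep))
  orphanRows <- issues(rep)[issues(rep)$rule_id == "MRS503", ]
  expect_identical(nrow(orphanRows), 1L)
  expect_identical(orphanRows$severity, "warning")
})

test_that("duplicate acquisition identities collide across index spellings", {
  root <- localDataset(nSubjects = 1, sessionsPerSubject = 0, nPoints = 64,
                       seed = 61)
  rec <- dataFiles(scanDataset(root))
  svsRec <- rec[grepl("_svs\\.nii\\.gz$", rec$path), ][1, ]
  dir <- file.path(root, dirname(svsRec$path))
  base <- sub("_svs\\.nii\\.gz$", "", basename(svsRec$path))
  # run-1 and run-01 denote the same nonnegative integer
  for (runVal in c("1", "01")) {
    nm <- paste0(sub("(sub-[^_]+)", paste0("\\1"), base), "_rec-a_run-", runVal,
                 "_svs.nii.gz")
    file.copy(file.path(root, svsRec$path), file.path(dir, nm))
    file.copy(file.path(root, svsRec$sidecar),
              file.path(dir, sub("\\.nii\\.gz$", ".json", nm)))
  }
  rep <- validateDataset(root)
  expect_identical(sum(issues(rep)$rule_id == "MRS504"), 1L)
})

test_that("reports render to text and JSON with stable content", {
  root <- localDataset(nSubjects = 1, nPoints = 64, seed = 71)
  good <- validateDataset(root)
  txt <- renderReport(good, "text")
  expect_match(txt, "Result: pass")
  expect_match(txt, "0 error\\(s\\)")

  applyMutation(root, "watersuppression_string")
  applyMutation(root, "missing_echotime")
  bad <- validateDataset(root)
  txt <- renderReport(bad, "text")
  expect_match(txt, "2 error\\(s\\)")
  expect_match(txt, "Result: fail")

  parsed <- jsonlite::fromJSON(renderReport(bad, "json"),
                               simplifyDataFrame = TRUE)
  expect_identical(nrow(parsed$issues), nrow(issues(bad)))
  expect_false(parsed$passed)
  expect_error(renderReport(bad, "yaml"), class = "mrsbids_UnknownFormat")
})
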