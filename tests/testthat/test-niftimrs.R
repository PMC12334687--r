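test_that("write/read round-trips values, geometry and metadata exactly", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  withr::with_seed(7, {
    fid <- complex(real = rnorm(64), imaginary = rnorm(64))
  })
  x <- niftiMrs(array(fid, c(1, 1, 1, 64)), dwellTime = 5e-4,
                headerExt = list(SpectrometerFrequency = 123.25,
                                 ResonantNucleus = "1H"))
  writeNiftiMrs(x, path)
  y <- readNiftiMrs(path)
  expect_identical(dims(y), c(1L, 1L, 1L, 64L, 1L, 1L, 1L))
  expect_identical(dwellTime(y), 5e-4)
  expect_identical(headerExt(y),
                   list(SpectrometerFrequency = 123.25, ResonantNucleus = "1H"))
  expect_identical(as.vector(spectralData(y)), fid)
  expect_identical(mrsHeader(y)@intentLabel, "mrs_v0_2")
  expect_true(mrsHeader(y)@hasExtension)
})

test_that("zero-filled data is stored exactly and beyond header size", {
  path <- withr::local_tempfile(fileext = ".nii")
  x <- niftiMrs(array(0 + 0i, c(1, 1, 1, 4, 1, 1, 1)), dwellTime = 5e-4,
                headerExt = list(ResonantNucleus = "1H"))
  writeNiftiMrs(x, path)
  expect_gt(file.size(path), 348)  # NIfTI-1 header alone is 348 bytes
  y <- readNiftiMrs(path)
  expect_true(all(spectralData(y) == 0 + 0i))
})

test_that("trailing singleton axes do not change the stored data", {
  pathA <- withr::local_tempfile(fileext = ".nii.gz")
  pathB <- withr::local_tempfile(fileext = ".nii.gz")
  fid <- complex(real = 1:8, imaginary = 8:1)
  writeNiftiMrs(niftiMrs(array(fid, c(1, 1, 1, 8)), dwellTime = 1e-3), pathA)
  writeNiftiMrs(niftiMrs(array(fid, c(1, 1, 1, 8, 1, 1, 1)),
                         dwellTime = 1e-3), pathB)
  a <- readNiftiMrs(pathA); b <- readNiftiMrs(pathB)
  expect_identical(dims(a), dims(b))
  expect_identical(spectralData(a), spectralData(b))
})

test_that("random complex blocks round-trip element-wise", {
  withr::with_seed(11, {
    for (i in 1:40) {
      d <- c(sample(1:3, 3, replace = TRUE), sample(2:32, 1))
      vals <- complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d)))
      path <- tempfile(fileext = ".nii.gz")
      writeNiftiMrs(niftiMrs(array(vals, d), dwellTime = 5e-4), path)
      y <- readNiftiMrs(path)
      expect_identical(as.vector(spectralData(y)), vals)
      unlink(path)
    }
  })
})

test_that("a plain anatomical NIfTI reads back with no extension, flagged", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4))), path)
  y <- readNiftiMrs(path)
  expect_false(mrsHeader(y)@hasExtension)
  expect_identical(headerExt(y), list())
  expect_identical(dims(y), c(4L, 4L, 4L, 1L, 1L, 1L, 1L))
})

test_that("unreadable files and dimension overflow raise classed errors", {
  bad <- withr::local_tempfile(fileext = ".nii")
  writeLines("definitely not nifti", bad)
  expect_error(readNiftiMrs(bad), class = "mrsbids_NotNifti")
  expect_error(readNiftiMrs(tempfile(fileext = ".nii")),
               class = "mrsbids_NotNifti")
  expect_error(niftiMrs(array(1 + 0i, rep(2, 8)), dwellTime = 1e-3),
               class = "mrsbids_DimOverflow")
})

test_that("container/sidecar coherence rules fire at the right severities", {
  mk <- function(dims, dwell, ext = list(SpectrometerFrequency = 123.25,
                                         ResonantNucleus = "1H")) {
    niftiMrsHeader(dims, dwellTime = dwell, headerExt = ext)
  }
  svsDoc <- function(extra = list())
    docFor(c(minimalRequired(), extra), "sub-01_svs.nii.gz")

  # exact reciprocal: consistent
  cc <- consistencyCheck(mk(c(1, 1, 1, 2048), 5e-4), svsDoc())
  expect_identical(nrow(cc), 0L)

  # 20% off: error
  hdr <- mk(c(1, 1, 1, 2048), 5e-4)
  doc25 <- docFor(modifyList(minimalRequired(), list(SpectralWidth = 2500)),
                  "sub-01_svs.nii.gz")
  cc <- consistencyCheck(hdr, doc25)
  expect_identical(cc$rule_id, "MRS403")
  expect_identical(cc$severity, "error")

  # nucleus disagreement between header extension and sidecar: warning
  hdrP <- mk(c(1, 1, 1, 2048), 5e-4,
             ext = list(SpectrometerFrequency = 123.25,
                        ResonantNucleus = "31P"))
  cc <- consistencyCheck(hdrP, svsDoc())
  expect_identical(cc$rule_id, "MRS404")
  expect_identical(cc$severity, "warning")

  # spectral-point count disagreement: warning
  cc <- consistencyCheck(mk(c(1, 1, 1, 1024), 5e-4),
                         svsDoc(list(NumberOfSpectralPoints = 2048L)))
  expect_identical(cc$rule_id, "MRS405")

  # spatial extents against the suffix
  cc <- consistencyCheck(mk(c(2, 1, 1, 2048), 5e-4), svsDoc())
  expect_identical(cc$rule_id, "MRS406")
  expect_identical(cc$severity, "error")
  mrsiDoc <- docFor(minimalRequired(), "sub-01_mrsi.nii.gz")
  cc <- consistencyCheck(mk(c(1, 1, 1, 2048), 5e-4), mrsiDoc)
  expect_identical(cc$rule_id, "MRS407")
  expect_identical(cc$severity, "warning")

  # missing embedded extension: warning
  cc <- consistencyCheck(niftiMrsHeader(c(1, 1, 1, 2048), 5e-4), svsDoc())
  expect_identical(cc$rule_id, "MRS402")
})
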