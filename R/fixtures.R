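## Default simulated metabolite components: three singlet-like peaks at the
## usual proton chemical shifts (NAA 2.01, Cr 3.03, Cho 3.20 ppm) expressed
## as frequency offsets from water (4.68 ppm) at the given field.
defaultMetabolites <- function(spectrometerFrequency = 123.25) {
  data.frame(amplitude = c(1.0, 0.9, 0.7),
             freqOffsetHz = (c(2.01, 3.03, 3.20) - 4.68) * spectrometerFrequency,
             t2 = c(0.25, 0.18, 0.22))
}

#' Specify a synthetic MRS-BIDS dataset
#'
#' Builds a [FixtureSpec-class] with study-level defaults: a two-subject,
#' one-session cohort acquiring a single-voxel sLASER-like spectrum plus a
#' water reference per session, simulated as a common 3T proton exam
#' (spectrometer frequency 123.25 MHz, spectral width 2000 Hz, 2048 complex
#' points, three metabolite peaks, additive complex Gaussian noise). When
#' \code{mrsiMatrix} is given, an MRSI acquisition is added.
#'
#' @param nSubjects Number of subjects (>= 1).
#' @param sessionsPerSubject Sessions per subject; 0 omits the session
#'   level entirely.
#' @param kinds Optional list of kind descriptors
#'   (\code{list(suffix = , entities = )}); \code{NULL} selects the default
#'   svs + mrsref (+ mrsi) set.
#' @param spectrometerFrequency In MHz.
#' @param spectralWidth In Hz.
#' @param nPoints Complex time-domain samples (>= 2).
#' @param metabolites Signal components; see [generateFid()].
#' @param noiseSd Noise standard deviation.
#' @param mrsiMatrix Length-3 spatial matrix size for the MRSI kind, or
#'   \code{NULL}.
#' @param seed Integer seed fixing all randomness in the generated data.
#' @param includeAnat Write a small anatomical image per subject and
#'   reference it via \code{AnatomicalImage}.
#' @return A [FixtureSpec-class].
#' @examples
#' fixtureSpec(nSubjects = 1, seed = 7)
#' @seealso [generateDataset()]
#' @export
fixtureSpec <- function(nSubjects = 2, sessionsPerSubject = 1, kinds = NULL,
                        spectrometerFrequency = 123.25, spectralWidth = 2000,
                        nPoints = 2048,
                        metabolites = defaultMetabolites(spectrometerFrequency),
                        noiseSd = 0.05, mrsiMatrix = NULL, seed = 1,
                        includeAnat = TRUE) {
  if (is.null(kinds)) {
    kinds <- list(
      list(suffix = "svs",
           entities = c(acq = "slaser", nuc = "1H", voi = "pcc")),
      list(suffix = "mrsref", entities = c(acq = "concref")))
    if (!is.null(mrsiMatrix))
      kinds <- c(kinds, list(list(suffix = "mrsi",
                                  entities = c(acq = "epsi", nuc = "1H"))))
  }
  new("FixtureSpec",
      nSubjects = as.integer(nSubjects),
      sessionsPerSubject = as.integer(sessionsPerSubject),
      kinds = kinds,
      spectrometerFrequency = as.numeric(spectrometerFrequency),
      spectralWidth = as.numeric(spectralWidth),
      nPoints = as.integer(nPoints),
      metabolites = metabolites,
      noiseSd = as.numeric(noiseSd),
      mrsiMatrix = as.integer(mrsiMatrix %||% integer(0)),
      seed = as.integer(seed),
      includeAnat = isTRUE(includeAnat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic sidecar serialization: keys sorted, fixed formatting.
writeSidecarJson <- function(content, path) {
  content <- content[order(names(content), method = "radix")]
  txt <- jsonlite::toJSON(content, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  writeLines(as.character(txt), path, useBytes = TRUE)
}

.PULSE_SEQ_NAMES <- c(slaser = "sLASER", press = "PRESS", steam = "STEAM",
                      epsi = "EPSI", concref = "sLASER water reference",
                      ecc = "sLASER water reference")

.VOI_DETAILS <- c(pcc = "posterior cingulate cortex",
                  acc = "anterior cingulate cortex",
                  dlpfc = "dorsolateral prefrontal cortex")

#' Generate a synthetic MRS-BIDS dataset
#'
#' Writes a complete, valid-by-construction dataset to \code{outRoot}:
#' \code{dataset_description.json}, \code{participants.tsv}, per-subject
#' (and per-session) \code{mrs/} trees with NIfTI-MRS data files (written
#' through [writeNiftiMrs()], so each carries the embedded JSON header
#' extension and the dwell time matching the spectral width) and sidecars
#' holding every required and applicable recommended field. Single-voxel
#' and MRSI sidecars point their \code{ReferenceSignal} at the generated
#' water reference and, when enabled, \code{AnatomicalImage} at a small
#' anatomical image under \code{anat/}. [validateDataset()] on the result
#' passes with zero errors; sidecar bytes are identical across runs with
#' the same spec and seed.
#'
#' @param spec A [FixtureSpec-class].
#' @param outRoot Output directory (created if needed).
#' @return The [DatasetInventory-class] of the written tree, invisibly.
#' @examples
#' \donttest{
#' root <- file.path(tempdir(), "ds-example")
#' inv <- generateDataset(fixtureSpec(nSubjects = 1, seed = 7), root)
#' passed(validateDataset(root))
#' }
#' @export
generateDataset <- function(spec, outRoot) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  dir.create(outRoot, recursive = TRUE, showWarnings = FALSE)
  writeSidecarJson(list(Name = "mrsbids synthetic example dataset",
                        BIDSVersion = "1.9.0", DatasetType = "raw"),
                   file.path(outRoot, "dataset_description.json"))
  subs <- sprintf("%02d", seq_len(spec@nSubjects))
  writeLines(c("participant_id", paste0("sub-", subs)),
             file.path(outRoot, "participants.tsv"), useBytes = TRUE)

  fileCounter <- 0L
  sessions <- if (spec@sessionsPerSubject > 0L)
    sprintf("%02d", seq_len(spec@sessionsPerSubject)) else NA_character_

  for (sub in subs) {
    anatRel <- NULL
    if (spec@includeAnat) {
      anatDir <- file.path(outRoot, paste0("sub-", sub), "anat")
      dir.create(anatDir, recursive = TRUE, showWarnings = FALSE)
      anatRel <- file.path(paste0("sub-", sub), "anat",
                           paste0("sub-", sub, "_T1w.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(array(0, c(4L, 4L, 4L))),
                         file.path(outRoot, anatRel))
    }
    for (ses in sessions) {
      base <- c(sub = sub)
      relDir <- paste0("sub-", sub, "/")
      if (!is.na(ses)) {
        base <- c(base, ses = ses)
        relDir <- paste0(relDir, "ses-", ses, "/")
      }
      relDir <- paste0(relDir, "mrs/")
      dir.create(file.path(outRoot, relDir), recursive = TRUE,
                 showWarnings = FALSE)

      names <- vapply(spec@kinds, function(k)
        buildMrsFilename(c(base, k$entities), k$suffix, ".nii.gz"),
        character(1))
      mrsrefIdx <- which(vapply(spec@kinds, function(k)
        k$suffix == "mrsref", logical(1)))
      mrsrefRel <- if (length(mrsrefIdx))
        paste0(relDir, names[mrsrefIdx[1L]]) else NULL

      for (j in seq_along(spec@kinds)) {
        kind <- spec@kinds[[j]]
        fileCounter <- fileCounter + 1L
        fileSeed <- (spec@seed * 1000L + fileCounter) %% 2147483647L
        writeFixtureFile(spec, kind, base, relDir, names[j], outRoot,
                         fileSeed, mrsrefRel, anatRel)
      }
    }
  }
  invisible(scanDataset(outRoot))
}

## One data file + sidecar for one acquisition kind.
writeFixtureFile <- function(spec, kind, base, relDir, fname, outRoot,
                             fileSeed, mrsrefRel, anatRel) {
  sfx <- kind$suffix
  ent <- kind$entities
  nuc <- if ("nuc" %in% names(ent)) ent[["nuc"]] else "1H"
  sw <- spec@spectralWidth
  np <- spec@nPoints

  comps <- if (sfx == "mrsref")
    data.frame(amplitude = 10, freqOffsetHz = 0, t2 = 0.05)
  else spec@metabolites

  if (sfx == "mrsi") {
    nvox <- prod(spec@mrsiMatrix)
    vox <- lapply(seq_len(nvox), function(v)
      generateFid(np, sw, comps, spec@noiseSd,
                  seed = (fileSeed + v) %% 2147483647L))
    ## voxel index varies fastest, matching the (x, y, z, t) layout
    data <- array(t(do.call(cbind, vox)), dim = c(spec@mrsiMatrix, np))
  } else {
    data <- array(generateFid(np, sw, comps, spec@noiseSd, seed = fileSeed),
                  dim = c(1L, 1L, 1L, np))
  }

  x <- niftiMrs(data, dwellTime = 1 / sw,
                headerExt = list(SpectrometerFrequency = spec@spectrometerFrequency,
                                 ResonantNucleus = nuc))
  writeNiftiMrs(x, file.path(outRoot, relDir, fname))

  content <- list(
    ResonantNucleus = nuc,
    SpectrometerFrequency = spec@spectrometerFrequency,
    SpectralWidth = sw,
    EchoTime = 0.03,
    WaterSuppression = sfx != "mrsref",
    NumberOfSpectralPoints = np,
    MixingTime = 0.012,
    AcquisitionVoxelSize = c(20, 20, 20))
  if (!is.null(anatRel)) content$AnatomicalImage <- anatRel
  if (sfx %in% c("svs", "unloc")) content$NumberOfTransients <- 64L
  if (sfx %in% c("svs", "mrsi", "unloc") && !is.null(mrsrefRel))
    content$ReferenceSignal <- mrsrefRel
  if (sfx == "mrsi") {
    content$AcquisitionVoxelSize <- c(10, 10, 15)
    content$MatrixSize <- spec@mrsiMatrix
    content$VolumeAffineMatrix <- diag(c(10, 10, 15, 1))
    content$EncodingTechnique <- "EPSI"
  }
  if ("voi" %in% names(ent)) {
    lab <- ent[["voi"]]
    content$BodyPart <- "BRAIN"
    content$BodyPartDetails <- .VOI_DETAILS[lab] %||na% lab
    content$BodyPartDetailsOntology <-
      "http://purl.obolibrary.org/obo/uberon.owl"
  }
  if ("acq" %in% names(ent)) {
    lab <- ent[["acq"]]
    content$PulseSequenceType <- .PULSE_SEQ_NAMES[lab] %||na% lab
  }
  if (sfx == "svs") {
    content$PulseSequencePulses <- c("excitation", "refocus1", "refocus2",
                                     "refocus3", "refocus4")
    content$PulseSequenceTiming <- c(0, 0.0045, 0.0125, 0.0205, 0.0285)
  }
  writeSidecarJson(content,
                   file.path(outRoot, relDir,
                             sub("\\.nii\\.gz$", ".json", fname)))
}

`%||na%` <- function(a, b) if (length(a) == 1L && !is.na(a)) unname(a) else b
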