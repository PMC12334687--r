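## ---------------------------------------------------------------------------
## Mutation registry: targeted single-rule violations of a generated
## dataset, for one-fault diagnosability testing of the validator. Every
## mutation breaks exactly one catalogued rule; in normal (non-strict) mode
## validating the mutated tree yields precisely that rule's error and no
## other error.
## ---------------------------------------------------------------------------

firstDataFile <- function(root, sfx) {
  inv <- scanDataset(root)
  for (i in seq_len(nrow(inv@dataFiles))) {
    p <- tryCatch(parseMrsFilename(basename(inv@dataFiles$path[i])),
                  mrsbids_error = function(e) NULL)
    if (!is.null(p) && p@suffix == sfx)
      return(inv@dataFiles[i, ])
  }
  mrsStop("UnknownMutation", "dataset has no parseable '%s' data file", sfx)
}

editSidecar <- function(root, rel, fn) {
  path <- file.path(root, rel)
  content <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = TRUE)
  writeSidecarJson(fn(content), path)
}

renameDataFile <- function(root, rec, newName) {
  file.rename(file.path(root, rec$path),
              file.path(root, dirname(rec$path), newName))
}

## Swap one filename token for another, keeping the rest of the name.
swapToken <- function(name, from, to) sub(from, to, name, fixed = TRUE)

.MUTATIONS <- list(
  duplicate_entity = list(
    rule_id = "MRS102",
    description = "repeat the acq entity in an svs filename",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      nm <- basename(rec$path)
      acq <- regmatches(nm, regexpr("acq-[A-Za-z0-9]+", nm))
      renameDataFile(root, rec, swapToken(nm, acq, paste(acq, acq, sep = "_")))
    }),
  entity_order_swap = list(
    rule_id = "MRS103",
    description = "swap the acq and nuc entities out of canonical order",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      nm <- basename(rec$path)
      acq <- regmatches(nm, regexpr("acq-[A-Za-z0-9]+", nm))
      nuc <- regmatches(nm, regexpr("nuc-[A-Za-z0-9]+", nm))
      renameDataFile(root, rec,
                     swapToken(swapToken(swapToken(nm, acq, "@"), nuc, acq),
                               "@", nuc))
    }),
  bad_label = list(
    rule_id = "MRS104",
    description = "non-alphanumeric character in the voi label",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      nm <- basename(rec$path)
      voi <- regmatches(nm, regexpr("voi-[A-Za-z0-9]+", nm))
      renameDataFile(root, rec, swapToken(nm, voi, paste0(voi, ".x")))
    }),
  unknown_suffix = list(
    rule_id = "MRS106",
    description = "rename the svs suffix to an unknown token",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      renameDataFile(root, rec,
                     swapToken(basename(rec$path), "_svs.", "_xvs."))
    }),
  missing_sidecar = list(
    rule_id = "MRS502",
    description = "delete the sidecar of an svs data file",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      unlink(file.path(root, rec$sidecar))
    }),
  missing_echotime = list(
    rule_id = "MRS201",
    description = "drop the required EchoTime field",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar, function(x) { x$EchoTime <- NULL; x })
    }),
  watersuppression_string = list(
    rule_id = "MRS203",
    description = "WaterSuppression as a string instead of a boolean",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar,
                  function(x) { x$WaterSuppression <- "yes"; x })
    }),
  acquisitionvoxelsize_length2 = list(
    rule_id = "MRS204",
    description = "AcquisitionVoxelSize with length 2",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar,
                  function(x) { x$AcquisitionVoxelSize <- c(20, 20); x })
    }),
  matrixsize_length4 = list(
    rule_id = "MRS204",
    description = "MatrixSize with length 4",
    apply = function(root) {
      rec <- firstDataFile(root, "mrsi")
      editSidecar(root, rec$sidecar,
                  function(x) { x$MatrixSize <- c(8L, 8L, 1L, 1L); x })
    }),
  volumeaffinematrix_3x3 = list(
    rule_id = "MRS204",
    description = "VolumeAffineMatrix as a 3x3 matrix",
    apply = function(root) {
      rec <- firstDataFile(root, "mrsi")
      editSidecar(root, rec$sidecar,
                  function(x) { x$VolumeAffineMatrix <- diag(3); x })
    }),
  voi_without_bodypart = list(
    rule_id = "MRS303",
    description = "voi entity used but BodyPart removed",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar, function(x) { x$BodyPart <- NULL; x })
    }),
  nuc_mismatch = list(
    rule_id = "MRS302",
    description = "ResonantNucleus contradicts the nuc entity",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar,
                  function(x) { x$ResonantNucleus <- "31P"; x })
    }),
  pulse_length_mismatch = list(
    rule_id = "MRS306",
    description = "PulseSequenceTiming shorter than PulseSequencePulses",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar, function(x) {
        x$PulseSequenceTiming <- utils::head(x$PulseSequenceTiming, -1L); x
      })
    }),
  dangling_referencesignal = list(
    rule_id = "MRS506",
    description = "ReferenceSignal points at a non-existent file",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar, function(x) {
        x$ReferenceSignal <- "sub-99/mrs/sub-99_acq-concref_mrsref.nii.gz"; x
      })
    }),
  dangling_anatomicalimage = list(
    rule_id = "MRS507",
    description = "AnatomicalImage points at a non-existent file",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar, function(x) {
        x$AnatomicalImage <- file.path(rec$subDir, "anat", "missing_T1w.nii.gz")
        x
      })
    }),
  missing_dataset_description = list(
    rule_id = "MRS501",
    description = "delete dataset_description.json",
    apply = function(root) {
      unlink(file.path(root, "dataset_description.json"))
    }),
  spectralwidth_mismatch = list(
    rule_id = "MRS403",
    description = "SpectralWidth inconsistent with the container dwell time",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      editSidecar(root, rec$sidecar,
                  function(x) { x$SpectralWidth <- x$SpectralWidth * 1.25; x })
    }),
  svs_spatial_extent = list(
    rule_id = "MRS406",
    description = "svs data block with a spatial extent of 2",
    apply = function(root) {
      rec <- firstDataFile(root, "svs")
      path <- file.path(root, rec$path)
      x <- readNiftiMrs(path)
      d <- dims(x)
      wide <- array(rep(spectralData(x), each = 2L),
                    dim = c(2L, 1L, 1L, d[4L]))
      writeNiftiMrs(niftiMrs(wide, dwellTime = dwellTime(x),
                             headerExt = headerExt(x)), path)
    })
)

#' Registry of targeted dataset mutations
#'
#' Each mutation introduces exactly one rule violation into an otherwise
#' valid generated dataset, so the validator's soundness and one-fault
#' diagnosability can be tested: validating the mutated tree must yield the
#' targeted rule's error and, in normal mode, no other error.
#'
#' @return A \code{data.frame} with columns \code{name}, \code{rule_id},
#'   \code{description}.
#' @examples
#' mutationRegistry()
#' @seealso [applyMutation()], [generateDataset()]
#' @export
mutationRegistry <- function() {
  data.frame(name = names(.MUTATIONS),
             rule_id = vapply(.MUTATIONS, `[[`, character(1), "rule_id"),
             description = vapply(.MUTATIONS, `[[`, character(1),
                                  "description"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply one targeted mutation to a generated dataset
#'
#' @param root Root of a dataset produced by [generateDataset()] (the
#'   default spec; mutations targeting MRSI need \code{mrsiMatrix} set).
#' @param name Mutation name; see [mutationRegistry()].
#' @return The targeted \code{rule_id}, invisibly.
#' @section Errors: \code{mrsbids_UnknownMutation} for an unknown name or a
#'   dataset lacking the targeted file.
#' @examples
#' \donttest{
#' root <- file.path(tempdir(), "ds-mut")
#' generateDataset(fixtureSpec(nSubjects = 1, seed = 3), root)
#' applyMutation(root, "missing_echotime")
#' issues(validateDataset(root))
#' }
#' @export
applyMutation <- function(root, name) {
  m <- .MUTATIONS[[name]]
  if (is.null(m))
    mrsStop("UnknownMutation", "unknown mutation '%s'", as.character(name)[1L])
  m$apply(root)
  invisible(m$rule_id)
}
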