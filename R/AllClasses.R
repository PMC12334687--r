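#' @import methods
NULL

#' Parsed MRS-BIDS filename
#'
#' Decomposition of an MRS-BIDS filename into its ordered entities, suffix
#' and extension. Objects are created by [parseMrsFilename()] or
#' [buildMrsFilename()]; the validity method enforces the grammar (entities
#' unique and in canonical order, label/index charsets, \code{sub} first).
#'
#' @slot entities Named character vector of entity values, names are entity
#'   keys in canonical order.
#' @slot suffix One of \code{svs}, \code{mrsi}, \code{unloc}, \code{mrsref}.
#' @slot extension One of \code{.nii}, \code{.nii.gz}, \code{.json}.
#' @seealso [parseMrsFilename()], [buildMrsFilename()],
#'   [expectedRelativePath()]
#' @export
setClass("MrsFilename",
  representation(entities = "character", suffix = "character",
                 extension = "character"))

setValidity("MrsFilename", function(object) {
  e <- object@entities
  keys <- names(e)
  if (is.null(keys) || anyNA(keys) || any(!nzchar(keys)))
    return("entities must be a named character vector")
  if (!all(keys %in% .ENTITIES$key))
    return(sprintf("unknown entity key(s): %s",
                   paste(setdiff(keys, .ENTITIES$key), collapse = ", ")))
  if (anyDuplicated(keys))
    return("entity keys must be unique")
  ranks <- .ENTITIES$rank[match(keys, .ENTITIES$key)]
  if (is.unsorted(ranks, strictly = TRUE))
    return("entity keys must be in canonical order")
  if (length(keys) == 0L || keys[1L] != "sub")
    return("the sub entity is mandatory and must come first")
  kinds <- .ENTITIES$kind[match(keys, .ENTITIES$key)]
  badLab <- kinds == "label" & !grepl("^[A-Za-z0-9]+$", e)
  if (any(badLab))
    return(sprintf("label value(s) not alphanumeric: %s",
                   paste(keys[badLab], collapse = ", ")))
  badIdx <- kinds == "index" & !grepl("^[0-9]+$", e)
  if (any(badIdx))
    return(sprintf("index value(s) not nonnegative integers: %s",
                   paste(keys[badIdx], collapse = ", ")))
  if (length(object@suffix) != 1L || !object@suffix %in% .SUFFIXES)
    return("suffix must be one of svs, mrsi, unloc, mrsref")
  if (length(object@extension) != 1L || !object@extension %in% .EXTENSIONS)
    return("extension must be one of .nii, .nii.gz, .json")
  TRUE
})

setClassUnion("MrsFilenameOrNULL", c("MrsFilename", "NULL"))

#' Sidecar metadata document
#'
#' A parsed JSON sidecar together with the provenance of its key-value pairs
#' (for inheritance merging) and the parsed filename of the data file it
#' describes.
#'
#' @slot content Named list of metadata key-value pairs.
#' @slot sourcePaths Character vector of contributing file paths, from the
#'   dataset root down to the file-level sidecar.
#' @slot context A [MrsFilename-class] giving the entities and suffix of the
#'   described data file, or \code{NULL} when validated out of context.
#' @seealso [validateSidecar()], [checkConditionalRequirements()],
#'   [mergeInherited()]
#' @export
setClass("SidecarDocument",
  representation(content = "list", sourcePaths = "character",
                 context = "MrsFilenameOrNULL"))

setValidity("SidecarDocument", function(object) {
  if (length(object@content) &&
      (is.null(names(object@content)) || any(!nzchar(names(object@content)))))
    return("content must be a named list")
  TRUE
})

#' Minimal NIfTI-MRS header
#'
#' The header facts the package needs from a NIfTI-MRS container: the seven
#' axis extents (first three spatial, fourth time-domain samples, fifth to
#' seventh free encoding dimensions), the dwell time (spacing of the time
#' axis, in s), the version tag carried in the NIfTI \code{intent_name}
#' field, and the key-value content of the embedded JSON header extension.
#'
#' @slot dims Integer vector of length 7; all extents >= 1.
#' @slot dwellTime Time-axis grid spacing in seconds; must be > 0 when a
#'   time axis (fourth extent > 1) exists.
#' @slot intentLabel Container version tag (default \code{"mrs_v0_2"}).
#' @slot headerExt Named list parsed from the embedded JSON extension.
#' @slot hasExtension Whether the file carried the extension at all.
#' @export
setClass("NiftiMrsHeader",
  representation(dims = "integer", dwellTime = "numeric",
                 intentLabel = "character", headerExt = "list",
                 hasExtension = "logical"))

setValidity("NiftiMrsHeader", function(object) {
  d <- object@dims
  if (length(d) != 7L) return("dims must have length 7")
  if (anyNA(d) || any(d < 1L)) return("all extents must be >= 1")
  if (d[4L] > 1L && (length(object@dwellTime) != 1L ||
                     is.na(object@dwellTime) || object@dwellTime <= 0))
    return("dwellTime must be > 0 when a time dimension exists")
  TRUE
})

#' NIfTI-MRS container in memory
#'
#' Pairs a [NiftiMrsHeader-class] with its (complex-valued) data block.
#' The element count of the data equals the product of the seven extents.
#'
#' @slot header A [NiftiMrsHeader-class].
#' @slot data A (complex or numeric) array whose dimensions match the
#'   header extents after singleton padding.
#' @seealso [readNiftiMrs()], [writeNiftiMrs()]
#' @export
setClass("NiftiMrs", representation(header = "NiftiMrsHeader", data = "array"))

setValidity("NiftiMrs", function(object) {
  if (length(object@data) != prod(object@header@dims))
    return("data element count must equal the product of the extents")
  TRUE
})

#' Dataset inventory
#'
#' The result of walking a BIDS dataset tree: subjects, sessions, MRS data
#' files with their resolved file-level sidecars, stray sidecars and
#' anatomical images, plus dataset-level bookkeeping.
#'
#' @slot root Dataset root path.
#' @slot subjects Character vector of subject labels.
#' @slot sessions Named list, per subject, of session labels (may be empty).
#' @slot dataFiles \code{data.frame} with columns \code{path} (dataset
#'   relative), \code{subDir}, \code{sesDir}, \code{datatype},
#'   \code{sidecar} (relative path or \code{NA}).
#' @slot sidecars Character vector of all sidecar paths in \code{mrs/}
#'   directories.
#' @slot anatFiles Character vector of anatomical image paths.
#' @slot hasDatasetDescription,hasParticipants Logical flags.
#' @slot ignored Files excluded via \code{.bidsignore}.
#' @seealso [scanDataset()], [validateDataset()]
#' @export
setClass("DatasetInventory",
  representation(root = "character", subjects = "character",
                 sessions = "list", dataFiles = "data.frame",
                 sidecars = "character", anatFiles = "character",
                 hasDatasetDescription = "logical",
                 hasParticipants = "logical", ignored = "character"))

#' Validation report
#'
#' Deterministic, ordered collection of validation issues for one dataset.
#' \code{passed} is \code{TRUE} exactly when no error-severity issue is
#' present.
#'
#' @slot root Dataset root the report refers to; issue paths are relative
#'   to it.
#' @slot issues \code{data.frame} with columns \code{rule_id},
#'   \code{severity} (\code{error}/\code{warning}/\code{info}), \code{file},
#'   \code{location}, \code{message}, sorted by (file, rule_id, location,
#'   message).
#' @slot strict Whether warnings were promoted to errors.
#' @seealso [validateDataset()], [renderReport()]
#' @export
setClass("ValidationReport",
  representation(root = "character", issues = "data.frame",
                 strict = "logical"))

setValidity("ValidationReport", function(object) {
  need <- c("rule_id", "severity", "file", "location", "message")
  if (!all(need %in% names(object@issues)))
    return(sprintf("issues must have columns %s", paste(need, collapse = ", ")))
  if (!all(object@issues$severity %in% c("error", "warning", "info")))
    return("severity must be error, warning or info")
  TRUE
})

#' Synthetic dataset specification
#'
#' Parameters for generating a fully synthetic MRS-BIDS dataset: cohort
#' layout, the acquisition kinds to emit per session, and the simulated
#' acquisition (spectrometer frequency, spectral width, points, metabolite
#' components, noise). A single seed fixes all randomness.
#'
#' @slot nSubjects Number of subjects (>= 1).
#' @slot sessionsPerSubject Sessions per subject; 0 drops the session level.
#' @slot kinds List of kind descriptors, each a list with elements
#'   \code{suffix} and named character \code{entities} (entity template
#'   excluding sub/ses).
#' @slot spectrometerFrequency In MHz.
#' @slot spectralWidth Sampled bandwidth in Hz; the dwell time is its
#'   reciprocal.
#' @slot nPoints Complex time-domain samples per transient (>= 2).
#' @slot metabolites \code{data.frame} with columns \code{amplitude},
#'   \code{freqOffsetHz}, \code{t2} (decay constant, s).
#' @slot noiseSd Standard deviation of the additive complex Gaussian noise.
#' @slot mrsiMatrix Spatial matrix size (length-3 integer) for the MRSI
#'   kind, or \code{integer(0)} for none.
#' @slot seed Integer seed fixing all randomness.
#' @slot includeAnat Whether to write a small anatomical image per subject
#'   and reference it from the sidecars.
#' @seealso [fixtureSpec()], [generateDataset()]
#' @export
setClass("FixtureSpec",
  representation(nSubjects = "integer", sessionsPerSubject = "integer",
                 kinds = "list", spectrometerFrequency = "numeric",
                 spectralWidth = "numeric", nPoints = "integer",
                 metabolites = "data.frame", noiseSd = "numeric",
                 mrsiMatrix = "integer", seed = "integer",
                 includeAnat = "logical"))

setValidity("FixtureSpec", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  if (object@sessionsPerSubject < 0L) return("sessionsPerSubject must be >= 0")
  if (object@nPoints < 2L) return("nPoints must be >= 2")
  if (object@spectralWidth <= 0) return("spectralWidth must be > 0")
  if (!all(c("amplitude", "freqOffsetHz", "t2") %in% names(object@metabolites)))
    return("metabolites needs columns amplitude, freqOffsetHz, t2")
  if (length(object@mrsiMatrix) && length(object@mrsiMatrix) != 3L)
    return("mrsiMatrix must have length 3")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})
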