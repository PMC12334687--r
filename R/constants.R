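#' @name mrsbids-constants
#' @title Constants of the MRS-BIDS grammar and container
#' @description
#' Fixed vocabulary used throughout the package: the canonical entity table,
#' the four MRS suffixes, recognised file extensions, and the NIfTI-MRS
#' header-extension code.
#'
#' The entity order is a strict total order: \code{sub} always first,
#' \code{ses} (when present) immediately second, then
#' \code{task, acq, nuc, voi, rec, run, echo, inv}. \code{run}, \code{echo}
#' and \code{inv} take nonnegative-integer indices; all other entities take
#' alphanumeric labels.
#' @keywords internal
NULL

## Canonical entity descriptor table. rank defines output order; kind decides
## the value charset (label = [A-Za-z0-9]+, index = [0-9]+).
.ENTITIES <- data.frame(
  key  = c("sub", "ses", "task", "acq", "nuc", "voi", "rec", "run", "echo", "inv"),
  kind = c("label", "label", "label", "label", "label", "label", "label",
           "index", "index", "index"),
  rank = 1:10,
  stringsAsFactors = FALSE
)

.SUFFIXES <- c("svs", "mrsi", "unloc", "mrsref")

## Data extensions first: .nii.gz must be tested before .nii.
.EXTENSIONS <- c(".nii.gz", ".nii", ".json")

## NIfTI header-extension code designated for MRS (ecode 44) and the
## container version tag carried in intent_name.
NIFTI_MRS_ECODE <- 44L
NIFTI_MRS_VERSION <- "mrs_v0_2"

#' Entity descriptor table
#'
#' Returns the canonical MRS-BIDS entity table: one row per entity key with
#' its value kind (\code{label} or \code{index}), its rank in the canonical
#' filename order, and whether it is required in every filename (only
#' \code{sub} is).
#'
#' @return A \code{data.frame} with columns \code{key}, \code{kind},
#'   \code{rank}, \code{filenameRequired}.
#' @examples
#' entityDescriptors()
#' @export
entityDescriptors <- function() {
  out <- .ENTITIES
  out$filenameRequired <- out$key == "sub"
  out
}

#' MRS suffixes and extensions
#'
#' @return Character vector of the four MRS data-type suffixes
#'   (\code{mrsSuffixes}) or of the recognised file extensions
#'   (\code{mrsExtensions}).
#' @examples
#' mrsSuffixes()
#' @export
mrsSuffixes <- function() .SUFFIXES

#' @rdname mrsSuffixes
#' @export
mrsExtensions <- function() .EXTENSIONS
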