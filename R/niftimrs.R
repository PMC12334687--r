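## Pad extents to the seven NIfTI-MRS axes; more than seven non-unit axes is
## an overflow.
padDims7 <- function(d) {
  d <- as.integer(d)
  if (length(d) > 7L) {
    if (any(d[-(1:7)] != 1L))
      mrsStop("DimOverflow", "more than 7 non-unit dimensions (%s)",
              paste(d, collapse = "x"))
    d <- d[1:7]
  }
  c(d, rep(1L, 7L - length(d)))
}

#' Construct a NIfTI-MRS header
#'
#' @param dims Axis extents (1 to 7 values); padded with trailing
#'   singletons to the seven NIfTI-MRS axes (three spatial, one time, three
#'   free encoding axes).
#' @param dwellTime Time-axis spacing in seconds; the reciprocal of the
#'   spectral width.
#' @param headerExt Named list to embed as the JSON header extension; by
#'   convention it carries at least \code{SpectrometerFrequency} and
#'   \code{ResonantNucleus}.
#' @param intentLabel Container version tag written to the NIfTI
#'   \code{intent_name} field.
#' @param hasExtension Whether the extension is (to be) present.
#' @return A [NiftiMrsHeader-class].
#' @examples
#' niftiMrsHeader(c(1, 1, 1, 2048), dwellTime = 1 / 2000,
#'   headerExt = list(SpectrometerFrequency = 123.25, ResonantNucleus = "1H"))
#' @export
niftiMrsHeader <- function(dims, dwellTime, headerExt = list(),
                           intentLabel = NIFTI_MRS_VERSION,
                           hasExtension = length(headerExt) > 0L) {
  new("NiftiMrsHeader", dims = padDims7(dims), dwellTime = as.numeric(dwellTime),
      intentLabel = intentLabel, headerExt = headerExt,
      hasExtension = hasExtension)
}

#' Construct an in-memory NIfTI-MRS container
#'
#' @param data Complex (or numeric) array; a plain vector is treated as a
#'   single-voxel time series along the fourth axis.
#' @inheritParams niftiMrsHeader
#' @return A [NiftiMrs-class].
#' @examples
#' fid <- complex(real = rnorm(64), imaginary = rnorm(64))
#' x <- niftiMrs(fid, dwellTime = 5e-4,
#'   headerExt = list(SpectrometerFrequency = 123.25, ResonantNucleus = "1H"))
#' dims(x)
#' @export
niftiMrs <- function(data, dwellTime, headerExt = list(),
                     intentLabel = NIFTI_MRS_VERSION) {
  if (is.null(dim(data))) dim(data) <- c(1L, 1L, 1L, length(data))
  d7 <- padDims7(dim(data))
  dim(data) <- d7
  hdr <- niftiMrsHeader(d7, dwellTime, headerExt = headerExt,
                        intentLabel = intentLabel)
  new("NiftiMrs", header = hdr, data = data)
}

#' @rdname mrsbids-accessors
#' @export
setMethod("dims", "NiftiMrsHeader", function(x) x@dims)

#' @rdname mrsbids-accessors
#' @export
setMethod("dims", "NiftiMrs", function(x) x@header@dims)

#' @rdname mrsbids-accessors
#' @export
setMethod("dwellTime", "NiftiMrsHeader", function(x) x@dwellTime)

#' @rdname mrsbids-accessors
#' @export
setMethod("dwellTime", "NiftiMrs", function(x) x@header@dwellTime)

#' @rdname mrsbids-accessors
#' @export
setMethod("headerExt", "NiftiMrsHeader", function(x) x@headerExt)

#' @rdname mrsbids-accessors
#' @export
setMethod("headerExt", "NiftiMrs", function(x) x@header@headerExt)

#' @rdname mrsbids-accessors
#' @export
setMethod("mrsHeader", "NiftiMrs", function(x) x@header)

#' @rdname mrsbids-accessors
#' @export
setMethod("spectralData", "NiftiMrs", function(x) x@data)

setMethod("show", "NiftiMrsHeader", function(object) {
  cat("NiftiMrsHeader\n")
  cat("  dims:", paste(object@dims, collapse = " x "), "\n")
  cat(sprintf("  dwell time: %g s (spectral width %g Hz)\n",
              object@dwellTime, 1 / object@dwellTime))
  cat("  intent:", object@intentLabel, "\n")
  cat(sprintf("  header extension: %s (%d key(s))\n",
              if (object@hasExtension) "present" else "absent",
              length(object@headerExt)))
  invisible(object)
})

setMethod("show", "NiftiMrs", function(object) {
  show(object@header)
  cat(sprintf("  data: %s array, %d elements\n",
              typeof(object@data), length(object@data)))
  invisible(object)
})

#' Read a NIfTI-MRS file
#'
#' Reads a NIfTI-1/NIfTI-2 file (optionally gzip-compressed), exposing the
#' full seven-axis geometry (absent trailing axes count as extent 1), the
#' dwell time from the fourth pixdim slot, and the embedded JSON header
#' extension (ecode 44). A file without the extension — e.g. a plain
#' anatomical image — yields an empty \code{headerExt} with
#' \code{hasExtension = FALSE}.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return A [NiftiMrs-class].
#' @section Errors: \code{mrsbids_NotNifti} when the file cannot be read as
#'   NIfTI; \code{mrsbids_UnreadableExtension} when the extension is present
#'   but not valid JSON.
#' @seealso [writeNiftiMrs()], [consistencyCheck()]
#' @export
readNiftiMrs <- function(path) {
  if (!file.exists(path))
    mrsStop("NotNifti", "'%s' does not exist", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    mrsStop("NotNifti", "'%s' is not a readable NIfTI file: %s",
                            path, conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  d <- hdr$dim[2:8]
  d[is.na(d) | d < 1L] <- 1L
  d <- as.integer(d)
  dt <- as.numeric(hdr$pixdim[5L])
  ## degenerate pixdim: keep the object constructible; the spectral-width
  ## coherence check will flag the implausible value downstream
  if (!is.finite(dt) || dt <= 0) dt <- 1
  ext <- list(); hasExt <- FALSE
  for (x in RNifti::extensions(img)) {
    if (identical(as.integer(attr(x, "code")), NIFTI_MRS_ECODE)) {
      txt <- rawToChar(x[x != as.raw(0L)])
      ext <- tryCatch(
        jsonlite::fromJSON(txt, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
        error = function(e)
          mrsStop("UnreadableExtension",
                  "'%s': embedded header extension is not valid JSON", path))
      hasExt <- TRUE
      break
    }
  }
  hdrObj <- niftiMrsHeader(d, dwellTime = dt, headerExt = ext,
                           intentLabel = as.character(hdr$intent_name),
                           hasExtension = hasExt)
  data <- as.array(img)
  attributes(data) <- list(dim = d)
  new("NiftiMrs", header = hdrObj, data = data)
}

#' Write a NIfTI-MRS file
#'
#' Writes the container to disk: the data block padded with trailing
#' singleton axes to seven dimensions, complex-valued storage, the dwell
#' time in the fourth pixdim slot, the version tag in \code{intent_name},
#' and the header content embedded as a JSON header extension (ecode 44).
#' \code{readNiftiMrs(writeNiftiMrs(x, path))} round-trips values, extents,
#' dwell time and extension content exactly.
#'
#' @param x A [NiftiMrs-class] (from [niftiMrs()] or [readNiftiMrs()]).
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @section Errors: \code{mrsbids_DimOverflow} for more than seven non-unit
#'   axes; \code{mrsbids_SerializationError} when the header extension
#'   cannot be serialized to JSON.
#' @export
writeNiftiMrs <- function(x, path) {
  stopifnot(is(x, "NiftiMrs"))
  validObject(x)
  hdr <- x@header
  arr <- x@data
  dim(arr) <- hdr@dims
  json <- tryCatch(
    as.character(jsonlite::toJSON(hdr@headerExt, auto_unbox = TRUE,
                                  digits = NA, null = "null")),
    error = function(e)
      mrsStop("SerializationError",
              "header extension does not serialize to JSON: %s",
              conditionMessage(e)))
  img <- RNifti::asNifti(arr, list(intent_name = hdr@intentLabel))
  nd <- length(dim(img))
  pd <- rep(1, nd)
  if (nd >= 4L) pd[4L] <- hdr@dwellTime
  RNifti::pixdim(img) <- pd
  if (hdr@hasExtension || length(hdr@headerExt))
    img <- RNifti::`extension<-`(img, NIFTI_MRS_ECODE, value = json)
  ## NIfTI-2: the header stores pixdim (the dwell time) in double precision,
  ## so the time grid round-trips exactly
  RNifti::writeNifti(img, path, version = 2)
  invisible(path)
}

## all.equal-style numeric match used for header/sidecar coherence
numMatch <- function(a, b, tol = 1e-6) {
  is.numeric(a) && is.numeric(b) && length(a) == length(b) &&
    all(abs(a - b) <= tol * pmax(1, abs(b)))
}

#' Cross-check a container header against its sidecar
#'
#' Coherence checks between the facts a NIfTI-MRS file states about itself
#' and the sidecar metadata describing it:
#' \itemize{
#'   \item sidecar \code{SpectralWidth} vs the reciprocal dwell time —
#'     relative difference above \code{tol} is an error;
#'   \item embedded-extension \code{SpectrometerFrequency} /
#'     \code{ResonantNucleus} vs the sidecar values — mismatch is a warning
#'     (neither source is authoritative, so nothing is auto-resolved);
#'   \item sidecar \code{NumberOfSpectralPoints} vs the time-axis extent —
#'     warning;
#'   \item spatial extents vs the suffix: any spatial extent > 1 on
#'     \code{svs} data is an error; all-singleton spatial extents on
#'     \code{mrsi} data is a warning;
#'   \item a missing embedded extension is a warning.
#' }
#'
#' @param header A [NiftiMrsHeader-class] (or [NiftiMrs-class]).
#' @param sidecar A [SidecarDocument-class]; its context supplies the
#'   suffix.
#' @param tol Relative tolerance for the spectral-width/dwell-time check.
#' @return A \code{data.frame} of issues (possibly empty).
#' @examples
#' x <- niftiMrs(complex(real = rnorm(4)), dwellTime = 5e-4,
#'   headerExt = list(SpectrometerFrequency = 123.25, ResonantNucleus = "1H"))
#' doc <- sidecarDocument(
#'   list(ResonantNucleus = "1H", SpectrometerFrequency = 123.25,
#'        SpectralWidth = 2000, EchoTime = 0.03),
#'   context = parseMrsFilename("sub-01_svs.nii.gz"))
#' consistencyCheck(mrsHeader(x), doc)  # consistent: no issues
#' @export
consistencyCheck <- function(header, sidecar, tol = 1e-3) {
  if (is(header, "NiftiMrs")) header <- header@header
  stopifnot(is(header, "NiftiMrsHeader"), is(sidecar, "SidecarDocument"))
  content <- sidecar@content
  file <- docFileLabel(sidecar)
  sfx <- if (!is.null(sidecar@context)) sidecar@context@suffix else NA_character_
  out <- list()
  add <- function(id, loc, msg)
    out[[length(out) + 1L]] <<- mrsIssue(id, file, loc, msg)

  if (!header@hasExtension)
    add("MRS402", "header extension",
        "file lacks the embedded JSON header extension")
  sw <- content[["SpectralWidth"]]
  if (isScalarNumber(sw) && sw > 0 && is.finite(header@dwellTime) &&
      header@dwellTime > 0) {
    if (abs(sw - 1 / header@dwellTime) / sw > tol)
      add("MRS403", "SpectralWidth",
          sprintf("SpectralWidth %g Hz is inconsistent with dwell time %g s (implies %g Hz)",
                  sw, header@dwellTime, 1 / header@dwellTime))
  }
  hsf <- header@headerExt[["SpectrometerFrequency"]]
  ssf <- content[["SpectrometerFrequency"]]
  if (!is.null(hsf) && !is.null(ssf) && isScalarNumber(ssf) &&
      !numMatch(as.numeric(hsf)[1L], ssf))
    add("MRS404", "SpectrometerFrequency",
        sprintf("embedded extension says %s MHz, sidecar says %g MHz",
                paste(hsf, collapse = ","), ssf))
  hrn <- header@headerExt[["ResonantNucleus"]]
  srn <- content[["ResonantNucleus"]]
  if (!is.null(hrn) && !is.null(srn) &&
      normalizeNucleus(hrn) != normalizeNucleus(srn))
    add("MRS404", "ResonantNucleus",
        sprintf("embedded extension says '%s', sidecar says '%s'",
                paste(hrn, collapse = ","), paste(srn, collapse = ",")))
  np <- content[["NumberOfSpectralPoints"]]
  if (isScalarNumber(np) && np != header@dims[4L])
    add("MRS405", "NumberOfSpectralPoints",
        sprintf("sidecar says %d spectral points, time axis has extent %d",
                as.integer(np), header@dims[4L]))
  if (identical(sfx, "svs") && any(header@dims[1:3] > 1L))
    add("MRS406", "dims",
        sprintf("svs data must be single-voxel; spatial extents are %s",
                paste(header@dims[1:3], collapse = "x")))
  if (identical(sfx, "mrsi") && all(header@dims[1:3] == 1L))
    add("MRS407", "dims",
        "mrsi data has no spatial extent greater than 1")
  sortIssues(do.call(bindIssues, out))
}
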