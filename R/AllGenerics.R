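#' Accessors for mrsbids objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access.
#'
#' @param x An object of the relevant class.
#' @name mrsbids-accessors
NULL

#' @rdname mrsbids-accessors
#' @return \code{entities()} returns the named character vector of entity
#'   values in canonical order.
#' @export
setGeneric("entities", function(x) standardGeneric("entities"))

#' @rdname mrsbids-accessors
#' @return \code{suffix()} returns the suffix token of a filename.
#' @export
setGeneric("suffix", function(x) standardGeneric("suffix"))

#' @rdname mrsbids-accessors
#' @return \code{fileExt()} returns the file extension (including dot).
#' @export
setGeneric("fileExt", function(x) standardGeneric("fileExt"))

#' @rdname mrsbids-accessors
#' @return \code{dims()} returns the seven axis extents of a NIfTI-MRS
#'   header (or container).
#' @export
setGeneric("dims", function(x) standardGeneric("dims"))

#' @rdname mrsbids-accessors
#' @return \code{dwellTime()} returns the time-axis spacing in seconds.
#' @export
setGeneric("dwellTime", function(x) standardGeneric("dwellTime"))

#' @rdname mrsbids-accessors
#' @return \code{headerExt()} returns the parsed embedded JSON extension
#'   content as a named list.
#' @export
setGeneric("headerExt", function(x) standardGeneric("headerExt"))

#' @rdname mrsbids-accessors
#' @return \code{mrsHeader()} returns the [NiftiMrsHeader-class] of a
#'   container.
#' @export
setGeneric("mrsHeader", function(x) standardGeneric("mrsHeader"))

#' @rdname mrsbids-accessors
#' @return \code{spectralData()} returns the data block.
#' @export
setGeneric("spectralData", function(x) standardGeneric("spectralData"))

#' @rdname mrsbids-accessors
#' @return \code{issues()} returns the issue table of a report.
#' @export
setGeneric("issues", function(x) standardGeneric("issues"))

#' @rdname mrsbids-accessors
#' @return \code{passed()} is \code{TRUE} when the report has no errors.
#' @export
setGeneric("passed", function(x) standardGeneric("passed"))

#' @rdname mrsbids-accessors
#' @return \code{severityCounts()} returns a named integer vector with the
#'   number of errors, warnings and infos.
#' @export
setGeneric("severityCounts", function(x) standardGeneric("severityCounts"))

#' @rdname mrsbids-accessors
#' @return \code{sidecarContent()} returns the metadata list of a sidecar
#'   document.
#' @export
setGeneric("sidecarContent", function(x) standardGeneric("sidecarContent"))

#' @rdname mrsbids-accessors
#' @return \code{sidecarContext()} returns the [MrsFilename-class] context
#'   of a sidecar document (or \code{NULL}).
#' @export
setGeneric("sidecarContext", function(x) standardGeneric("sidecarContext"))

#' @rdname mrsbids-accessors
#' @return \code{dataFiles()} returns the data-file table of an inventory.
#' @export
setGeneric("dataFiles", function(x) standardGeneric("dataFiles"))
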