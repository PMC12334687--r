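#' Create a sidecar document
#'
#' Wraps parsed sidecar content, its provenance and the parsed filename of
#' the data file it describes into a [SidecarDocument-class].
#'
#' @param content Named list of metadata key-value pairs (as produced by
#'   parsing the sidecar JSON).
#' @param context A [MrsFilename-class] for the described data file, or
#'   \code{NULL}.
#' @param sourcePaths Character vector of contributing file paths, shallow
#'   (dataset root) first.
#' @return A [SidecarDocument-class].
#' @examples
#' doc <- sidecarDocument(
#'   list(ResonantNucleus = "1H", SpectrometerFrequency = 123.25,
#'        SpectralWidth = 2000, EchoTime = 0.03),
#'   context = parseMrsFilename("sub-01_svs.nii.gz"))
#' @export
sidecarDocument <- function(content, context = NULL,
                            sourcePaths = character(0)) {
  new("SidecarDocument", content = as.list(content), context = context,
      sourcePaths = as.character(sourcePaths))
}

#' Read a sidecar JSON file
#'
#' @param path Path to a \code{.json} sidecar.
#' @param context Optional [MrsFilename-class] of the described data file;
#'   when \code{NULL} it is derived from the sidecar's own filename if that
#'   parses.
#' @return A [SidecarDocument-class].
#' @section Errors: \code{mrsbids_MalformedDocument} when the file is not
#'   valid JSON (distinct from validation issues).
#' @export
readSidecar <- function(path, context = NULL) {
  content <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
    error = function(e)
      mrsStop("MalformedDocument", "'%s' is not valid JSON: %s",
              path, conditionMessage(e)))
  if (is.null(context)) {
    context <- tryCatch(parseMrsFilename(basename(path)),
                        mrsbids_error = function(e) NULL)
  }
  sidecarDocument(content, context = context, sourcePaths = path)
}

#' @rdname mrsbids-accessors
#' @export
setMethod("sidecarContent", "SidecarDocument", function(x) x@content)

#' @rdname mrsbids-accessors
#' @export
setMethod("sidecarContext", "SidecarDocument", function(x) x@context)

setMethod("show", "SidecarDocument", function(object) {
  cat(sprintf("SidecarDocument: %d field(s)\n", length(object@content)))
  if (!is.null(object@context))
    cat("  describes:", format(object@context), "\n")
  if (length(object@sourcePaths))
    cat("  sources:", paste(object@sourcePaths, collapse = " <- "), "\n")
  invisible(object)
})

## --- value checking ---------------------------------------------------------

isScalarNumber <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
isIntegral <- function(v) is.numeric(v) && all(is.finite(v)) && all(v == floor(v))

## Returns NULL when the value conforms, otherwise list(kind, message) where
## kind is "type" or "shape".
checkValueType <- function(name, value, row) {
  t <- row$value_type
  n <- row$shape
  bad <- function(kind, msg) list(kind = kind, msg = msg)
  switch(t,
    boolean = {
      if (!(is.logical(value) && length(value) == 1L && !is.na(value)))
        return(bad("type", sprintf("%s must be true or false", name)))
    },
    number = {
      if (!isScalarNumber(value))
        return(bad("type", sprintf("%s must be a single number", name)))
    },
    integer = {
      if (!isScalarNumber(value) || !isIntegral(value))
        return(bad("type", sprintf("%s must be a single integer", name)))
    },
    string = {
      if (!(is.character(value) && length(value) == 1L && !is.na(value)))
        return(bad("type", sprintf("%s must be a string", name)))
    },
    uri = {
      if (!(is.character(value) && length(value) == 1L && !is.na(value)))
        return(bad("type", sprintf("%s must be a URI string", name)))
    },
    string_array = {
      if (!(is.character(value) && length(value) >= 1L))
        return(bad("type", sprintf("%s must be an array of strings", name)))
    },
    string_or_string_array = ,
    path_or_path_array = {
      if (!(is.character(value) && length(value) >= 1L && !anyNA(value)))
        return(bad("type",
                   sprintf("%s must be a string or array of strings", name)))
    },
    number_array = {
      if (!is.numeric(value) || is.matrix(value))
        return(bad("type", sprintf("%s must be an array of numbers", name)))
      if (length(value) != n)
        return(bad("shape", sprintf("%s must have length %d, found %d",
                                    name, n, length(value))))
    },
    integer_array = {
      if (!is.numeric(value) || is.matrix(value) || !isIntegral(value))
        return(bad("type", sprintf("%s must be an array of integers", name)))
      if (length(value) != n)
        return(bad("shape", sprintf("%s must have length %d, found %d",
                                    name, n, length(value))))
    },
    number_array_var = {
      if (!is.numeric(value) || is.matrix(value) || length(value) < 1L)
        return(bad("type", sprintf("%s must be an array of numbers", name)))
    },
    square_matrix = {
      if (is.list(value))  # ragged rows defeat matrix simplification
        return(bad("shape", sprintf("%s must be a %dx%d matrix", name, n, n)))
      if (!is.matrix(value) || !is.numeric(value))
        return(bad("type", sprintf("%s must be an array of numeric arrays",
                                   name)))
      if (!all(dim(value) == c(n, n)))
        return(bad("shape", sprintf("%s must be %dx%d, found %dx%d",
                                    name, n, n, nrow(value), ncol(value))))
    },
    stop("unhandled value_type: ", t)  # catalog bug, not user error
  )
  NULL
}

## Physical-domain constraints implied by the units; violations are errors.
.DOMAIN_CHECKS <- list(
  SpectrometerFrequency  = function(v) if (v <= 0) "must be > 0 MHz",
  SpectralWidth          = function(v) if (v <= 0) "must be > 0 Hz",
  EchoTime               = function(v) if (v < 0) "must be >= 0 s",
  MixingTime             = function(v) if (v < 0) "must be >= 0 s",
  NumberOfSpectralPoints = function(v) if (v < 1) "must be >= 1",
  NumberOfTransients     = function(v) if (v < 1) "must be >= 1",
  PulseSequenceTiming    = function(v) if (any(v < 0)) "must be >= 0 s"
)

isWellFormedUri <- function(v) grepl("^[A-Za-z][A-Za-z0-9+.-]*:.+", v)

docFileLabel <- function(doc) {
  if (length(doc@sourcePaths)) doc@sourcePaths[length(doc@sourcePaths)] else ""
}

## --- schema validation ------------------------------------------------------

#' Validate a sidecar against the field catalog
#'
#' Checks one sidecar document in the context of the data file it
#' describes: an error per missing required field, a warning per missing
#' recommended field applicable to the file's suffix, an error per
#' type/shape/domain violation of a present field, an info notice per key
#' outside the catalog, and silence for absent optional fields. The issue
#' list is sorted by (file, rule id, location) and is fully deterministic.
#'
#' @param doc A [SidecarDocument-class]; its \code{context} supplies the
#'   suffix that decides field applicability (without a context, every
#'   catalogued field is treated as applicable).
#' @return A \code{data.frame} of issues (possibly empty); see
#'   [ValidationReport-class] for the columns.
#' @examples
#' doc <- sidecarDocument(
#'   list(ResonantNucleus = "1H", SpectrometerFrequency = 123.25,
#'        SpectralWidth = 2000, EchoTime = 0.03),
#'   context = parseMrsFilename("sub-01_svs.nii.gz"))
#' v <- validateSidecar(doc)
#' subset(v, severity == "error")  # none
#' @seealso [checkConditionalRequirements()], [sidecarCatalog()]
#' @export
validateSidecar <- function(doc) {
  stopifnot(is(doc, "SidecarDocument"))
  sfx <- if (!is.null(doc@context)) doc@context@suffix else NA_character_
  file <- docFileLabel(doc)
  content <- doc@content
  out <- list()
  for (i in seq_len(nrow(.FIELD_CATALOG))) {
    row <- .FIELD_CATALOG[i, ]
    applies <- is.na(sfx) || fieldApplies(row, sfx)
    present <- row$name %in% names(content)
    if (!present) {
      if (!applies) next
      if (row$level == "required") {
        out[[length(out) + 1L]] <- mrsIssue("MRS201", file, row$name,
          sprintf("required field '%s' is missing", row$name))
      } else if (row$level == "recommended") {
        out[[length(out) + 1L]] <- mrsIssue("MRS202", file, row$name,
          sprintf("recommended field '%s' is missing", row$name))
      }
      next
    }
    value <- content[[row$name]]
    tv <- checkValueType(row$name, value, row)
    if (!is.null(tv)) {
      out[[length(out) + 1L]] <- mrsIssue(
        if (tv$kind == "shape") "MRS204" else "MRS203", file, row$name, tv$msg)
      next
    }
    dc <- .DOMAIN_CHECKS[[row$name]]
    if (!is.null(dc)) {
      dmsg <- dc(value)
      if (!is.null(dmsg)) {
        out[[length(out) + 1L]] <- mrsIssue("MRS205", file, row$name,
          sprintf("%s %s (found %s)", row$name, dmsg,
                  paste(utils::head(value, 3L), collapse = ", ")))
        next
      }
    }
    if (row$value_type == "uri" && !isWellFormedUri(value)) {
      out[[length(out) + 1L]] <- mrsIssue("MRS309", file, row$name,
        sprintf("%s is not a well-formed URI: '%s'", row$name, value))
    }
  }
  unknown <- setdiff(names(content), .FIELD_CATALOG$name)
  for (key in unknown) {
    out[[length(out) + 1L]] <- mrsIssue("MRS206", file, key,
      sprintf("key '%s' is outside the MRS field catalog", key))
  }
  sortIssues(do.call(bindIssues, out))
}

## nuc labels and ResonantNucleus values compare after case-insensitive
## alphanumeric normalization; an array (dual-tuned) compares against the
## in-order concatenation of its elements.
normalizeNucleus <- function(v) {
  toupper(gsub("[^A-Za-z0-9]", "", paste(v, collapse = "")))
}

#' Check entity-conditional sidecar requirements
#'
#' Enforces the rules that couple filename entities to sidecar content:
#' \itemize{
#'   \item \code{nuc-<label>} requires \code{ResonantNucleus}, with a value
#'     matching the label (case-insensitive alphanumeric comparison;
#'     dual-tuned arrays compare against their concatenation);
#'   \item \code{voi-<label>} requires \code{BodyPart} and
#'     \code{BodyPartDetails} (\code{BodyPartDetailsOntology} stays
#'     optional);
#'   \item \code{acq-<label>} without \code{PulseSequenceType} draws a
#'     warning;
#'   \item \code{PulseSequencePulses} requires a \code{PulseSequenceTiming}
#'     array of equal length;
#'   \item for \code{mrsi} data, absent \code{MatrixSize},
#'     \code{VolumeAffineMatrix} or \code{EncodingTechnique} draw warnings;
#'   \item \code{NumberOfTransients} on \code{mrsi} data draws an info
#'     notice (it is meant for single-voxel and unlocalized acquisitions).
#' }
#'
#' @inheritParams validateSidecar
#' @return A \code{data.frame} of issues (possibly empty).
#' @examples
#' doc <- sidecarDocument(list(ResonantNucleus = "1H"),
#'   context = parseMrsFilename("sub-01_nuc-1H_voi-pcc_svs.nii.gz"))
#' checkConditionalRequirements(doc)  # BodyPart/BodyPartDetails missing
#' @export
checkConditionalRequirements <- function(doc) {
  stopifnot(is(doc, "SidecarDocument"))
  if (is.null(doc@context))
    mrsStop("BadInput", "conditional checks need a parsed filename context")
  e <- doc@context@entities
  sfx <- doc@context@suffix
  content <- doc@content
  file <- docFileLabel(doc)
  out <- list()
  add <- function(id, loc, msg)
    out[[length(out) + 1L]] <<- mrsIssue(id, file, loc, msg)

  if ("nuc" %in% names(e)) {
    rn <- content[["ResonantNucleus"]]
    if (is.null(rn)) {
      add("MRS301", "ResonantNucleus",
          sprintf("entity nuc-%s requires the ResonantNucleus field", e[["nuc"]]))
    } else if (normalizeNucleus(rn) != normalizeNucleus(e[["nuc"]])) {
      add("MRS302", "ResonantNucleus",
          sprintf("ResonantNucleus '%s' does not match entity nuc-%s",
                  paste(rn, collapse = ","), e[["nuc"]]))
    }
  }
  if ("voi" %in% names(e)) {
    if (is.null(content[["BodyPart"]]))
      add("MRS303", "BodyPart",
          sprintf("entity voi-%s requires the BodyPart field", e[["voi"]]))
    if (is.null(content[["BodyPartDetails"]]))
      add("MRS304", "BodyPartDetails",
          sprintf("entity voi-%s requires the BodyPartDetails field", e[["voi"]]))
  }
  if ("acq" %in% names(e) && is.null(content[["PulseSequenceType"]]))
    add("MRS305", "PulseSequenceType",
        sprintf("entity acq-%s should be described in PulseSequenceType",
                e[["acq"]]))
  if (!is.null(content[["PulseSequencePulses"]])) {
    pulses <- content[["PulseSequencePulses"]]
    timing <- content[["PulseSequenceTiming"]]
    if (is.null(timing)) {
      add("MRS306", "PulseSequenceTiming",
          "PulseSequencePulses requires a PulseSequenceTiming array")
    } else if (length(pulses) != length(timing)) {
      add("MRS306", "PulseSequencePulses",
          sprintf("PulseSequencePulses (length %d) and PulseSequenceTiming (length %d) must have equal length",
                  length(pulses), length(timing)))
    }
  }
  if (identical(sfx, "mrsi")) {
    for (f in c("MatrixSize", "VolumeAffineMatrix", "EncodingTechnique")) {
      if (is.null(content[[f]]))
        add("MRS307", f, sprintf("'%s' is recommended for MRSI data", f))
    }
    if (!is.null(content[["NumberOfTransients"]]))
      add("MRS308", "NumberOfTransients",
          "NumberOfTransients is recommended for SVS and unlocalized acquisitions only")
  }
  sortIssues(do.call(bindIssues, out))
}

#' Merge sidecar fragments by the inheritance principle
#'
#' Key-wise shallow merge of sidecar fragments ordered from the dataset
#' root down to the file level: a key set at a deeper (more specific) level
#' overrides the same key from a shallower one. Merging is deterministic
#' and idempotent; \code{sourcePaths} accumulates provenance in merge
#' order.
#'
#' @param sources List of [SidecarDocument-class] fragments, shallowest
#'   first.
#' @return The merged [SidecarDocument-class]; the context is taken from
#'   the deepest fragment that has one.
#' @examples
#' root <- sidecarDocument(list(SpectrometerFrequency = 123.25))
#' leaf <- sidecarDocument(list(EchoTime = 0.03))
#' sidecarContent(mergeInherited(list(root, leaf)))
#' @export
mergeInherited <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1L,
            all(vapply(sources, is, logical(1), "SidecarDocument")))
  content <- list()
  paths <- character(0)
  context <- NULL
  for (doc in sources) {
    for (key in names(doc@content)) content[[key]] <- doc@content[[key]]
    paths <- c(paths, doc@sourcePaths)
    if (!is.null(doc@context)) context <- doc@context
  }
  sidecarDocument(content, context = context,
                  sourcePaths = unique(paths))
}
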