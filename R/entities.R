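#' Parse an MRS-BIDS filename
#'
#' Tokenizes a filename of the form
#' \code{<entities>_<suffix>.<extension>} into a [MrsFilename-class].
#' Parsing is strict: any grammar violation raises a classed error rather
#' than repairing the name. Filenames must begin with \code{sub-<label>}
#' (optionally followed immediately by \code{ses-<label>}), every entity key
#' may appear only once, keys must follow the canonical order
#' \code{sub, ses, task, acq, nuc, voi, rec, run, echo, inv}, labels are
#' alphanumeric and indices are nonnegative integers.
#'
#' @param name A single filename string (no directory components).
#' @param lenient If \code{TRUE}, an out-of-order (but otherwise valid)
#'   entity sequence is re-sorted with a warning instead of an error. Meant
#'   only for interactive inspection; validation always uses strict mode.
#' @return A [MrsFilename-class].
#' @section Errors:
#' Classed conditions \code{mrsbids_UnknownEntity},
#' \code{mrsbids_DuplicateEntity}, \code{mrsbids_OrderViolation},
#' \code{mrsbids_BadLabel}, \code{mrsbids_BadIndex},
#' \code{mrsbids_MissingSuffix}, \code{mrsbids_UnknownSuffix},
#' \code{mrsbids_UnknownExtension}, \code{mrsbids_MissingSubject}.
#' @examples
#' p <- parseMrsFilename("sub-06_ses-02_task-nback_acq-slaser_nuc-1H_voi-dlpfc_svs.nii.gz")
#' entities(p)
#' suffix(p)
#' @seealso [buildMrsFilename()], [expectedRelativePath()]
#' @export
parseMrsFilename <- function(name, lenient = FALSE) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    mrsStop("BadInput", "name must be a single non-empty string")
  ext <- NA_character_
  for (e in .EXTENSIONS) {
    if (endsWith(name, e)) { ext <- e; break }
  }
  if (is.na(ext))
    mrsStop("UnknownExtension", "'%s': extension must be .nii, .nii.gz or .json", name)
  stem <- substr(name, 1L, nchar(name) - nchar(ext))
  tokens <- strsplit(stem, "_", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || !nzchar(tokens[length(tokens)]))
    mrsStop("MissingSuffix", "'%s': no suffix before the extension", name)
  sfx <- tokens[length(tokens)]
  if (grepl("-", sfx, fixed = TRUE))
    mrsStop("MissingSuffix", "'%s': last token '%s' is an entity, not a suffix",
            name, sfx)
  if (!sfx %in% .SUFFIXES)
    mrsStop("UnknownSuffix", "'%s': unknown suffix '%s' (expected one of %s)",
            name, sfx, paste(.SUFFIXES, collapse = ", "))
  entTokens <- tokens[-length(tokens)]

  keys <- character(0); vals <- character(0)
  for (tok in entTokens) {
    dash <- regexpr("-", tok, fixed = TRUE)
    key <- if (dash > 0L) substr(tok, 1L, dash - 1L) else tok
    val <- if (dash > 0L) substr(tok, dash + 1L, nchar(tok)) else ""
    row <- match(key, .ENTITIES$key)
    if (is.na(row))
      mrsStop("UnknownEntity", "'%s': unknown entity key '%s'", name, key)
    if (key %in% keys)
      mrsStop("DuplicateEntity",
              "'%s': entity '%s' must be used only once in a filename", name, key)
    if (.ENTITIES$kind[row] == "label") {
      if (!grepl("^[A-Za-z0-9]+$", val))
        mrsStop("BadLabel", "'%s': value '%s' of entity '%s' is not alphanumeric",
                name, val, key)
    } else {
      if (!grepl("^[0-9]+$", val))
        mrsStop("BadIndex",
                "'%s': value '%s' of entity '%s' is not a nonnegative integer",
                name, val, key)
    }
    keys <- c(keys, key); vals <- c(vals, val)
  }
  if (length(keys) == 0L || keys[1L] != "sub")
    mrsStop("MissingSubject", "'%s': filename must begin with sub-<label>", name)
  ranks <- .ENTITIES$rank[match(keys, .ENTITIES$key)]
  if (is.unsorted(ranks, strictly = TRUE)) {
    if (!lenient)
      mrsStop("OrderViolation",
              "'%s': entities out of canonical order (%s)", name,
              paste(keys, collapse = ", "))
    mrsWarn("OrderViolation", "'%s': entities re-sorted into canonical order", name)
    ord <- order(ranks)
    keys <- keys[ord]; vals <- vals[ord]
  }
  new("MrsFilename", entities = stats::setNames(vals, keys),
      suffix = sfx, extension = ext)
}

#' Construct an MRS-BIDS filename
#'
#' Builds a filename string from entities, suffix and extension. Entities
#' may be given in any order; they are validated and emitted in the
#' canonical order, so the result always re-parses to an identical
#' [MrsFilename-class] (round-trip identity).
#'
#' @param entities Named character vector or named list of entity values;
#'   must include \code{sub}.
#' @param suffix One of \code{svs}, \code{mrsi}, \code{unloc}, \code{mrsref}.
#' @param extension One of \code{.nii}, \code{.nii.gz}, \code{.json}.
#' @return The filename as a single string.
#' @examples
#' buildMrsFilename(c(sub = "01", acq = "ecc"), "mrsref", ".nii.gz")
#' @export
buildMrsFilename <- function(entities, suffix, extension) {
  entities <- unlist(entities)
  keys <- names(entities)
  if (is.null(keys) || any(!nzchar(keys)))
    mrsStop("BadInput", "entities must be named")
  vals <- as.character(entities)
  bad <- setdiff(keys, .ENTITIES$key)
  if (length(bad))
    mrsStop("UnknownEntity", "unknown entity key '%s'", bad[1L])
  if (anyDuplicated(keys))
    mrsStop("DuplicateEntity", "entity '%s' given more than once",
            keys[duplicated(keys)][1L])
  rows <- match(keys, .ENTITIES$key)
  for (i in seq_along(keys)) {
    if (.ENTITIES$kind[rows[i]] == "label") {
      if (!grepl("^[A-Za-z0-9]+$", vals[i]))
        mrsStop("BadLabel", "value '%s' of entity '%s' is not alphanumeric",
                vals[i], keys[i])
    } else if (!grepl("^[0-9]+$", vals[i])) {
      mrsStop("BadIndex", "value '%s' of entity '%s' is not a nonnegative integer",
              vals[i], keys[i])
    }
  }
  if (!"sub" %in% keys)
    mrsStop("MissingSubject", "the sub entity is mandatory")
  if (length(suffix) != 1L || !suffix %in% .SUFFIXES)
    mrsStop("UnknownSuffix", "unknown suffix '%s'", as.character(suffix)[1L])
  if (length(extension) != 1L || !extension %in% .EXTENSIONS)
    mrsStop("UnknownExtension", "unknown extension '%s'",
            as.character(extension)[1L])
  ord <- order(.ENTITIES$rank[rows])
  paste0(paste(paste0(keys[ord], "-", vals[ord]), collapse = "_"),
         "_", suffix, extension)
}

#' Expected dataset-relative directory for a parsed filename
#'
#' MRS data files live under \code{sub-<label>/[ses-<label>]/mrs/}; the
#' subject (and session, when present) directory components must match the
#' filename entities.
#'
#' @param parsed A [MrsFilename-class].
#' @return The expected directory path, ending in \code{"mrs/"}.
#' @examples
#' expectedRelativePath(parseMrsFilename("sub-01_svs.nii"))
#' @export
expectedRelativePath <- function(parsed) {
  stopifnot(is(parsed, "MrsFilename"))
  e <- parsed@entities
  p <- paste0("sub-", e[["sub"]], "/")
  if ("ses" %in% names(e)) p <- paste0(p, "ses-", e[["ses"]], "/")
  paste0(p, "mrs/")
}

#' @rdname mrsbids-accessors
#' @export
setMethod("entities", "MrsFilename", function(x) x@entities)

#' @rdname mrsbids-accessors
#' @export
setMethod("suffix", "MrsFilename", function(x) x@suffix)

#' @rdname mrsbids-accessors
#' @export
setMethod("fileExt", "MrsFilename", function(x) x@extension)

#' Format a parsed filename back into its string form
#'
#' @param x A [MrsFilename-class].
#' @param ... Ignored.
#' @return The filename string.
#' @export
setMethod("format", "MrsFilename", function(x, ...) {
  buildMrsFilename(x@entities, x@suffix, x@extension)
})

setMethod("show", "MrsFilename", function(object) {
  cat("MrsFilename:", format(object), "\n")
  e <- object@entities
  cat(sprintf("  entities (%d): %s\n", length(e),
              paste(paste0(names(e), "=", e), collapse = ", ")))
  cat("  suffix:", object@suffix, "  extension:", object@extension, "\n")
  invisible(object)
})

## Identity key used for duplicate-acquisition detection: indices compare as
## integers (run-01 collides with run-1), labels verbatim, extension ignored.
collisionKey <- function(parsed) {
  e <- parsed@entities
  kinds <- .ENTITIES$kind[match(names(e), .ENTITIES$key)]
  vals <- as.character(e)
  idx <- kinds == "index"
  vals[idx] <- as.character(as.integer(vals[idx]))
  paste0(paste(names(e), vals, sep = "-", collapse = "_"),
         "_", parsed@suffix)
}
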