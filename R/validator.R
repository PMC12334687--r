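## Map a classed parse failure onto its catalogued rule id.
.PARSE_RULE <- c(
  mrsbids_UnknownEntity   = "MRS101",
  mrsbids_DuplicateEntity = "MRS102",
  mrsbids_OrderViolation  = "MRS103",
  mrsbids_BadLabel        = "MRS104",
  mrsbids_BadIndex        = "MRS105",
  mrsbids_MissingSuffix   = "MRS106",
  mrsbids_UnknownSuffix   = "MRS106",
  mrsbids_UnknownExtension = "MRS107",
  mrsbids_MissingSubject  = "MRS108"
)

parseRuleFor <- function(cond) {
  hit <- intersect(class(cond), names(.PARSE_RULE))
  if (length(hit)) .PARSE_RULE[[hit[1L]]] else "MRS106"
}

## Tokenize an inheritance fragment name (entities optional, no sub
## requirement): returns list(entities, suffix) or NULL.
parseFragmentName <- function(name) {
  ext <- if (endsWith(name, ".json")) ".json" else return(NULL)
  stem <- substr(name, 1L, nchar(name) - nchar(ext))
  tokens <- strsplit(stem, "_", fixed = TRUE)[[1L]]
  if (!length(tokens)) return(NULL)
  sfx <- tokens[length(tokens)]
  if (!sfx %in% .SUFFIXES) return(NULL)
  keys <- character(0); vals <- character(0)
  for (tok in tokens[-length(tokens)]) {
    dash <- regexpr("-", tok, fixed = TRUE)
    if (dash < 1L) return(NULL)
    key <- substr(tok, 1L, dash - 1L)
    if (!key %in% .ENTITIES$key || key %in% keys) return(NULL)
    keys <- c(keys, key)
    vals <- c(vals, substr(tok, dash + 1L, nchar(tok)))
  }
  list(entities = stats::setNames(vals, keys), suffix = sfx)
}

## Collect inheritance fragments for one data file: dataset root, subject
## and session levels, shallowest first. Only fragments with the same
## suffix whose entities are an equal-valued subset of the file's entities
## are merged (avoids cross-acquisition leakage).
inheritanceSources <- function(root, rec, parsed) {
  levels <- c("", rec$subDir)
  if (!is.na(rec$sesDir)) levels <- c(levels, file.path(rec$subDir, rec$sesDir))
  out <- list()
  for (lvl in levels) {
    dir <- if (nzchar(lvl)) file.path(root, lvl) else root
    jsons <- sort(list.files(dir, pattern = "\\.json$", recursive = FALSE),
                  method = "radix")
    jsons <- setdiff(jsons, "dataset_description.json")
    for (j in jsons) {
      frag <- parseFragmentName(j)
      if (is.null(frag)) next
      if (frag$suffix != parsed@suffix) next
      keys <- names(frag$entities)
      if (!all(keys %in% names(parsed@entities))) next
      if (!all(frag$entities == parsed@entities[keys])) next
      rel <- if (nzchar(lvl)) file.path(lvl, j) else j
      doc <- tryCatch(readSidecar(file.path(root, rel), context = parsed),
                      mrsbids_MalformedDocument = function(e) NULL)
      if (is.null(doc)) next
      doc@sourcePaths <- rel
      out[[length(out) + 1L]] <- doc
    }
  }
  out
}

stripBidsUri <- function(p) sub("^bids::?", "", p)

resolveReferenceSignal <- function(root, rec, target) {
  target <- stripBidsUri(target)
  cands <- c(file.path(root, target),
             file.path(root, dirname(rec$path), target))
  hit <- cands[file.exists(cands)]
  if (!length(hit)) return(FALSE)
  p <- tryCatch(parseMrsFilename(basename(hit[1L])),
                mrsbids_error = function(e) NULL)
  !is.null(p) && p@suffix == "mrsref"
}

resolveAnatomicalImage <- function(root, rec, target) {
  target <- stripBidsUri(target)
  if (file.exists(file.path(root, target))) return(TRUE)
  anatDirs <- file.path(root, rec$subDir,
                        c("anat", file.path(stats::na.omit(rec$sesDir), "anat")))
  any(file.exists(file.path(anatDirs, basename(target))))
}

#' Validate an MRS-BIDS dataset tree
#'
#' Runs the full rule set over a dataset: per data file, the filename
#' grammar, agreement between the file's location and the path implied by
#' its entities, sidecar resolution with inheritance merging, the sidecar
#' schema and conditional-requirement checks, and the container coherence
#' checks; at dataset level, the presence of
#' \code{dataset_description.json}, duplicate acquisition identities,
#' consistency of \code{BodyPart}/\code{BodyPartDetails} per voi label, and
#' resolution of every \code{ReferenceSignal} (must point at an existing
#' \code{mrsref} file) and \code{AnatomicalImage} cross-reference.
#'
#' A file whose name does not parse gets exactly its grammar issue and is
#' otherwise skipped; a file without a sidecar gets the missing-sidecar
#' error and no content checks. Issue paths are dataset-relative, so
#' validating a copied tree yields an identical report apart from the root.
#'
#' @param root Dataset root directory.
#' @param strict If \code{TRUE}, warnings are promoted to errors.
#' @param disabledRules Character vector of rule ids to suppress.
#' @return A [ValidationReport-class].
#' @examples
#' \donttest{
#' root <- file.path(tempdir(), "demo-ds")
#' generateDataset(fixtureSpec(nSubjects = 1, seed = 1), root)
#' rep <- validateDataset(root)
#' passed(rep)
#' }
#' @seealso [scanDataset()], [renderReport()], [generateDataset()]
#' @export
validateDataset <- function(root, strict = FALSE,
                            disabledRules = character(0)) {
  inv <- scanDataset(root)
  out <- list()
  add <- function(df) if (!is.null(df) && nrow(df)) out[[length(out) + 1L]] <<- df

  if (!inv@hasDatasetDescription)
    add(mrsIssue("MRS501", "dataset_description.json", "dataset",
                 "dataset_description.json is missing at the dataset root"))
  if (!inv@hasParticipants)
    add(mrsIssue("MRS509", "participants.tsv", "dataset",
                 "participants.tsv is missing at the dataset root"))

  parsedList <- vector("list", nrow(inv@dataFiles))
  mergedDocs <- vector("list", nrow(inv@dataFiles))

  for (i in seq_len(nrow(inv@dataFiles))) {
    rec <- inv@dataFiles[i, ]
    parsed <- tryCatch(parseMrsFilename(basename(rec$path)),
                       mrsbids_error = function(e) e)
    if (inherits(parsed, "condition")) {
      add(mrsIssue(parseRuleFor(parsed), rec$path, "filename",
                   conditionMessage(parsed)))
      next
    }
    parsedList[[i]] <- parsed

    expected <- expectedRelativePath(parsed)
    actual <- paste0(dirname(rec$path), "/")
    if (actual != expected)
      add(mrsIssue("MRS110", rec$path, "path",
                   sprintf("file is at '%s' but its entities imply '%s'",
                           actual, expected)))

    doc <- NULL
    if (is.na(rec$sidecar)) {
      add(mrsIssue("MRS502", rec$path, "sidecar",
                   "data file has no JSON sidecar"))
    } else {
      fileDoc <- tryCatch(readSidecar(file.path(root, rec$sidecar),
                                      context = parsed),
                          mrsbids_MalformedDocument = function(e) e)
      if (inherits(fileDoc, "condition")) {
        add(mrsIssue("MRS207", rec$sidecar, "json", conditionMessage(fileDoc)))
      } else {
        fileDoc@sourcePaths <- rec$sidecar
        frags <- inheritanceSources(root, rec, parsed)
        doc <- mergeInherited(c(frags, list(fileDoc)))
        doc@sourcePaths <- rec$sidecar  # issues cite the file-level sidecar
        add(validateSidecar(doc))
        add(checkConditionalRequirements(doc))
        mergedDocs[[i]] <- doc
      }
    }

    container <- tryCatch(readNiftiMrs(file.path(root, rec$path)),
                          mrsbids_NotNifti = function(e) e,
                          mrsbids_UnreadableExtension = function(e) e)
    if (inherits(container, "condition")) {
      rule <- if (inherits(container, "mrsbids_UnreadableExtension"))
        "MRS408" else "MRS401"
      add(mrsIssue(rule, rec$path, "container", conditionMessage(container)))
    } else {
      ccDoc <- if (!is.null(doc)) doc else
        sidecarDocument(list(), context = parsed)
      cc <- consistencyCheck(container@header, ccDoc)
      if (nrow(cc)) cc$file <- rec$path
      add(cc)
    }

    if (!is.null(doc)) {
      for (target in stripBidsUri(as.character(doc@content[["ReferenceSignal"]]))) {
        if (!resolveReferenceSignal(root, rec, target))
          add(mrsIssue("MRS506", rec$sidecar, "ReferenceSignal",
                       sprintf("'%s' does not resolve to an existing mrsref data file",
                               target)))
      }
      for (target in stripBidsUri(as.character(doc@content[["AnatomicalImage"]]))) {
        if (!resolveAnatomicalImage(root, rec, target))
          add(mrsIssue("MRS507", rec$sidecar, "AnatomicalImage",
                       sprintf("'%s' does not resolve to an existing anatomical image",
                               target)))
      }
    }
  }

  ## duplicate acquisition identities across the whole dataset
  ok <- !vapply(parsedList, is.null, logical(1))
  if (any(ok)) {
    keys <- vapply(parsedList[ok], collisionKey, character(1))
    paths <- inv@dataFiles$path[ok]
    for (k in unique(keys[duplicated(keys)])) {
      grp <- paths[keys == k]
      for (p in grp[-1L])
        add(mrsIssue("MRS504", p, "filename",
                     sprintf("acquisition identity collides with '%s'", grp[1L])))
    }
  }

  ## same voi label must map to the same BodyPart/BodyPartDetails
  voiTab <- list()
  for (i in seq_len(nrow(inv@dataFiles))) {
    p <- parsedList[[i]]; d <- mergedDocs[[i]]
    if (is.null(p) || is.null(d) || !"voi" %in% names(p@entities)) next
    lab <- p@entities[["voi"]]
    combo <- paste(c(d@content[["BodyPart"]], d@content[["BodyPartDetails"]]),
                   collapse = " / ")
    voiTab[[lab]] <- unique(c(voiTab[[lab]], combo))
  }
  for (lab in sort(names(voiTab))) {
    if (length(voiTab[[lab]]) > 1L)
      add(mrsIssue("MRS505", "(dataset)", paste0("voi-", lab),
                   sprintf("voi label '%s' maps to different tissue descriptions: %s",
                           lab, paste(voiTab[[lab]], collapse = " vs "))))
  }

  ## orphan sidecars
  for (s in setdiff(inv@sidecars, stats::na.omit(inv@dataFiles$sidecar)))
    add(mrsIssue("MRS503", s, "sidecar", "sidecar has no matching data file"))

  issues <- sortIssues(do.call(bindIssues, out))

  ## a field absent on MRSI is reported once, under its MRSI-specific rule
  if (nrow(issues)) {
    dup <- issues$rule_id == "MRS202" &
      paste(issues$file, issues$location) %in%
        paste(issues$file, issues$location)[issues$rule_id %in%
                                              c("MRS307", "MRS308")]
    issues <- issues[!dup, , drop = FALSE]
  }
  if (length(disabledRules))
    issues <- issues[!issues$rule_id %in% disabledRules, , drop = FALSE]
  if (strict)
    issues$severity[issues$severity == "warning"] <- "error"
  issues <- sortIssues(issues)

  new("ValidationReport", root = root, issues = issues, strict = strict)
}
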