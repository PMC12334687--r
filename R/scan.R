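## Read .bidsignore glob patterns (one per line, blank lines and comments
## skipped) and return the relative paths they match.
bidsIgnoreMatches <- function(root, relPaths) {
  ignoreFile <- file.path(root, ".bidsignore")
  if (!file.exists(ignoreFile) || !length(relPaths)) return(character(0))
  patterns <- readLines(ignoreFile, warn = FALSE)
  patterns <- trimws(patterns)
  patterns <- patterns[nzchar(patterns) & !startsWith(patterns, "#")]
  hit <- rep(FALSE, length(relPaths))
  for (p in patterns) {
    rx <- utils::glob2rx(sub("/$", "/*", p))
    hit <- hit | grepl(rx, relPaths) | grepl(rx, basename(relPaths))
  }
  relPaths[hit]
}

#' Inventory a BIDS dataset tree
#'
#' Walks the directory tree under \code{root} and collects everything the
#' validator needs: subject and session labels, MRS data files (files in
#' \code{mrs/} datatype directories) with their file-level sidecars,
#' stray sidecars, anatomical images, and dataset-level files.
#' \code{sourcedata/}, \code{derivatives/} and \code{code/} trees are
#' skipped, as are files matched by a \code{.bidsignore} at the root.
#' Unparseable filenames are kept in the inventory — the validator reports
#' them; nothing is dropped silently.
#'
#' @param root Path to the dataset root.
#' @return A [DatasetInventory-class].
#' @seealso [validateDataset()]
#' @export
scanDataset <- function(root) {
  if (!dir.exists(root))
    mrsStop("NotADirectory", "'%s' is not a readable directory", root)
  all <- list.files(root, recursive = TRUE, all.files = FALSE,
                    full.names = FALSE)
  all <- sort(all, method = "radix")
  topdir <- sub("/.*$", "", all)
  all <- all[!topdir %in% c("sourcedata", "derivatives", "code")]
  ignored <- bidsIgnoreMatches(root, all)
  files <- setdiff(all, ignored)

  subjects <- sort(unique(grep("^sub-[A-Za-z0-9]+$",
                               list.dirs(root, recursive = FALSE,
                                         full.names = FALSE),
                               value = TRUE)))
  subLabels <- sub("^sub-", "", subjects)
  sessions <- lapply(subjects, function(s) {
    ses <- grep("^ses-[A-Za-z0-9]+$",
                list.dirs(file.path(root, s), recursive = FALSE,
                          full.names = FALSE), value = TRUE)
    sub("^ses-", "", sort(ses))
  })
  names(sessions) <- subLabels

  inSub <- grepl("^sub-[A-Za-z0-9]+/", files)
  parts <- strsplit(files, "/", fixed = TRUE)
  datatype <- vapply(parts, function(p)
    if (length(p) >= 2L) p[length(p) - 1L] else "", character(1))
  isMrs <- inSub & datatype == "mrs"
  mrsFiles <- files[isMrs]
  isData <- grepl("\\.nii(\\.gz)?$", mrsFiles)
  dataPaths <- mrsFiles[isData]
  sidecars <- mrsFiles[grepl("\\.json$", mrsFiles)]

  sidecarFor <- function(p) {
    cand <- paste0(sub("\\.nii(\\.gz)?$", "", p), ".json")
    if (cand %in% sidecars) cand else NA_character_
  }
  dataFiles <- data.frame(
    path = dataPaths,
    subDir = vapply(strsplit(dataPaths, "/"), `[`, character(1), 1L),
    sesDir = vapply(strsplit(dataPaths, "/"), function(p)
      if (grepl("^ses-", p[2L])) p[2L] else NA_character_, character(1)),
    sidecar = vapply(dataPaths, sidecarFor, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  rownames(dataFiles) <- NULL

  anatFiles <- files[inSub & datatype == "anat" &
                       grepl("\\.nii(\\.gz)?$", files)]

  new("DatasetInventory",
      root = root, subjects = subLabels, sessions = sessions,
      dataFiles = dataFiles, sidecars = sidecars, anatFiles = anatFiles,
      hasDatasetDescription = file.exists(file.path(root,
                                                    "dataset_description.json")),
      hasParticipants = file.exists(file.path(root, "participants.tsv")),
      ignored = ignored)
}

#' @rdname mrsbids-accessors
#' @export
setMethod("dataFiles", "DatasetInventory", function(x) x@dataFiles)

setMethod("show", "DatasetInventory", function(object) {
  cat("DatasetInventory:", object@root, "\n")
  cat(sprintf("  %d subject(s); %d MRS data file(s); %d sidecar(s); %d anatomical image(s)\n",
              length(object@subjects), nrow(object@dataFiles),
              length(object@sidecars), length(object@anatFiles)))
  cat("  dataset_description.json:",
      if (object@hasDatasetDescription) "present" else "MISSING", "\n")
  invisible(object)
})
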