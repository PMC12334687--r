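## ---------------------------------------------------------------------------
## Sidecar field catalog
##
## One row per MRS sidecar field: requirement level, value type (with a
## fixed shape where one is mandated), units, and the suffixes the field
## applies to. Units are documentation plus sign/domain constraints only; no
## conversion is ever performed (the standard stores fixed units: MHz, Hz,
## s, mm, ppm).
## ---------------------------------------------------------------------------

.fieldRow <- function(name, level, type, units = "", shape = NA_integer_,
                      applies = "svs,mrsi,unloc,mrsref", condition = NA_character_) {
  data.frame(name = name, level = level, value_type = type, units = units,
             shape = shape, applicability = applies, condition = condition,
             stringsAsFactors = FALSE)
}

.FIELD_CATALOG <- do.call(rbind, list(
  ## MRS-relevant fields: required in every sidecar
  .fieldRow("ResonantNucleus", "required", "string_or_string_array",
            condition = "entity nuc present: value must match the nuc label"),
  .fieldRow("SpectrometerFrequency", "required", "number", units = "MHz"),
  .fieldRow("SpectralWidth", "required", "number", units = "Hz"),
  .fieldRow("EchoTime", "required", "number", units = "s"),
  ## recommended
  .fieldRow("WaterSuppression", "recommended", "boolean"),
  .fieldRow("NumberOfSpectralPoints", "recommended", "integer"),
  .fieldRow("MixingTime", "recommended", "number", units = "s"),
  .fieldRow("AcquisitionVoxelSize", "recommended", "number_array",
            units = "mm", shape = 3L),
  .fieldRow("ReferenceSignal", "recommended", "path_or_path_array",
            applies = "svs,mrsi,unloc"),
  .fieldRow("NumberOfTransients", "recommended", "integer",
            applies = "svs,unloc"),
  .fieldRow("MatrixSize", "recommended", "integer_array", shape = 3L,
            applies = "mrsi"),
  .fieldRow("VolumeAffineMatrix", "recommended", "square_matrix", shape = 4L,
            applies = "mrsi"),
  .fieldRow("EncodingTechnique", "recommended", "string", applies = "mrsi"),
  .fieldRow("AnatomicalImage", "recommended", "path_or_path_array"),
  ## scanner hardware (optional)
  .fieldRow("NumberReceiveCoilActiveElements", "optional", "integer"),
  .fieldRow("NumberTransmitCoilActiveElements", "optional", "integer"),
  ## sequence specifics (optional)
  .fieldRow("WaterSuppressionTechnique", "optional", "string"),
  .fieldRow("OuterVolumeSuppression", "optional", "boolean"),
  .fieldRow("B0ShimmingTechnique", "optional", "string"),
  .fieldRow("B1ShimmingTechnique", "optional", "string"),
  ## tissue description (optional; conditionally required with voi-<label>)
  .fieldRow("BodyPart", "optional", "string",
            condition = "entity voi present: field becomes required"),
  .fieldRow("BodyPartDetails", "optional", "string",
            condition = "entity voi present: field becomes required"),
  .fieldRow("BodyPartDetailsOntology", "optional", "uri"),
  ## further optional MRS fields
  .fieldRow("ChemicalShiftOffset", "optional", "number", units = "ppm"),
  .fieldRow("ChemicalShiftReference", "optional", "number", units = "ppm"),
  .fieldRow("EditTarget", "optional", "string_or_string_array"),
  .fieldRow("EditPulse", "optional", "string_or_string_array"),
  .fieldRow("EditCondition", "optional", "string_or_string_array"),
  .fieldRow("EchoAcquisition", "optional", "string_or_string_array"),
  .fieldRow("PulseSequenceTiming", "optional", "number_array_var", units = "s",
            condition = "PulseSequencePulses present: lengths must be equal"),
  .fieldRow("PulseSequencePulses", "optional", "string_array",
            condition = "requires PulseSequenceTiming of equal length"),
  .fieldRow("ReceiveGain", "optional", "number"),
  .fieldRow("PulseSequenceType", "optional", "string",
            condition = "entity acq present: field should describe the label")
))

#' MRS sidecar field catalog
#'
#' The machine-readable catalog of every MRS sidecar metadata field: its
#' requirement level (\code{required}, \code{recommended}, \code{optional}),
#' value type (with a fixed shape where one is mandated, e.g. length 3 for
#' \code{AcquisitionVoxelSize}, 4 for the 4x4 \code{VolumeAffineMatrix}),
#' units, the suffixes the field applies to, and any conditionality note.
#'
#' @return A \code{data.frame} with one row per field and columns
#'   \code{name}, \code{level}, \code{value_type}, \code{units},
#'   \code{shape}, \code{applicability}, \code{condition}.
#' @examples
#' cat <- sidecarCatalog()
#' subset(cat, level == "required")$name
#' @export
sidecarCatalog <- function() .FIELD_CATALOG

#' Look up one field specification
#'
#' @param name Field name, e.g. \code{"AcquisitionVoxelSize"}.
#' @return A one-row \code{data.frame} (see [sidecarCatalog()]), or an
#'   error if the field is unknown.
#' @examples
#' fieldSpec("VolumeAffineMatrix")
#' @export
fieldSpec <- function(name) {
  row <- .FIELD_CATALOG[.FIELD_CATALOG$name == name, , drop = FALSE]
  if (nrow(row) == 0L)
    mrsStop("UnknownField", "no such sidecar field: '%s'", name)
  row
}

fieldApplies <- function(row, sfx) {
  sfx %in% strsplit(row$applicability, ",", fixed = TRUE)[[1L]]
}

## ---------------------------------------------------------------------------
## Validation rule catalog
## ---------------------------------------------------------------------------

.ruleRow <- function(id, severity, summary) {
  data.frame(rule_id = id, severity = severity, summary = summary,
             stringsAsFactors = FALSE)
}

.RULES <- do.call(rbind, list(
  ## filename grammar
  .ruleRow("MRS101", "error", "Filename uses an entity key outside the MRS-BIDS vocabulary."),
  .ruleRow("MRS102", "error", "An entity key is used more than once in a filename."),
  .ruleRow("MRS103", "error", "Entities are not in the canonical order (sub, ses, task, acq, nuc, voi, rec, run, echo, inv; the tail order follows the published BIDS MRS template)."),
  .ruleRow("MRS104", "error", "An entity label contains characters outside [A-Za-z0-9]."),
  .ruleRow("MRS105", "error", "An entity index is not a nonnegative integer."),
  .ruleRow("MRS106", "error", "Filename lacks a suffix or uses one other than svs, mrsi, unloc, mrsref."),
  .ruleRow("MRS107", "error", "File extension is not .nii, .nii.gz or .json."),
  .ruleRow("MRS108", "error", "Filename does not begin with sub-<label>."),
  .ruleRow("MRS110", "error", "File location does not match the sub-<label>/[ses-<label>]/mrs/ path implied by its entities."),
  ## sidecar schema
  .ruleRow("MRS201", "error", "A required metadata field (ResonantNucleus, SpectrometerFrequency, SpectralWidth, EchoTime) is missing."),
  .ruleRow("MRS202", "warning", "A recommended metadata field applicable to this data type is missing."),
  .ruleRow("MRS203", "error", "A metadata value has the wrong JSON type."),
  .ruleRow("MRS204", "error", "A metadata array has the wrong shape (AcquisitionVoxelSize and MatrixSize must have length 3; VolumeAffineMatrix must be 4x4)."),
  .ruleRow("MRS205", "error", "A metadata value is outside its physical domain (e.g. nonpositive SpectralWidth or SpectrometerFrequency, negative EchoTime)."),
  .ruleRow("MRS206", "info", "Sidecar carries a key outside the MRS field catalog."),
  .ruleRow("MRS207", "error", "Sidecar is not parseable as JSON."),
  ## conditional requirements
  .ruleRow("MRS301", "error", "Entity nuc-<label> is used but ResonantNucleus is absent from the sidecar."),
  .ruleRow("MRS302", "error", "ResonantNucleus does not match the nuc-<label> entity value."),
  .ruleRow("MRS303", "error", "Entity voi-<label> is used but BodyPart is absent from the sidecar."),
  .ruleRow("MRS304", "error", "Entity voi-<label> is used but BodyPartDetails is absent from the sidecar."),
  .ruleRow("MRS305", "warning", "Entity acq-<label> is used but PulseSequenceType does not describe it."),
  .ruleRow("MRS306", "error", "PulseSequencePulses and PulseSequenceTiming differ in length (or the timing array is absent)."),
  .ruleRow("MRS307", "warning", "MatrixSize, VolumeAffineMatrix and EncodingTechnique are recommended for MRSI but absent."),
  .ruleRow("MRS308", "info", "NumberOfTransients is recommended for single-voxel and unlocalized acquisitions only, not MRSI."),
  .ruleRow("MRS309", "error", "BodyPartDetailsOntology is not a well-formed URI (scheme plus non-empty remainder)."),
  ## container
  .ruleRow("MRS401", "error", "Data file is not a readable NIfTI file."),
  .ruleRow("MRS402", "warning", "NIfTI-MRS file lacks the embedded JSON header extension."),
  .ruleRow("MRS403", "error", "Sidecar SpectralWidth is inconsistent with the container dwell time (relative difference > 1e-3)."),
  .ruleRow("MRS404", "warning", "Embedded header extension and sidecar disagree on SpectrometerFrequency or ResonantNucleus."),
  .ruleRow("MRS405", "warning", "Sidecar NumberOfSpectralPoints differs from the container time-axis extent."),
  .ruleRow("MRS406", "error", "Single-voxel (svs) data block has a spatial extent greater than 1."),
  .ruleRow("MRS407", "warning", "MRSI data block has no spatial extent greater than 1."),
  .ruleRow("MRS408", "error", "Embedded header extension is present but not valid JSON."),
  ## dataset level
  .ruleRow("MRS501", "error", "dataset_description.json is missing at the dataset root."),
  .ruleRow("MRS502", "error", "An MRS data file has no JSON sidecar."),
  .ruleRow("MRS503", "warning", "A sidecar has no matching data file (orphan)."),
  .ruleRow("MRS504", "error", "Two data files resolve to the same acquisition identity (entities plus suffix; indices compared as integers)."),
  .ruleRow("MRS505", "warning", "The same voi label maps to different BodyPart/BodyPartDetails across files."),
  .ruleRow("MRS506", "error", "ReferenceSignal does not resolve to an existing mrsref data file."),
  .ruleRow("MRS507", "error", "AnatomicalImage does not resolve to an existing anatomical image file."),
  .ruleRow("MRS509", "info", "participants.tsv is missing at the dataset root.")
))

#' Validation rule catalog
#'
#' Stable identifiers for every check the validator can emit, with the
#' default severity and a one-line summary. \code{exportRuleCatalog()}
#' writes the catalog as machine-readable JSON for documentation or for
#' building rule-disabling configs.
#'
#' @return A \code{data.frame} with columns \code{rule_id}, \code{severity},
#'   \code{summary}.
#' @examples
#' head(ruleCatalog())
#' @export
ruleCatalog <- function() .RULES

#' @rdname ruleCatalog
#' @param path File to write the JSON catalog to.
#' @return \code{exportRuleCatalog()} returns \code{path} invisibly.
#' @export
exportRuleCatalog <- function(path) {
  jsonlite::write_json(.RULES, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

ruleSeverity <- function(id) {
  s <- .RULES$severity[match(id, .RULES$rule_id)]
  if (anyNA(s)) mrsStop("UnknownRule", "unknown rule id '%s'", id[is.na(s)][1L])
  s
}

## One issue row; severity defaults to the rule's catalogued severity.
mrsIssue <- function(rule_id, file, location, message,
                     severity = ruleSeverity(rule_id)) {
  data.frame(rule_id = rule_id, severity = severity, file = file,
             location = location, message = message, stringsAsFactors = FALSE)
}

emptyIssues <- function() {
  data.frame(rule_id = character(0), severity = character(0),
             file = character(0), location = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

bindIssues <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (!length(parts)) return(emptyIssues())
  do.call(rbind, parts)
}

sortIssues <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$file, df$rule_id, df$location, df$message,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}
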