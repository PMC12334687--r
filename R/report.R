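#' @rdname mrsbids-accessors
#' @export
setMethod("issues", "ValidationReport", function(x) x@issues)

#' @rdname mrsbids-accessors
#' @export
setMethod("severityCounts", "ValidationReport", function(x) {
  c(error = sum(x@issues$severity == "error"),
    warning = sum(x@issues$severity == "warning"),
    info = sum(x@issues$severity == "info"))
})

#' @rdname mrsbids-accessors
#' @export
setMethod("passed", "ValidationReport", function(x) {
  !any(x@issues$severity == "error")
})

setMethod("show", "ValidationReport", function(object) {
  n <- severityCounts(object)
  cat("ValidationReport:", object@root,
      if (object@strict) "(strict)" else "", "\n")
  cat(sprintf("  %d error(s), %d warning(s), %d info notice(s)\n",
              n[["error"]], n[["warning"]], n[["info"]]))
  cat("  result:", if (passed(object)) "PASS" else "FAIL", "\n")
  invisible(object)
})

#' Render a validation report
#'
#' \code{format = "text"} produces a human-readable report grouped by file
#' with severity tags, a counts section and a pass/fail summary line.
#' \code{format = "json"} produces a stable machine-readable document
#' (root, counts, passed, and the issue table with rule_id, severity, file,
#' location, message). Both renderings are byte-identical across repeated
#' runs on the same tree.
#'
#' @param report A [ValidationReport-class].
#' @param format \code{"text"} or \code{"json"}.
#' @return A single string.
#' @examples
#' rep <- new("ValidationReport", root = ".", strict = FALSE,
#'            issues = mrsbids:::emptyIssues())
#' cat(renderReport(rep))
#' @export
renderReport <- function(report, format = c("text", "json")) {
  stopifnot(is(report, "ValidationReport"))
  if (!is.character(format) || !format[1L] %in% c("text", "json"))
    mrsStop("UnknownFormat", "format must be 'text' or 'json'")
  format <- format[1L]
  df <- report@issues
  n <- severityCounts(report)
  if (format == "json") {
    payload <- list(
      root = report@root,
      strict = report@strict,
      passed = passed(report),
      counts = as.list(n),
      issues = df)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  }
  lines <- c(sprintf("MRS-BIDS validation: %s%s", report@root,
                     if (report@strict) " [strict]" else ""))
  for (f in unique(df$file)) {
    lines <- c(lines, paste0("  ", f))
    sel <- df[df$file == f, , drop = FALSE]
    lines <- c(lines, sprintf("    [%s] %s (%s): %s",
                              toupper(sel$severity), sel$rule_id,
                              sel$location, sel$message))
  }
  lines <- c(lines,
             sprintf("Counts: %d error(s), %d warning(s), %d info notice(s)",
                     n[["error"]], n[["warning"]], n[["info"]]),
             sprintf("Result: %s", if (passed(report)) "pass" else "fail"))
  paste0(paste(lines, collapse = "\n"), "\n")
}
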