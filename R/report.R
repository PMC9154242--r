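# Unified validation report: standard-keyword and custom-keyword failures in
# one ordered error list. `valid` is true iff the list is empty.

#' Construct a validation report
#'
#' @param errors Ordered list of structured errors (fields `keyword`,
#'   `instancePath`, `message`, `params`).
#' @return A `validation_report`.
#' @export
validation_report <- function(errors = list()) {
  structure(list(valid = length(errors) == 0L, errors = errors),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("<validation_report: valid>\n")
  } else {
    cat("<validation_report: INVALID, ", length(x$errors), " error(s)>\n",
        sep = "")
    for (e in x$errors)
      cat("  [", e$keyword, "] at '", e$instancePath, "': ", e$message,
          "\n", sep = "")
  }
  invisible(x)
}

#' One row per error, as a data frame
#'
#' @param x A `validation_report`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return Data frame with columns `keyword`, `instancePath`, `message`.
#' @export
as.data.frame.validation_report <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(
    keyword = vapply(x$errors, function(e) e$keyword, character(1)),
    instancePath = vapply(x$errors, function(e) e$instancePath, character(1)),
    message = vapply(x$errors, function(e) e$message, character(1)),
    stringsAsFactors = FALSE)
}

#' Serialize a report to its canonical JSON wire form
#'
#' The same serializer backs the CLI and both HTTP endpoints, so the three
#' interfaces emit byte-identical reports for the same inputs:
#' `{"valid": bool, "errors": [{"keyword", "instancePath", "message",
#' "params"}]}`.
#'
#' @param report A `validation_report`.
#' @return A length-one character JSON string.
#' @export
report_to_json <- function(report) {
  errs <- lapply(report$errors, function(e) {
    list(keyword = e$keyword, instancePath = e$instancePath,
         message = e$message,
         params = e$params %||% structure(list(), names = character(0)))
  })
  as.character(jsonlite::toJSON(list(valid = report$valid, errors = errs),
                                auto_unbox = TRUE, null = "null",
                                digits = NA))
}
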