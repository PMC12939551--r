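# JSON result serialization shared by the test functions and the CLI.

#' Convert a test result to a plain report list
#'
#' Flattens an `"ifra_test"` or `"competitor_test"` object into a named
#' list of scalar fields (plus package version) suitable for JSON
#' serialization.
#'
#' @param result An `"ifra_test"` or `"competitor_test"` object.
#' @return A named list.
#' @export
as_report <- function(result) {
  stopifnot(inherits(result, c("ifra_test", "competitor_test")))
  out <- unclass(result)
  out <- out[!vapply(out, is.null, logical(1))]
  out$package_version <- as.character(utils::packageVersion("ifratest"))
  out
}

#' Write a test result to a JSON file
#'
#' @param result An `"ifra_test"` or `"competitor_test"` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(result, path) {
  jsonlite::write_json(as_report(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
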