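# Sample containers and file readers.

#' Construct a lifetime sample
#'
#' Validates a vector of non-negative lifetimes and wraps it with its order
#' statistics and mean.  All statistics in the package accept either a plain
#' numeric vector or a `lifetime_sample`.
#'
#' @param values Numeric vector of non-negative observations, length at least
#'   2, with at least one strictly positive value (the scale-invariant
#'   statistics divide by the sample mean).
#' @return An object of class `"lifetime_sample"`: a list with `values`,
#'   `sorted`, `n` and `mean`.
#' @examples
#' s <- lifetime_sample(c(3, 1, 2))
#' s$sorted
#' @export
lifetime_sample <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("lifetimes must be finite and non-missing", call. = FALSE)
  if (any(values < 0)) stop("lifetimes must be non-negative", call. = FALSE)
  if (all(values == 0)) stop("all observations are zero; sample mean must be positive", call. = FALSE)
  structure(list(values = values, sorted = sort(values),
                 n = length(values), mean = mean(values)),
            class = "lifetime_sample")
}

#' @export
print.lifetime_sample <- function(x, ...) {
  cat(sprintf("Lifetime sample: N = %d, mean = %.4g, range = [%.4g, %.4g]\n",
              x$n, x$mean, x$sorted[1L], x$sorted[x$n]))
  invisible(x)
}

.as_sample <- function(x) {
  if (inherits(x, "lifetime_sample")) x else lifetime_sample(x)
}

#' Construct a right-censored sample
#'
#' Pairs observed times `Z_i = min(X_i, T_i)` with event indicators
#' `delta_i = 1{X_i <= T_i}` (1 = observed failure, 0 = right-censored).
#'
#' @param time Non-negative observed times.
#' @param event Event indicators in `{0, 1}` (or logical), same length as
#'   `time`.
#' @return An object of class `"censored_sample"` with elements `time`,
#'   `event` and `n`.  A sample with no events is permitted but flagged by
#'   downstream estimators.
#' @export
censored_sample <- function(time, event) {
  time <- as.numeric(time)
  if (is.logical(event)) event <- as.numeric(event)
  event <- as.numeric(event)
  if (length(time) != length(event))
    stop("`time` and `event` must have the same length", call. = FALSE)
  if (length(time) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(time) || any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stop("event indicators must be 0 or 1", call. = FALSE)
  structure(list(time = time, event = event, n = length(time)),
            class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  cat(sprintf("Right-censored sample: N = %d, events = %d (%.0f%% censored)\n",
              x$n, sum(x$event), 100 * mean(x$event == 0)))
  invisible(x)
}

#' Read lifetimes from a file
#'
#' Reads either a plain-text file with one non-negative value per row
#' (blank lines ignored), or — with `censored = TRUE` — a CSV with columns
#' `time` and `event`.
#'
#' @param path Path to the input file.
#' @param censored If `TRUE`, parse a two-column `time,event` CSV and return
#'   a [censored_sample()]; otherwise return a [lifetime_sample()].
#' @return A `lifetime_sample` or `censored_sample`.
#' @export
read_lifetimes <- function(path, censored = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (censored) {
    df <- utils::read.csv(path)
    if (!all(c("time", "event") %in% names(df)))
      stop("censored input must be a CSV with columns `time` and `event`", call. = FALSE)
    return(censored_sample(df$time, df$event))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # tolerate a single-column CSV with a header line
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1L]))) &&
      tolower(gsub("\"", "", lines[1L])) %in% c("value", "values", "time", "x", "lifetime"))
    lines <- lines[-1L]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric value %s at data row %d of %s",
                 shQuote(lines[bad]), bad, path), call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0)[1L]
    stop(sprintf("negative lifetime at data row %d of %s", bad, path), call. = FALSE)
  }
  lifetime_sample(vals)
}
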