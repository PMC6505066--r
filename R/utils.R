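#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an ISO-8601 datetime column to POSIXct (UTC)
#'
#' Day boundaries throughout the package are the calendar dates of the
#' recorded datetimes; no time-zone normalization is applied (single-system
#' assumption), so all parsing pins to UTC for determinism.
#' @noRd
pd_parse_datetime <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                            "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

#' @noRd
pd_date <- function(x) as.Date(x, tz = "UTC")

#' Stop with a classed condition so callers can test error categories
#' @noRd
pd_stop <- function(msg, class) {
  stop(structure(class = c(class, "patientday_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a delimited table (comma-separated, header row, UTF-8)
#'
#' Thin wrapper around [data.table::fread()] pinned to the package's
#' external-interface contract.
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
pd_read_table <- function(path) {
  if (!file.exists(path)) pd_stop(sprintf("input file not found: %s", path),
                                  "pd_config_error")
  fread(path, sep = ",", header = TRUE, colClasses = NULL,
        na.strings = c("", "NA"), encoding = "UTF-8")
}

#' Write a delimited table with stable column order and row order
#'
#' Output is byte-stable: fixed separator, ISO-8601 datetimes, no quoting
#' beyond what commas require.
#'
#' @param x A data.frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
pd_write_table <- function(x, path) {
  x <- as.data.table(x)
  for (col in names(x)) {
    if (inherits(x[[col]], "POSIXct"))
      data.table::set(x, j = col, value = format(x[[col]], "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    else if (inherits(x[[col]], "Date"))
      data.table::set(x, j = col, value = format(x[[col]], "%Y-%m-%d"))
  }
  fwrite(x, path, sep = ",", quote = "auto", na = "", eol = "\n")
  invisible(path)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
binom_ci_exact <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}
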