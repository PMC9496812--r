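#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all reported percentages:
#' 0.005 rounds to 0.01 rather than to the nearest even digit.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a denominator
#'
#' `100 * numerator / denominator`, rounded half-up to two decimals — the
#' convention used for every percentage the pipeline reports.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return percentage on the 0–100 scale, two decimals.
#' @examples
#' cla_percentage(6942, 13726) # 50.58
#' @export
cla_percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("cla_percentage(): denominator must be > 0", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, 2)
}

#' Median, interquartile range and range of per-address physician counts
#'
#' Quartiles use linear interpolation of order statistics at p = 0.25 / 0.75
#' (the default type-7 method of [stats::quantile()]); this choice is fixed
#' and documented because integer-looking IQRs do not disambiguate it.
#'
#' @param counts non-empty integer vector.
#' @return named numeric vector `(median, q1, q3, min, max)`.
#' @examples
#' median_iqr_range(c(1, 2, 2, 3, 5, 23)) # median 2.5, IQR 2-4.5, range 1-23
#' @export
median_iqr_range <- function(counts) {
  if (length(counts) == 0) stop("median_iqr_range(): empty input", call. = FALSE)
  q <- stats::quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
  c(median = stats::median(counts), q1 = q[1], q3 = q[2],
    min = min(counts), max = max(counts))
}

# Internal CSV wrappers: UTF-8, header row, RFC-4180 quoting.
read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", encoding = "UTF-8")
}

#' Write a table to CSV
#'
#' UTF-8, header row, RFC-4180 quoting; used for every pipeline output so
#' that [read_table()] is its exact inverse.
#'
#' @param rows a data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path CSV file path.
#' @return data.frame of character columns.
#' @export
read_table <- function(path) read_csv_strict(path)

blank <- function(x) is.na(x) | !nzchar(trimws(x))

collapse_ids <- function(x) paste(x, collapse = ";")
split_ids <- function(x) if (!nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
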