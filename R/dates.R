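#' FAERS date handling
#'
#' FAERS emits dates as digit strings: `YYYYMMDD` (full), `YYYYMM` or `YYYY`
#' (partial). Partial dates carry a usable reporting year but no usable day,
#' so they feed year-level summaries while day-resolution arithmetic (onset
#' intervals, dedup recency) treats them as missing.
#'
#' @param x Character vector of FAERS date strings.
#' @return `faers_date_parse()` returns a [Date] vector (`NA` unless the
#'   input is a valid full 8-digit calendar date); `faers_date_year()` an
#'   integer vector of years (`NA` only when not even a year is present).
#' @examples
#' faers_date_parse(c("20200229", "20230230", "202003", NA))
#' faers_date_year(c("20200229", "202003", "2021", "bad"))
#' @name faers-dates
NULL

#' @rdname faers-dates
#' @export
faers_date_parse <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  if (any(full)) {
    parsed <- as.Date(x[full], format = "%Y%m%d")
    # as.Date() rolls some impossible dates; round-trip to catch them
    ok <- !is.na(parsed) & format(parsed, "%Y%m%d") == x[full]
    parsed[!ok] <- NA
    out[full] <- parsed
  }
  out
}

#' @rdname faers-dates
#' @export
faers_date_year <- function(x) {
  x <- as.character(x)
  yr <- rep(NA_integer_, length(x))
  has_year <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  yr[has_year] <- as.integer(substr(x[has_year], 1L, 4L))
  yr
}

# Count of full-date strings that fail calendar validation (used by readers
# to report how many date fields were blanked).
invalid_full_dates <- function(x) {
  x <- as.character(x)
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  sum(full & is.na(faers_date_parse(x)))
}

# TRUE where the string is date-shaped (4, 6 or 8 digits) and, if full,
# a real calendar date. Anything else is treated as missing on read.
valid_faers_date <- function(x) {
  x <- as.character(x)
  shaped <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  full <- shaped & nchar(x) == 8L
  shaped[full] <- !is.na(faers_date_parse(x[full]))
  shaped
}

date_to_faers <- function(d) {
  ifelse(is.na(d), NA_character_, format(d, "%Y%m%d"))
}
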