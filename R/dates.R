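#' Parse FAERS-style partial dates
#'
#' FAERS encodes dates as `YYYYMMDD` strings, with truncation to `YYYYMM` or
#' `YYYY` when the reporter supplied only partial information. This parser
#' classifies each string by its precision and never throws: anything that is
#' not a valid full, month- or year-precision date (including impossible
#' calendar dates and years outside 1900--2100) is returned with precision
#' `"invalid"`.
#'
#' @param x Character vector of raw date strings.
#'
#' @return A tibble with one row per input and columns `raw`, `year`,
#'   `month`, `day` (integer, `NA` where absent), `precision` (one of
#'   `"day"`, `"month"`, `"year"`, `"invalid"`) and `date` (a `Date`, `NA`
#'   unless precision is `"day"`).
#'
#' @examples
#' parse_faers_date(c("20230115", "202301", "2023", "20231340", ""))
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringr::str_trim(x)
  nx <- length(x)

  year <- month <- day <- rep(NA_integer_, nx)
  precision <- rep("invalid", nx)
  date <- rep(as.Date(NA), nx)

  d8 <- stringr::str_detect(x, "^[0-9]{8}$")
  d6 <- stringr::str_detect(x, "^[0-9]{6}$")
  d4 <- stringr::str_detect(x, "^[0-9]{4}$")

  yr <- rep(NA_integer_, nx)
  yr[d8 | d6 | d4] <- as.integer(substr(x[d8 | d6 | d4], 1, 4))
  mo <- rep(NA_integer_, nx)
  mo[d8 | d6] <- as.integer(substr(x[d8 | d6], 5, 6))
  dy <- rep(NA_integer_, nx)
  dy[d8] <- as.integer(substr(x[d8], 7, 8))

  yr_ok <- !is.na(yr) & yr >= 1900 & yr <= 2100
  mo_ok <- !is.na(mo) & mo >= 1 & mo <= 12

  # full dates must survive a round trip through Date (catches Feb 30 etc.)
  full <- d8 & yr_ok & mo_ok
  if (any(full)) {
    dt <- as.Date(x[full], format = "%Y%m%d")
    keep <- !is.na(dt)
    idx <- which(full)[keep]
    precision[idx] <- "day"
    year[idx] <- yr[idx]
    month[idx] <- mo[idx]
    day[idx] <- dy[idx]
    date[idx] <- dt[keep]
  }

  mon <- d6 & yr_ok & mo_ok
  precision[mon] <- "month"
  year[mon] <- yr[mon]
  month[mon] <- mo[mon]

  yonly <- d4 & yr_ok
  precision[yonly] <- "year"
  year[yonly] <- yr[yonly]

  tibble(
    raw = x, year = year, month = month, day = day,
    precision = precision, date = date
  )
}

#' Extract the report year from raw FAERS date strings
#'
#' Returns the calendar year for any string with at least year precision,
#' `NA` otherwise.
#'
#' @param x Character vector of raw date strings.
#' @return Integer vector of years.
#' @export
faers_date_year <- function(x) {
  parse_faers_date(x)$year
}

# internal: "YYYYMMDD" -> Date (NA unless day precision)
faers_date_to_date <- function(x) {
  parse_faers_date(x)$date
}

# internal: Date -> "YYYYMMDD"
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(d)] <- ""
  out
}
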