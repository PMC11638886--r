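#' Convert reported ages to years
#'
#' FAERS ages come with a unit code (`AGE_COD`). Values are converted to
#' years using calendar-average factors; a missing or unrecognized code is
#' taken to mean years (the dominant convention in the raw files). Results
#' that are not positive or are at least 150 years are implausible and
#' returned as `NA`.
#'
#' Conversion factors: `YR` x1, `DEC` x10, `MON` /12, `WK` /52.1775,
#' `DY` /365.25, `HR` /8766.
#'
#' @param value Numeric vector of reported ages.
#' @param unit_code Character vector of FAERS age unit codes.
#' @return Numeric vector of ages in years (`NA` where unknown/implausible).
#' @examples
#' normalize_age(c(24, 5, 200), c("MON", "DEC", "YR"))
#' @export
normalize_age <- function(value, unit_code = "YR") {
  value <- suppressWarnings(as.numeric(value))
  unit_code <- toupper(stringr::str_trim(as.character(unit_code)))
  unit_code <- dplyr::if_else(is.na(unit_code) | unit_code == "", "YR", unit_code)
  factor <- dplyr::case_match(
    unit_code,
    "YR" ~ 1, "DEC" ~ 10, "MON" ~ 1 / 12, "WK" ~ 1 / 52.1775,
    "DY" ~ 1 / 365.25, "HR" ~ 1 / 8766,
    .default = 1
  )
  out <- value * factor
  out[!is.finite(out) | out <= 0 | out >= 150] <- NA_real_
  out
}

#' Convert reported weights to kilograms
#'
#' Unit codes: `KG` x1, `LBS` x0.453592, `GMS` /1000; missing code means kg.
#' Nonpositive or >= 700 kg results are implausible and returned as `NA`.
#'
#' @param value Numeric vector of reported weights.
#' @param unit_code Character vector of FAERS weight unit codes.
#' @return Numeric vector of weights in kg.
#' @export
normalize_weight <- function(value, unit_code = "KG") {
  value <- suppressWarnings(as.numeric(value))
  unit_code <- toupper(stringr::str_trim(as.character(unit_code)))
  unit_code <- dplyr::if_else(is.na(unit_code) | unit_code == "", "KG", unit_code)
  factor <- dplyr::case_match(
    unit_code,
    "KG" ~ 1, "LBS" ~ 0.453592, "GMS" ~ 1e-3,
    .default = 1
  )
  out <- value * factor
  out[!is.finite(out) | out <= 0 | out >= 700] <- NA_real_
  out
}

#' Normalize FAERS sex codes
#'
#' Maps `F`/`M` (any case) to `"female"`/`"male"`; everything else becomes
#' `"unknown"`.
#'
#' @param x Character vector of raw sex codes.
#' @return Character vector in `{"female", "male", "unknown"}`.
#' @export
normalize_sex <- function(x) {
  x <- toupper(stringr::str_trim(as.character(x)))
  dplyr::case_match(x, "F" ~ "female", "M" ~ "male", .default = "unknown")
}

#' Assign analysis age bands
#'
#' The subgroup bands are `under45` (age < 45), `45to59` (45 <= age <= 59)
#' and `over59` (age > 59); unknown ages map to `NA` and are excluded from
#' age-stratified analyses.
#'
#' @param age_years Numeric vector of ages in years.
#' @return Character vector of band labels.
#' @export
age_band <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ NA_character_,
    age_years < 45 ~ "under45",
    age_years <= 59 ~ "45to59",
    TRUE ~ "over59"
  )
}

# internal: canonical drug-name normalization for synonym matching.
# Case-folds, turns punctuation into spaces, and drops dosage/formulation
# tokens ("30mg", "tablet", "er", ...). Deliberately exact (no fuzzy match).
normalize_drug_name <- function(x) {
  stop_tokens <- c(
    "mg", "mcg", "g", "ml", "l", "iu", "tab", "tabs", "tablet", "tablets",
    "cap", "caps", "capsule", "capsules", "er", "xr", "sr", "cr", "la",
    "dr", "od", "oral", "solution", "injection", "hcl", "hydrochloride",
    "besylate", "succinate", "unknown"
  )
  x <- tolower(as.character(x))
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
  tokens <- stringr::str_split(stringr::str_squish(x), stringr::fixed(" "))
  vapply(tokens, function(tk) {
    drop <- tk %in% stop_tokens |
      stringr::str_detect(tk, "^[0-9]+([.][0-9]+)?(mg|mcg|g|ml|l|iu)?$")
    paste(tk[!drop], collapse = " ")
  }, character(1))
}
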