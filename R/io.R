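# Canonical column names per table, with legacy (ISR-era) variants mapped.
# FAERS switched from ISR/CASE identifiers to PRIMARYID/CASEID in 2012 Q4.
faers_column_map <- function() {
  c(
    isr = "primaryid", "case" = "caseid", case_id = "caseid",
    gndr_cod = "sex", i_f_cod = "i_f_code"
  )
}

faers_required_columns <- function() {
  list(
    demo = c("primaryid", "caseid", "fda_dt"),
    drug = c("primaryid", "role_cod", "drugname"),
    reac = c("primaryid", "pt"),
    ther = c("primaryid", "start_dt"),
    outc = c("primaryid", "outc_cod"),
    indi = c("primaryid")
  )
}

#' Read a FAERS quarterly ASCII directory
#'
#' Reads the `'$'`-delimited quarterly tables (DEMO, DRUG, REAC, THER and,
#' when present, OUTC, INDI) from a directory, normalizes column names to
#' one canonical lower-case schema (legacy `ISR`/`CASE` identifiers are
#' mapped to `primaryid`/`caseid`), and coerces identifier columns to
#' numeric. Rows whose field count does not match the header are rejected,
#' counted, and reported -- never silently dropped.
#'
#' @param directory Directory containing files named like `DEMO24Q1.txt`.
#' @param required Tables that must be present; a missing one is an error.
#' @return An object of class `faers_tables`: a named list of tibbles with
#'   attributes `rejected` (tibble of per-table rejected line counts) and
#'   `source` (the directory).
#' @export
read_faers_quarter <- function(directory,
                               required = c("demo", "drug", "reac")) {
  if (!dir.exists(directory)) {
    abort(sprintf("directory '%s' does not exist", directory),
      class = "faersignal_io_error"
    )
  }
  files <- list.files(directory, pattern = "\\.txt$", ignore.case = TRUE,
                      full.names = TRUE)
  known <- c("demo", "drug", "reac", "ther", "outc", "indi", "rpsr")
  tag <- tolower(stringr::str_extract(
    toupper(basename(files)), "^(DEMO|DRUG|REAC|THER|OUTC|INDI|RPSR)"
  ))
  files <- files[!is.na(tag)]
  tag <- tag[!is.na(tag)]

  missing <- setdiff(required, tag)
  if (length(missing)) {
    abort(
      sprintf(
        "missing mandatory FAERS table(s) in '%s': %s",
        directory, toString(toupper(missing))
      ),
      class = "faersignal_io_error"
    )
  }

  tables <- list()
  rejected <- tibble(table = character(0), n_rejected = integer(0))
  for (i in seq_along(files)) {
    nm <- tag[i]
    if (!nm %in% known || nm %in% names(tables)) next
    parsed <- read_faers_table(files[i], nm)
    tables[[nm]] <- parsed$table
    rejected <- bind_rows(rejected,
      tibble(table = nm, n_rejected = parsed$n_rejected))
  }
  if (sum(rejected$n_rejected) > 0) {
    inform(sprintf(
      "read_faers_quarter: rejected %d malformed row(s) (%s)",
      sum(rejected$n_rejected),
      paste(sprintf("%s: %d", rejected$table[rejected$n_rejected > 0],
        rejected$n_rejected[rejected$n_rejected > 0]), collapse = ", ")
    ))
  }
  structure(tables,
    rejected = rejected, source = directory, class = "faers_tables"
  )
}

# internal: read one '$'-delimited table, mapping schema variants
read_faers_table <- function(path, name) {
  df <- suppressWarnings(readr::read_delim(
    path,
    delim = "$", quote = "", na = character(),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(df)
  n_rejected <- 0L
  if (nrow(probs)) {
    bad_rows <- unique(probs$row) - 1L # problems() rows are file lines
    bad_rows <- bad_rows[bad_rows >= 1 & bad_rows <= nrow(df)]
    n_rejected <- length(bad_rows)
    if (n_rejected) df <- df[-bad_rows, ]
  }
  nms <- tolower(names(df))
  map <- faers_column_map()
  hit <- nms %in% names(map)
  nms[hit] <- unname(map[nms[hit]])
  names(df) <- nms

  need <- faers_required_columns()[[name]]
  if (!is.null(need)) {
    miss <- setdiff(need, nms)
    if (length(miss)) {
      abort(
        sprintf(
          "unrecognized schema for %s table '%s': missing column(s) %s",
          toupper(name), basename(path), toString(miss)
        ),
        class = "faersignal_schema_error"
      )
    }
  }
  for (col in intersect(c("primaryid", "caseid"), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in intersect(
    c("drug_seq", "dsg_drug_seq", "indi_drug_seq", "age", "wt"), names(df)
  )) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  list(table = as_tibble(df), n_rejected = n_rejected)
}

#' Count rejected rows from a read
#'
#' @param tables A `faers_tables` object from [read_faers_quarter()].
#' @return Tibble with columns `table`, `n_rejected`.
#' @export
faers_rejected <- function(tables) {
  attr(tables, "rejected") %||% tibble(table = character(0),
                                       n_rejected = integer(0))
}

#' Deduplicate cases by the FDA rule
#'
#' FAERS re-submits updated versions of the same safety report. For each
#' CASEID the surviving record is the one with the most recent FDA receipt
#' date; when FDA dates tie, the numerically larger PRIMARYID wins. Records
#' with a missing or unparseable FDA date are treated as the oldest
#' possible, so any dated version supersedes them. The operation is
#' idempotent and invariant to input row order.
#'
#' @param demo Tibble of case records with columns `primaryid`, `caseid`,
#'   `fda_dt`.
#' @return The surviving rows of `demo`, ordered by `primaryid`.
#' @examples
#' dedup_cases(tibble::tibble(
#'   primaryid = c(1, 2), caseid = c(9, 9),
#'   fda_dt = c("20200101", "20210101")
#' ))
#' @export
dedup_cases <- function(demo) {
  demo <- as_tibble(demo)
  for (col in c("primaryid", "caseid", "fda_dt")) {
    if (!col %in% names(demo)) {
      abort(sprintf("`demo` lacks required column '%s'", col))
    }
  }
  fda <- as.character(demo$fda_dt)
  fda[is.na(fda) | !stringr::str_detect(fda, "^[0-9]{8}$")] <- "00000000"
  demo %>%
    mutate(.fda_key = fda) %>%
    arrange(caseid, dplyr::desc(.fda_key), dplyr::desc(primaryid)) %>%
    distinct(caseid, .keep_all = TRUE) %>%
    select(-".fda_key") %>%
    arrange(primaryid)
}

#' Deduplicate a full multi-table dataset
#'
#' Applies [dedup_cases()] to the DEMO table and drops all child-table rows
#' (DRUG, REAC, THER, OUTC, INDI) belonging to superseded PRIMARYIDs.
#'
#' @param tables Named list of tibbles (as from [read_faers_quarter()] or
#'   `generate_faers()$tables`).
#' @return A list like `tables` with superseded versions removed, plus an
#'   attribute `removed`: the superseded DEMO rows.
#' @export
dedup_faers <- function(tables) {
  if (inherits(tables, "faers_dataset")) tables <- tables$tables
  if (!"demo" %in% names(tables)) abort("`tables` must contain a demo table")
  survivors <- dedup_cases(tables$demo)
  removed <- anti_join(as_tibble(tables$demo), survivors,
    by = "primaryid"
  )
  out <- tables
  out$demo <- survivors
  keep <- survivors["primaryid"]
  for (nm in setdiff(names(out), "demo")) {
    out[[nm]] <- semi_join(as_tibble(out[[nm]]), keep, by = "primaryid")
  }
  attr(out, "removed") <- removed
  out
}

#' Read a drug-synonym map
#'
#' A two-column delimited text table mapping verbatim drug names (brand or
#' generic, any case) to the analysis generic name.
#'
#' @param path File with columns `synonym`, `generic` (tab- or
#'   comma-delimited, header row).
#' @return Tibble with columns `synonym`, `generic`.
#' @export
read_synonym_map <- function(path) {
  read_two_column(path, c("synonym", "generic"))
}

#' Read a preferred-term to system-organ-class map
#'
#' @param path File with columns `pt`, `soc`.
#' @return Tibble with columns `pt`, `soc`.
#' @export
read_pt_soc_map <- function(path) {
  read_two_column(path, c("pt", "soc"))
}

#' Read a one-column term list (e.g. important medical events)
#'
#' @param path Text file with one preferred term per line (a header line
#'   named `pt` or `term` is tolerated).
#' @return Character vector of terms.
#' @export
read_term_list <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path),
      class = "faersignal_io_error"
    )
  }
  x <- readr::read_lines(path)
  x <- stringr::str_trim(x)
  x <- x[x != ""]
  if (length(x) && tolower(x[1]) %in% c("pt", "term")) x <- x[-1]
  x
}

read_two_column <- function(path, cols) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path),
      class = "faersignal_io_error"
    )
  }
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (stringr::str_detect(first, "\t")) "\t" else ","
  df <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(df) <- tolower(names(df))
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf(
      "'%s' must have columns %s (missing: %s)",
      path, toString(cols), toString(miss)
    ), class = "faersignal_schema_error")
  }
  as_tibble(df[cols])
}

#' Restrict drug mentions to primary-suspect target-drug rows
#'
#' Keeps only mentions whose role code is `PS` and whose verbatim drug name
#' matches a synonym of a target drug after case-folding and stripping
#' punctuation and dosage/formulation tokens. Matching is exact on the
#' normalized string; no fuzzy matching is attempted. The matched rows gain
#' a `normalized_name` column holding the generic name.
#'
#' @param mentions Tibble of drug mentions with columns `role_cod` and
#'   `drugname` (plus identifiers).
#' @param synonym_map Tibble with columns `synonym`, `generic`, as from
#'   [read_synonym_map()].
#' @return The matching subset of `mentions` with `normalized_name` added.
#' @examples
#' m <- tibble::tibble(
#'   primaryid = 1:3, role_cod = c("PS", "SS", "PS"),
#'   drugname = c("Cymbalta 30mg", "CYMBALTA", "FLUOXETINE")
#' )
#' map <- tibble::tibble(synonym = "cymbalta", generic = "duloxetine")
#' filter_primary_suspect(m, map)
#' @export
filter_primary_suspect <- function(mentions, synonym_map) {
  synonym_map <- as_tibble(synonym_map)
  if (!nrow(synonym_map) ||
    !all(c("synonym", "generic") %in% names(synonym_map))) {
    abort("`synonym_map` must be a nonempty table with columns `synonym`, `generic`",
      class = "faersignal_config_error"
    )
  }
  mentions <- as_tibble(mentions)
  lookup <- synonym_map %>%
    mutate(.key = normalize_drug_name(synonym)) %>%
    distinct(.key, .keep_all = TRUE)
  mentions %>%
    filter(toupper(role_cod) == "PS") %>%
    mutate(.key = normalize_drug_name(drugname)) %>%
    inner_join(select(lookup, ".key", normalized_name = "generic"),
      by = ".key"
    ) %>%
    select(-".key")
}
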