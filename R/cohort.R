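#' Build the analytic record table for target drugs
#'
#' Joins deduplicated, primary-suspect-filtered target-drug mentions to
#' reactions, demographics, serious outcomes and therapy dates. The result
#' has one row per case x target drug x preferred term ("reaction record"),
#' the native unit of disproportionality counting; case-level views are
#' obtained with `dplyr::distinct(primaryid, drug, ...)`.
#'
#' @param tables Deduplicated multi-table dataset (list with `demo`,
#'   `drug`, `reac`, optionally `ther`, `outc`).
#' @param synonym_map Drug-synonym map (columns `synonym`, `generic`).
#' @param unit Counting unit recorded in the output metadata: `"record"`
#'   (case-PT pairs, the default) or `"case"`.
#' @return A tibble with columns `primaryid`, `caseid`, `drug`, `pt`,
#'   `sex`, `age_years`, `age_band`, `weight_kg`, `country`, `occupation`,
#'   `outcomes`, `fda_dt`, `event_dt`, `start_dt`, `report_year`, plus a
#'   `counting_unit` attribute. Empty (with a warning) when no target-drug
#'   record is present.
#' @export
build_analytic <- function(tables, synonym_map, unit = c("record", "case")) {
  unit <- arg_match(unit)
  if (inherits(tables, "faers_dataset")) tables <- tables$tables
  ps <- filter_primary_suspect(tables$drug, synonym_map)
  if (!nrow(ps)) {
    warn("no primary-suspect target-drug mention found; returning empty table")
    out <- tibble(
      primaryid = numeric(0), caseid = numeric(0), drug = character(0),
      pt = character(0)
    )
    attr(out, "counting_unit") <- unit
    return(out)
  }
  seq_col <- intersect(c("drug_seq"), names(ps))
  ps <- ps %>%
    select(primaryid, drug = "normalized_name", any_of("drug_seq")) %>%
    distinct()

  demo <- as_tibble(tables$demo)
  for (col in c("sex", "event_dt", "occr_country", "occp_cod")) {
    if (!col %in% names(demo)) demo[[col]] <- NA_character_
  }
  for (col in c("age", "wt")) {
    if (!col %in% names(demo)) demo[[col]] <- NA_real_
  }
  for (col in c("age_cod", "wt_cod")) {
    if (!col %in% names(demo)) demo[[col]] <- ""
  }
  demo_norm <- demo %>%
    mutate(
      sex = normalize_sex(sex),
      age_years = normalize_age(age, age_cod),
      weight_kg = normalize_weight(wt, wt_cod),
      age_band = age_band(age_years),
      country = dplyr::na_if(as.character(occr_country), ""),
      occupation = dplyr::na_if(as.character(occp_cod), ""),
      event_dt = as.character(event_dt),
      report_year = faers_date_year(fda_dt)
    ) %>%
    select(
      primaryid, caseid, fda_dt, event_dt,
      sex, age_years, age_band, weight_kg, country, occupation, report_year
    )

  # one row per case: most severe outcome (DE > LT > HO > DS > CA > RI > OT)
  severity <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  outcomes <- if (!is.null(tables$outc) && nrow(tables$outc)) {
    as_tibble(tables$outc) %>%
      mutate(.rank = match(toupper(outc_cod), severity)) %>%
      filter(!is.na(.rank)) %>%
      arrange(primaryid, .rank) %>%
      distinct(primaryid, .keep_all = TRUE) %>%
      transmute(primaryid, outcomes = severity[.rank])
  } else {
    tibble(primaryid = numeric(0), outcomes = character(0))
  }

  # earliest valid (day- or month-precision) therapy start per case-drug_seq
  ther <- if (!is.null(tables$ther) && nrow(tables$ther)) {
    th <- as_tibble(tables$ther)
    seqcol <- intersect(c("dsg_drug_seq", "drug_seq"), names(th))[1]
    th %>%
      mutate(
        .start_key = dplyr::if_else(
          stringr::str_detect(as.character(start_dt), "^[0-9]{8}$"),
          as.character(start_dt), "99999999"
        ),
        .seq = if (!is.na(seqcol)) .data[[seqcol]] else 1
      ) %>%
      arrange(primaryid, .seq, .start_key) %>%
      distinct(primaryid, .seq, .keep_all = TRUE) %>%
      transmute(primaryid,
        drug_seq = .seq,
        start_dt = as.character(start_dt),
        end_dt = if ("end_dt" %in% names(th)) as.character(end_dt) else NA_character_
      )
  } else {
    tibble(
      primaryid = numeric(0), drug_seq = numeric(0),
      start_dt = character(0), end_dt = character(0)
    )
  }

  reac <- as_tibble(tables$reac) %>%
    filter(!is.na(pt), pt != "") %>%
    distinct(primaryid, pt)

  out <- ps %>%
    inner_join(reac, by = "primaryid") %>%
    left_join(demo_norm, by = "primaryid") %>%
    left_join(outcomes, by = "primaryid")
  if (length(seq_col)) {
    out <- left_join(out, ther, by = c("primaryid", "drug_seq")) %>%
      select(-any_of("drug_seq"))
  } else {
    out <- left_join(out,
      distinct(ther, primaryid, .keep_all = TRUE) %>%
        select(-any_of("drug_seq")),
      by = "primaryid"
    )
  }
  out <- out %>%
    mutate(outcomes = dplyr::coalesce(outcomes, "unknown")) %>%
    arrange(primaryid, drug, pt)
  attr(out, "counting_unit") <- unit
  out
}

#' Build the full-database drug--event pair table
#'
#' The comparator population for disproportionality is every deduplicated
#' report in the database. This returns one row per case x primary-suspect
#' drug x preferred term for *all* drugs; target drugs are mapped to their
#' generic names via the synonym map, other drugs keep their (case-folded)
#' verbatim names. Demographic stratifiers are carried for subgroup
#' restriction.
#'
#' @param tables Deduplicated multi-table dataset.
#' @param synonym_map Optional drug-synonym map for target-name mapping.
#' @return Tibble with columns `primaryid`, `drug`, `pt`, `sex`,
#'   `age_band`.
#' @export
build_pair_table <- function(tables, synonym_map = NULL) {
  if (inherits(tables, "faers_dataset")) tables <- tables$tables
  drug <- as_tibble(tables$drug) %>%
    filter(toupper(role_cod) == "PS") %>%
    mutate(drug = tolower(as.character(drugname)))
  if (!is.null(synonym_map)) {
    lookup <- as_tibble(synonym_map) %>%
      mutate(.key = normalize_drug_name(synonym)) %>%
      distinct(.key, generic)
    drug <- drug %>%
      mutate(.key = normalize_drug_name(drugname)) %>%
      left_join(lookup, by = ".key") %>%
      mutate(drug = dplyr::coalesce(generic, drug)) %>%
      select(-".key", -any_of("generic"))
  }
  drug <- distinct(drug, primaryid, drug)

  demo <- as_tibble(tables$demo)
  if (!"sex" %in% names(demo)) demo$sex <- NA_character_
  if (!"age" %in% names(demo)) demo$age <- NA_real_
  if (!"age_cod" %in% names(demo)) demo$age_cod <- ""
  demo <- demo %>%
    mutate(
      sex = normalize_sex(sex),
      age_band = age_band(normalize_age(age, age_cod))
    ) %>%
    select(primaryid, sex, age_band)

  as_tibble(tables$reac) %>%
    filter(!is.na(pt), pt != "") %>%
    distinct(primaryid, pt) %>%
    inner_join(drug, by = "primaryid", relationship = "many-to-many") %>%
    left_join(demo, by = "primaryid") %>%
    select(primaryid, drug, pt, sex, age_band)
}

#' Subgroup key constructor
#'
#' @param sex One of `"all"`, `"female"`, `"male"`.
#' @param age One of `"all"`, `"under45"`, `"45to59"`, `"over59"`.
#' @return Named list of class `subgroup_key`.
#' @export
subgroup <- function(sex = "all", age = "all") {
  sex <- arg_match(sex, c("all", "female", "male"))
  age <- arg_match(age, c("all", "under45", "45to59", "over59"))
  structure(list(sex = sex, age = age), class = "subgroup_key")
}

restrict_stratum <- function(pairs, stratum) {
  if (stratum$sex != "all") pairs <- filter(pairs, sex == stratum$sex)
  if (stratum$age != "all") pairs <- filter(pairs, age_band == stratum$age)
  pairs
}

#' Build one 2x2 contingency table
#'
#' For a (drug, preferred term) pair within a stratum of the full cleaned
#' database: `a` counts target drug & target term, `b` the drug's other
#' terms, `c` the term under all other drugs, and `d` the remainder, so
#' that `a+b+c+d` is the stratum total. Under `unit = "record"` the
#' counting unit is the case-PT pair; under `"case"` it is the unique case.
#'
#' @param pairs Full-database pair table from [build_pair_table()].
#' @param drug,pt Target drug and preferred term.
#' @param stratum A [subgroup()] key.
#' @param unit `"record"` or `"case"`.
#' @return One-row tibble with columns `drug`, `pt`, `sex`, `age`, `a`,
#'   `b`, `c`, `d`, `n_total` plus `degenerate` and `zero_cell` flags.
#' @export
build_contingency <- function(pairs, drug, pt, stratum = subgroup(),
                              unit = c("record", "case")) {
  unit <- arg_match(unit)
  target_drug <- drug
  target_pt <- pt
  pairs <- restrict_stratum(pairs, stratum)
  if (unit == "record") {
    n_tot <- nrow(pairs)
    n_drug <- sum(pairs$drug == target_drug)
    n_pt <- sum(pairs$pt == target_pt)
    a <- sum(pairs$drug == target_drug & pairs$pt == target_pt)
  } else {
    cases <- distinct(pairs, primaryid)
    n_tot <- nrow(cases)
    n_drug <- dplyr::n_distinct(pairs$primaryid[pairs$drug == target_drug])
    n_pt <- dplyr::n_distinct(pairs$primaryid[pairs$pt == target_pt])
    a <- dplyr::n_distinct(
      intersect(
        pairs$primaryid[pairs$drug == target_drug],
        pairs$primaryid[pairs$pt == target_pt]
      )
    )
  }
  b <- n_drug - a
  cc <- n_pt - a
  dd <- n_tot - a - b - cc
  tibble(
    drug = target_drug, pt = target_pt,
    sex = stratum$sex, age = stratum$age,
    a = a, b = b, c = cc, d = dd, n_total = n_tot,
    degenerate = (a + b) == 0,
    zero_cell = any(c(a, b, cc, dd) == 0)
  )
}

#' Build all contingency tables for target drugs
#'
#' Vectorized construction of 2x2 tables for every (drug, preferred term)
#' combination observed for the given drugs, overall and optionally within
#' sex and age subgroups (both margins subgroup-restricted).
#'
#' @param pairs Full-database pair table from [build_pair_table()].
#' @param drugs Character vector of target drug names (default: all drugs
#'   in `pairs`).
#' @param pts Optional character vector restricting the preferred terms.
#' @param by_sex,by_age Also emit per-sex / per-age-band strata.
#' @param unit Counting unit, as in [build_contingency()].
#' @param min_a Keep only rows with `a >= min_a` (default 1).
#' @return Tibble of contingency rows ordered by (drug, pt, stratum).
#' @export
contingency_tables <- function(pairs, drugs = NULL, pts = NULL,
                               by_sex = FALSE, by_age = FALSE,
                               unit = c("record", "case"), min_a = 1L) {
  unit <- arg_match(unit)
  if (is.null(drugs)) drugs <- sort(unique(pairs$drug))
  strata <- list(subgroup())
  if (by_sex) strata <- c(strata, list(subgroup("female"), subgroup("male")))
  if (by_age) {
    strata <- c(strata, lapply(
      c("under45", "45to59", "over59"),
      function(a) subgroup("all", a)
    ))
  }
  out <- purrr::map(strata, function(st) {
    sub <- restrict_stratum(pairs, st)
    if (unit == "case") {
      drug_cases <- distinct(sub, primaryid, drug)
      pt_cases <- distinct(sub, primaryid, pt)
      cell <- distinct(sub, primaryid, drug, pt)
      n_tot <- dplyr::n_distinct(sub$primaryid)
      drug_tot <- count(drug_cases, drug, name = "n_drug")
      pt_tot <- count(pt_cases, pt, name = "n_event")
      a_tbl <- count(cell, drug, pt, name = "a")
    } else {
      n_tot <- nrow(sub)
      drug_tot <- count(sub, drug, name = "n_drug")
      pt_tot <- count(sub, pt, name = "n_event")
      a_tbl <- count(sub, drug, pt, name = "a")
    }
    a_tbl %>%
      filter(drug %in% drugs, if (!is.null(pts)) pt %in% pts else TRUE) %>%
      left_join(drug_tot, by = "drug") %>%
      left_join(pt_tot, by = "pt") %>%
      mutate(
        b = n_drug - a, c = n_event - a, d = n_tot - n_drug - n_event + a,
        n_total = n_tot, sex = st$sex, age = st$age
      )
  }) %>%
    bind_rows() %>%
    filter(a >= min_a) %>%
    mutate(
      degenerate = (a + b) == 0,
      zero_cell = a == 0 | b == 0 | c == 0 | d == 0
    ) %>%
    select(
      drug, pt, sex, age, a, b, c, d, n_total, degenerate, zero_cell
    ) %>%
    arrange(drug, pt, sex, age)
  out
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Descriptive cohort summary
#'
#' Per-drug counts and percentages over sex, age bands, weight bands
#' (<50, 50--100, >100 kg), reporter occupation, most severe serious
#' outcome, and the top reporting countries. Percentages are
#' count / drug total x 100, rounded half-up to one decimal; an `unknown`
#' level completes every block so counts sum to the drug total.
#'
#' @param analytic Analytic records from [build_analytic()].
#' @param unit Counting unit: `"record"` (case-PT rows) or `"case"`
#'   (unique reports). Defaults to the analytic table's recorded unit.
#' @param top_countries Number of countries to report (default 5).
#' @return Tibble with columns `drug`, `block`, `level`, `n`, `pct`.
#' @export
descriptive_summary <- function(analytic,
                                unit = NULL, top_countries = 5) {
  if (!nrow(analytic)) abort("`analytic` is empty")
  unit <- unit %||% attr(analytic, "counting_unit") %||% "record"
  dat <- if (unit == "case") {
    distinct(analytic, primaryid, drug, .keep_all = TRUE)
  } else {
    analytic
  }
  dat <- dat %>%
    mutate(
      weight_band = dplyr::case_when(
        is.na(weight_kg) ~ "unknown",
        weight_kg < 50 ~ "<50kg",
        weight_kg <= 100 ~ "50to100kg",
        TRUE ~ ">100kg"
      ),
      age_level = dplyr::coalesce(age_band, "unknown"),
      occ_level = dplyr::coalesce(occupation, "unknown"),
      country_level = dplyr::coalesce(country, "unknown"),
      outcome_level = outcomes
    )

  totals <- count(dat, drug, name = "total")
  block <- function(d, col, blockname) {
    count(d, drug, level = .data[[col]], name = "n") %>%
      mutate(block = blockname)
  }
  out <- bind_rows(
    totals %>% transmute(drug, block = "total", level = "total", n = total),
    block(dat, "sex", "sex"),
    block(dat, "age_level", "age_band"),
    block(dat, "weight_band", "weight"),
    block(dat, "occ_level", "occupation"),
    block(dat, "outcome_level", "serious_outcome")
  )
  # top-k countries per drug, remainder grouped as "other"
  ctry <- count(dat, drug, level = country_level, name = "n") %>%
    group_by(drug) %>%
    arrange(dplyr::desc(n), level, .by_group = TRUE) %>%
    mutate(.top = row_number() <= top_countries & level != "unknown") %>%
    ungroup()
  ctry_top <- filter(ctry, .top) %>% select(-".top") %>%
    mutate(block = "country")
  ctry_rest <- filter(ctry, !.top) %>%
    group_by(drug) %>%
    summarise(n = sum(n), .groups = "drop") %>%
    mutate(block = "country", level = "other")
  out <- bind_rows(out, ctry_top, ctry_rest) %>%
    left_join(totals, by = "drug") %>%
    mutate(pct = round_half_up(100 * n / total, 1)) %>%
    select(drug, block, level, n, pct) %>%
    arrange(drug, block, dplyr::desc(n))
  attr(out, "counting_unit") <- unit
  out
}

#' Annual report counts
#'
#' Counts analytic reports per drug and calendar year of the FDA receipt
#' date (any date with at least year precision contributes).
#'
#' @param analytic Analytic records from [build_analytic()].
#' @param unit Counting unit (`"record"` or `"case"`); defaults to the
#'   table's recorded unit.
#' @return Tibble with columns `drug`, `year`, `n`.
#' @export
annual_counts <- function(analytic, unit = NULL) {
  unit <- unit %||% attr(analytic, "counting_unit") %||% "record"
  dat <- if (unit == "case") {
    distinct(analytic, primaryid, drug, .keep_all = TRUE)
  } else {
    analytic
  }
  dat %>%
    filter(!is.na(report_year)) %>%
    count(drug, year = report_year, name = "n") %>%
    arrange(drug, year)
}
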