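#' Configure the synthetic spontaneous-report generator
#'
#' Builds a validated configuration for [generate_faers()]. The defaults
#' describe the study conditions emulated throughout the package: a
#' reporting database dominated by non-target drugs, two target
#' serotonin-norepinephrine reuptake inhibitors (duloxetine, venlafaxine)
#' with injected reproductive-toxicity signals, Weibull-distributed
#' erectile-dysfunction onset times, FDA-style duplicate case versions,
#' and FAERS-like missingness and partial-date rates.
#'
#' @param n_cases Number of unique cases to generate (before duplicate
#'   versions are added).
#' @param drugs Tibble with columns `name` and `prob`: the probability that
#'   a case's primary-suspect drug is each listed drug. Probabilities must
#'   be in (0,1) and are renormalized to sum to one.
#' @param events Tibble with columns `pt`, `soc`, `prob`: MedDRA preferred
#'   terms, their system organ class, and the baseline per-case inclusion
#'   weight (in (0,1)).
#' @param signals Tibble with columns `drug`, `pt`, `rr`: drug--event pairs
#'   whose reporting rate is tilted by the relative-risk multiplier `rr`
#'   (>= 0; 1 means null). Pairs must reference configured drugs and events.
#' @param tto_models Tibble with columns `drug`, `pt`, `scale`, `shape`:
#'   Weibull time-to-onset models (scale in days > 0, shape > 0) applied to
#'   cases reporting that pair under that primary-suspect drug.
#' @param duplicate_rate Fraction in \[0,1) of cases additionally emitted as
#'   an older, superseded version with the same CASEID.
#' @param secondary_rate Fraction in \[0,1) of cases given one extra
#'   non-primary-suspect (SS/C/I) drug mention, exercising role filtering.
#' @param missingness Named list of per-field blanking fractions in \[0,1):
#'   `sex`, `age`, `weight`, `event_dt`, `country`, `occupation`.
#' @param date_window Length-2 `Date` vector: calendar window for therapy
#'   start dates.
#' @param partial_date_rate Fraction in \[0,1) of event/therapy dates
#'   truncated to `YYYYMM` or `YYYY`.
#' @param mean_extra_pts Poisson mean of the number of reaction terms per
#'   case beyond the first.
#' @param seed Integer seed; identical configurations with identical seeds
#'   reproduce byte-identical datasets.
#'
#' @return An object of class `faers_config`.
#' @seealso [generate_faers()], [default_faers_config()]
#' @export
faers_config <- function(n_cases = 50000,
                         drugs = default_drugs(),
                         events = default_events(),
                         signals = default_signals(),
                         tto_models = default_tto_models(),
                         duplicate_rate = 0.08,
                         secondary_rate = 0.3,
                         missingness = list(
                           sex = 0.08, age = 0.38, weight = 0.72,
                           event_dt = 0.35, country = 0.05, occupation = 0.06
                         ),
                         date_window = as.Date(c("2004-01-01", "2023-12-31")),
                         partial_date_rate = 0.05,
                         mean_extra_pts = 1.5,
                         seed = 20040101L) {
  bad <- function(field, why) {
    abort(sprintf("invalid generator configuration: `%s` %s", field, why),
      class = "faersignal_config_error"
    )
  }
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 1 ||
    n_cases != floor(n_cases)) {
    bad("n_cases", "must be a positive integer")
  }
  drugs <- as_tibble(drugs)
  if (!all(c("name", "prob") %in% names(drugs)) || nrow(drugs) == 0) {
    bad("drugs", "needs columns `name`, `prob` and at least one row")
  }
  if (anyDuplicated(drugs$name)) bad("drugs", "has duplicated names")
  if (!all(drugs$prob > 0 & drugs$prob < 1)) {
    bad("drugs", "probabilities must each lie in (0,1)")
  }
  events <- as_tibble(events)
  if (!all(c("pt", "soc", "prob") %in% names(events)) || nrow(events) == 0) {
    bad("events", "needs columns `pt`, `soc`, `prob` and at least one row")
  }
  if (anyDuplicated(events$pt)) bad("events", "has duplicated preferred terms")
  if (!all(events$prob > 0 & events$prob < 1)) {
    bad("events", "baseline probabilities must each lie in (0,1)")
  }
  signals <- as_tibble(signals)
  if (nrow(signals)) {
    if (!all(c("drug", "pt", "rr") %in% names(signals))) {
      bad("signals", "needs columns `drug`, `pt`, `rr`")
    }
    if (!all(signals$drug %in% drugs$name)) {
      bad("signals", "references a drug not in `drugs`")
    }
    if (!all(signals$pt %in% events$pt)) {
      bad("signals", "references a preferred term not in `events`")
    }
    if (!all(is.finite(signals$rr) & signals$rr >= 0)) {
      bad("signals", "relative risks must be finite and >= 0")
    }
  }
  tto_models <- as_tibble(tto_models)
  if (nrow(tto_models)) {
    if (!all(c("drug", "pt", "scale", "shape") %in% names(tto_models))) {
      bad("tto_models", "needs columns `drug`, `pt`, `scale`, `shape`")
    }
    if (!all(tto_models$drug %in% drugs$name)) {
      bad("tto_models", "references a drug not in `drugs`")
    }
    if (!all(tto_models$pt %in% events$pt)) {
      bad("tto_models", "references a preferred term not in `events`")
    }
    if (!all(tto_models$scale > 0 & tto_models$shape > 0)) {
      bad("tto_models", "scale and shape must be positive")
    }
  }
  for (fld in c("duplicate_rate", "secondary_rate", "partial_date_rate")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v >= 1) {
      bad(fld, "must be a fraction in [0,1)")
    }
  }
  need_miss <- c("sex", "age", "weight", "event_dt", "country", "occupation")
  if (!all(need_miss %in% names(missingness))) {
    bad("missingness", paste("must name fractions for", toString(need_miss)))
  }
  mv <- unlist(missingness[need_miss])
  if (!all(mv >= 0 & mv < 1)) bad("missingness", "fractions must lie in [0,1)")
  date_window <- as.Date(date_window)
  if (length(date_window) != 2 || anyNA(date_window) ||
    date_window[1] > date_window[2]) {
    bad("date_window", "must be a nonempty (start, end) date pair")
  }
  if (!is.numeric(mean_extra_pts) || mean_extra_pts < 0) {
    bad("mean_extra_pts", "must be nonnegative")
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != floor(seed)) {
    bad("seed", "must be an integer")
  }

  structure(
    list(
      n_cases = as.integer(n_cases), drugs = drugs, events = events,
      signals = signals, tto_models = tto_models,
      duplicate_rate = duplicate_rate, secondary_rate = secondary_rate,
      missingness = missingness[need_miss], date_window = date_window,
      partial_date_rate = partial_date_rate,
      mean_extra_pts = mean_extra_pts, seed = as.integer(seed)
    ),
    class = "faers_config"
  )
}

#' @export
print.faers_config <- function(x, ...) {
  cat("<faers_config>\n")
  cat("  cases:", x$n_cases, " drugs:", nrow(x$drugs),
      " events:", nrow(x$events), "\n")
  cat("  injected signals:", nrow(x$signals),
      " tto models:", nrow(x$tto_models), "\n")
  cat("  duplicate rate:", x$duplicate_rate,
      " partial-date rate:", x$partial_date_rate, " seed:", x$seed, "\n")
  invisible(x)
}

#' Default drug marginal distribution
#'
#' Two target SNRIs plus common comparator drugs and a background pool;
#' probabilities are the chance that a case's primary-suspect drug is each
#' one.
#' @return Tibble with columns `name`, `prob`.
#' @export
default_drugs <- function() {
  tibble(
    name = c(
      "duloxetine", "venlafaxine", "sertraline", "fluoxetine",
      "atorvastatin", "metformin", "ibuprofen", "lisinopril",
      "omeprazole", "adalimumab", "background"
    ),
    prob = c(0.045, 0.040, 0.05, 0.05, 0.09, 0.09, 0.10, 0.08, 0.08,
             0.075, 0.30)
  )
}

#' Default event dictionary
#'
#' A mix of rare reproductive-system preferred terms (including
#' breast-related terms used to exercise exclusion lists) and common
#' general adverse-event terms from other system organ classes.
#' @return Tibble with columns `pt`, `soc`, `prob`.
#' @export
default_events <- function() {
  repro <- "Reproductive system and breast disorders"
  tibble(
    pt = c(
      "Erectile dysfunction", "Sexual dysfunction", "Ejaculation disorder",
      "Retrograde ejaculation", "Priapism", "Ejaculation failure",
      "Ejaculation delayed", "Haemorrhagic ovarian cyst",
      "Female sexual dysfunction", "Genital hypoaesthesia",
      "Vulvovaginal dryness", "Menopausal symptoms",
      "Breast pain", "Breast tenderness", "Gynaecomastia",
      "Nausea", "Vomiting", "Diarrhoea", "Dry mouth",
      "Headache", "Dizziness", "Somnolence", "Tremor",
      "Insomnia", "Anxiety", "Fatigue", "Rash", "Pruritus",
      "Hyperhidrosis", "Weight increased"
    ),
    soc = c(
      rep(repro, 15),
      rep("Gastrointestinal disorders", 4),
      rep("Nervous system disorders", 4),
      rep("Psychiatric disorders", 2),
      "General disorders and administration site conditions",
      rep("Skin and subcutaneous tissue disorders", 2),
      "Skin and subcutaneous tissue disorders",
      "Investigations"
    ),
    prob = c(
      0.010, 0.008, 0.003, 0.0015, 0.002, 0.002, 0.0015, 0.001,
      0.0015, 0.0015, 0.003, 0.004, 0.004, 0.003, 0.002,
      0.10, 0.06, 0.07, 0.05,
      0.10, 0.09, 0.05, 0.04,
      0.06, 0.05, 0.09, 0.06, 0.05,
      0.03, 0.04
    )
  )
}

#' Default injected disproportionality signals
#'
#' Target-drug reproductive-toxicity pairs with elevated relative reporting
#' rates, mirroring the magnitude of signals seen for SNRIs.
#' @return Tibble with columns `drug`, `pt`, `rr`.
#' @export
default_signals <- function() {
  tibble(
    drug = c(
      "duloxetine", "duloxetine", "duloxetine",
      "venlafaxine", "venlafaxine", "venlafaxine", "venlafaxine"
    ),
    pt = c(
      "Sexual dysfunction", "Erectile dysfunction", "Ejaculation delayed",
      "Erectile dysfunction", "Sexual dysfunction", "Retrograde ejaculation",
      "Ejaculation delayed"
    ),
    rr = c(5.2, 1.3, 6.9, 3.5, 6.2, 3.3, 10.7)
  )
}

#' Default time-to-onset models
#'
#' Weibull onset-time models for target-drug erectile dysfunction, with
#' sub-unity shapes (early-failure kinetics).
#' @return Tibble with columns `drug`, `pt`, `scale`, `shape`.
#' @export
default_tto_models <- function() {
  tibble(
    drug = c("duloxetine", "venlafaxine"),
    pt = c("Erectile dysfunction", "Erectile dysfunction"),
    scale = c(110, 500.55),
    shape = c(0.65, 0.49)
  )
}

#' Default study configuration
#'
#' Shorthand for [faers_config()] with all defaults; `...` overrides
#' individual fields.
#' @param ... Passed to [faers_config()].
#' @return An object of class `faers_config`.
#' @export
default_faers_config <- function(...) faers_config(...)

#' Generate a synthetic FAERS-like dataset with ground truth
#'
#' Draws a multi-table spontaneous-reporting dataset from the configured
#' data-generating process and returns it together with a ground-truth
#' ledger. Each case has exactly one primary-suspect (PS) drug mention and
#' at least one MedDRA preferred-term reaction; reaction terms are sampled
#' without replacement with weights proportional to
#' `baseline(pt) * rr(drug, pt)`, so the cross-product ratio of the
#' realized 2x2 tables approaches the configured relative risk for rare
#' events. Onset days for modelled drug--event pairs are drawn from the
#' configured Weibull and rounded up to whole days (minimum 1).
#' Superseded duplicate case versions carry the same CASEID with a strictly
#' smaller FDA date, or an equal FDA date and smaller PRIMARYID.
#'
#' @param config A [faers_config()] object.
#' @return An object of class `faers_dataset`: a list with elements
#'   `tables` (tibbles `demo`, `drug`, `reac`, `ther`, `outc`, `indi`),
#'   `ledger` (injected pairs, true onset models, duplicate map, surviving
#'   case ids) and `config`.
#' @examples
#' ds <- generate_faers(faers_config(n_cases = 200, seed = 1))
#' names(ds$tables)
#' @export
generate_faers <- function(config) {
  if (!inherits(config, "faers_config")) {
    abort("`config` must be created by `faers_config()`",
      class = "faersignal_config_error"
    )
  }
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
    add = TRUE
  )
  set.seed(config$seed)

  n <- config$n_cases
  drugs <- config$drugs
  events <- config$events
  m <- nrow(events)

  caseid <- 10000000L + seq_len(n)
  primaryid <- as.numeric(caseid) * 10 + 1

  ## --- demographics ------------------------------------------------------
  sex_raw <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.62, 0.38))
  true_age <- pmin(pmax(rnorm(n, mean = 52, sd = 17), 1), 99)
  age_cod <- sample(c("YR", "DEC", "MON"), n,
    replace = TRUE, prob = c(0.92, 0.04, 0.04)
  )
  age_val <- dplyr::case_match(
    age_cod,
    "YR" ~ round(true_age),
    "DEC" ~ round(true_age / 10),
    "MON" ~ round(true_age * 12)
  )
  wt_kg <- pmin(pmax(rnorm(n, 76, 16), 30), 200)
  wt_cod <- sample(c("KG", "LBS"), n, replace = TRUE, prob = c(0.85, 0.15))
  wt_val <- round(ifelse(wt_cod == "LBS", wt_kg / 0.453592, wt_kg), 1)
  country <- sample(
    c("US", "GB", "JP", "CA", "FR", "DE", "IT", "AU"), n,
    replace = TRUE, prob = c(0.60, 0.07, 0.06, 0.06, 0.07, 0.06, 0.04, 0.04)
  )
  occp <- sample(
    c("CN", "MD", "OT", "PH", "HP", "LW", "RN"), n,
    replace = TRUE, prob = c(0.45, 0.25, 0.10, 0.07, 0.08, 0.02, 0.03)
  )

  ## --- primary-suspect drug and reactions -------------------------------
  drug_idx <- sample.int(nrow(drugs), n,
    replace = TRUE,
    prob = drugs$prob / sum(drugs$prob)
  )

  # per-drug sampling weights over preferred terms, tilted by injected RR
  weight_mat <- matrix(events$prob, nrow(drugs), m, byrow = TRUE)
  if (nrow(config$signals)) {
    di <- match(config$signals$drug, drugs$name)
    ei <- match(config$signals$pt, events$pt)
    weight_mat[cbind(di, ei)] <- events$prob[ei] * config$signals$rr
  }

  k <- pmin(1L + rpois(n, config$mean_extra_pts), m)
  pt_idx_list <- vector("list", n)
  for (d in seq_len(nrow(drugs))) {
    idx <- which(drug_idx == d)
    if (!length(idx)) next
    w <- weight_mat[d, ]
    pt_idx_list[idx] <- lapply(k[idx], function(kk) {
      sort(sample.int(m, kk, replace = FALSE, prob = w))
    })
  }

  ## --- dates and time-to-onset ------------------------------------------
  win <- as.integer(config$date_window[2] - config$date_window[1])
  start_date <- config$date_window[1] + sample.int(win + 1L, n, TRUE) - 1L

  onset <- pmax(1, ceiling(rexp(n, rate = 1 / 90))) # baseline onset days
  if (nrow(config$tto_models)) {
    for (j in seq_len(nrow(config$tto_models))) {
      md <- config$tto_models[j, ]
      d <- match(md$drug, drugs$name)
      e <- match(md$pt, events$pt)
      hit <- which(drug_idx == d &
        vapply(pt_idx_list, function(p) e %in% p, logical(1)))
      if (length(hit)) {
        onset[hit] <- pmax(1, ceiling(
          rweibull(length(hit), shape = md$shape, scale = md$scale)
        ))
      }
    }
  }
  event_date <- start_date + onset
  fda_date <- event_date + pmax(1, round(rexp(n, 1 / 45)))
  ther_end <- start_date + pmax(onset, round(rexp(n, 1 / 180)))

  event_dt <- format_faers_date(event_date)
  start_dt <- format_faers_date(start_date)
  end_dt <- format_faers_date(ther_end)
  fda_dt <- format_faers_date(fda_date)

  # partial-date truncation (event and therapy dates; FDA date stays full)
  truncate_dates <- function(x) {
    u <- runif(length(x))
    part <- u < config$partial_date_rate & nchar(x) == 8
    half <- runif(length(x)) < 0.5
    x[part & half] <- substr(x[part & half], 1, 6)
    x[part & !half] <- substr(x[part & !half], 1, 4)
    x
  }
  event_dt <- truncate_dates(event_dt)
  start_dt <- truncate_dates(start_dt)
  end_dt <- truncate_dates(end_dt)

  ## --- missingness -------------------------------------------------------
  mrate <- config$missingness
  blank <- function(x, rate) {
    x[runif(length(x)) < rate] <- ""
    x
  }
  sex_raw <- blank(sex_raw, mrate$sex)
  miss_age <- runif(n) < mrate$age
  age_val[miss_age] <- NA
  age_cod[miss_age] <- ""
  miss_wt <- runif(n) < mrate$weight
  wt_val[miss_wt] <- NA
  wt_cod[miss_wt] <- ""
  event_dt <- blank(event_dt, mrate$event_dt)
  country <- blank(country, mrate$country)
  occp <- blank(occp, mrate$occupation)

  ## --- core tables -------------------------------------------------------
  demo <- tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, sex = sex_raw,
    age = age_val, age_cod = age_cod, wt = wt_val, wt_cod = wt_cod,
    occr_country = country, occp_cod = occp
  )

  drug_tbl <- tibble(
    primaryid = primaryid, caseid = caseid, drug_seq = 1L,
    role_cod = "PS", drugname = drugs$name[drug_idx]
  )
  # extra non-PS mentions (noise for role filtering)
  extra <- which(runif(n) < config$secondary_rate)
  if (length(extra)) {
    drug_tbl <- bind_rows(drug_tbl, tibble(
      primaryid = primaryid[extra], caseid = caseid[extra], drug_seq = 2L,
      role_cod = sample(c("SS", "C", "I"), length(extra), TRUE),
      drugname = drugs$name[sample.int(nrow(drugs), length(extra), TRUE,
        prob = drugs$prob / sum(drugs$prob)
      )]
    ))
  }

  reac <- tibble(
    primaryid = rep(primaryid, lengths(pt_idx_list)),
    caseid = rep(caseid, lengths(pt_idx_list)),
    pt = events$pt[unlist(pt_idx_list)]
  )

  ther <- tibble(
    primaryid = primaryid, caseid = caseid, dsg_drug_seq = 1L,
    start_dt = start_dt, end_dt = end_dt
  )

  outc_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  n_outc <- sample(0:2, n, TRUE, prob = c(0.45, 0.40, 0.15))
  outc_rows <- which(n_outc > 0)
  outc <- tibble(
    primaryid = rep(primaryid[outc_rows], n_outc[outc_rows]),
    caseid = rep(caseid[outc_rows], n_outc[outc_rows]),
    outc_cod = unlist(lapply(n_outc[outc_rows], function(kk) {
      sample(outc_codes, kk,
        prob = c(0.06, 0.05, 0.25, 0.05, 0.02, 0.02, 0.55)
      )
    }))
  )

  indi <- tibble(
    primaryid = primaryid, caseid = caseid, indi_drug_seq = 1L,
    indi_pt = sample(
      c("Depression", "Anxiety", "Pain",
        "Product used for unknown indication"),
      n, TRUE, prob = c(0.4, 0.2, 0.2, 0.2)
    )
  )

  ## --- superseded duplicate versions -------------------------------------
  dup <- which(runif(n) < config$duplicate_rate)
  duplicate_map <- tibble(
    superseded_primaryid = numeric(0), surviving_primaryid = numeric(0)
  )
  if (length(dup)) {
    old_pid <- as.numeric(caseid[dup]) * 10 # smaller than the survivor's
    lag <- sample(0:30, length(dup), TRUE) # 0 exercises the PRIMARYID tie rule
    old_fda <- format_faers_date(fda_date[dup] - lag)
    dup_demo <- demo[dup, ]
    dup_demo$primaryid <- old_pid
    dup_demo$fda_dt <- old_fda
    demo <- bind_rows(demo, dup_demo)
    copy_child <- function(tb) {
      rows <- tb[tb$primaryid %in% primaryid[dup], ]
      rows$primaryid <- old_pid[match(rows$primaryid, primaryid[dup])]
      bind_rows(tb, rows)
    }
    drug_tbl <- copy_child(drug_tbl)
    reac <- copy_child(reac)
    ther <- copy_child(ther)
    outc <- copy_child(outc)
    indi <- copy_child(indi)
    duplicate_map <- tibble(
      superseded_primaryid = old_pid,
      surviving_primaryid = primaryid[dup]
    )
  }

  order_tbl <- function(tb) arrange(tb, primaryid)
  tables <- list(
    demo = order_tbl(demo), drug = order_tbl(drug_tbl),
    reac = order_tbl(reac), ther = order_tbl(ther),
    outc = order_tbl(outc), indi = order_tbl(indi)
  )

  ledger <- list(
    injected_pairs = config$signals,
    true_tto_params = config$tto_models,
    duplicate_map = duplicate_map,
    survivors = tibble(primaryid = primaryid, caseid = caseid),
    n_cases = n
  )

  structure(list(tables = tables, ledger = ledger, config = config),
    class = "faers_dataset"
  )
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat("<faers_dataset>\n")
  cat("  unique cases:", x$ledger$n_cases,
      " duplicate versions:", nrow(x$ledger$duplicate_map), "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %s: %d rows\n", toupper(nm), nrow(x$tables[[nm]])))
  }
  invisible(x)
}

#' Write a dataset as a FAERS-dialect ASCII quarter
#'
#' Writes one `'$'`-delimited text file per table (header row, empty string
#' for missing values, no quoting) using FAERS-style file names such as
#' `DEMO24Q1.txt`. Because the dialect has no quoting, any field containing
#' the delimiter is rejected.
#'
#' @param dataset A `faers_dataset` from [generate_faers()], or a plain
#'   named list of tables.
#' @param directory Output directory (created if needed).
#' @param quarter Quarter label embedded in file names, e.g. `"24Q1"`.
#' @return Invisibly, a named character vector of written file paths.
#' @export
write_faers_quarter <- function(dataset, directory, quarter = "24Q1") {
  tables <- if (inherits(dataset, "faers_dataset")) dataset$tables else dataset
  if (!is.list(tables) || is.null(names(tables))) {
    abort("`dataset` must be a faers_dataset or a named list of tables")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", directory))
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- as_tibble(tables[[nm]])
    chr <- dplyr::mutate(tb, across(dplyr::everything(), as.character))
    has_delim <- vapply(
      chr, function(col) any(stringr::str_detect(col, stringr::fixed("$")),
        na.rm = TRUE
      ),
      logical(1)
    )
    if (any(has_delim)) {
      abort(
        sprintf(
          "table '%s' contains the '$' delimiter in column(s): %s",
          nm, toString(names(chr)[has_delim])
        ),
        class = "faersignal_validation_error"
      )
    }
    path <- file.path(directory, paste0(toupper(nm), quarter, ".txt"))
    readr::write_delim(chr, path, delim = "$", na = "", quote = "none")
    paths[nm] <- path
  }
  invisible(paths)
}
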