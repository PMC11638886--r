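#' Configure an end-to-end pipeline run
#'
#' Collects everything [run_faers_pipeline()] needs: the input mode
#' (synthetic generation or a FAERS ASCII directory), the target-drug
#' synonym map, the term maps and lists, criteria, and time-to-onset
#' settings. Exactly one input mode must be set, and any referenced path
#' must exist -- checked here, before any computation.
#'
#' @param mode `"synthetic"` or `"faers"`.
#' @param generator A [faers_config()] (synthetic mode).
#' @param input_dir Directory of quarterly ASCII files (faers mode).
#' @param synonym_map Drug-synonym map: a tibble (`synonym`, `generic`) or
#'   a file path.
#' @param pt_soc_map Preferred-term to SOC map: tibble (`pt`, `soc`) or a
#'   file path. In synthetic mode defaults to the generator's event
#'   dictionary.
#' @param ime_terms IME term list: character vector or file path.
#' @param exclude_terms Signal-table exclusion terms (e.g. breast-related
#'   preferred terms): character vector or file path.
#' @param soc System organ class to screen.
#' @param criteria A [signal_criteria()] object.
#' @param unit Counting unit (`"record"` or `"case"`).
#' @param by_sex,by_age Emit sex / age-band subgroup signal tables.
#' @param tto_pt Preferred term analyzed for time-to-onset across target
#'   drugs.
#' @param zero_day Zero-day onset policy (see [compute_tto()]).
#' @param outdir Optional output directory for delimited text artifacts.
#' @param seed Root seed for synthetic mode.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "faers"),
                            generator = default_faers_config(),
                            input_dir = NULL,
                            synonym_map = default_synonym_map(),
                            pt_soc_map = NULL,
                            ime_terms = default_ime_terms(),
                            exclude_terms = default_breast_terms(),
                            soc = "Reproductive system and breast disorders",
                            criteria = signal_criteria(),
                            unit = c("record", "case"),
                            by_sex = TRUE, by_age = TRUE,
                            tto_pt = "Erectile dysfunction",
                            zero_day = "map_to_1",
                            outdir = NULL,
                            seed = NULL) {
  mode <- arg_match(mode)
  unit <- arg_match(unit)
  cfg_err <- function(msg) abort(msg, class = "faersignal_config_error")

  if (mode == "faers") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      cfg_err("faers mode requires an existing `input_dir`")
    }
  } else {
    if (!inherits(generator, "faers_config")) {
      cfg_err("synthetic mode requires `generator` from faers_config()")
    }
    if (!is.null(seed)) {
      generator$seed <- as.integer(seed)
    }
  }
  load_tbl <- function(x, reader, what) {
    if (is.character(x) && length(x) == 1) {
      if (!file.exists(x)) cfg_err(sprintf("%s path '%s' does not exist", what, x))
      reader(x)
    } else {
      x
    }
  }
  synonym_map <- load_tbl(synonym_map, read_synonym_map, "synonym map")
  if (is.null(pt_soc_map) && mode == "synthetic") {
    pt_soc_map <- generator$events[c("pt", "soc")]
  }
  if (is.null(pt_soc_map)) cfg_err("faers mode requires `pt_soc_map`")
  pt_soc_map <- load_tbl(pt_soc_map, read_pt_soc_map, "PT-SOC map")
  ime_terms <- load_tbl(ime_terms, read_term_list, "IME list")
  exclude_terms <- load_tbl(exclude_terms, read_term_list, "exclusion list")

  structure(
    list(
      mode = mode, generator = generator, input_dir = input_dir,
      synonym_map = as_tibble(synonym_map),
      pt_soc_map = as_tibble(pt_soc_map),
      ime_terms = ime_terms, exclude_terms = exclude_terms,
      soc = soc, criteria = criteria, unit = unit,
      by_sex = by_sex, by_age = by_age,
      tto_pt = tto_pt, zero_day = zero_day, outdir = outdir
    ),
    class = "pipeline_config"
  )
}

#' Run the end-to-end signal-detection pipeline
#'
#' Orchestrates ingest (or synthetic generation), FDA-rule deduplication,
#' primary-suspect filtering, cohort description, SOC screening with all
#' four disproportionality algorithms (the MGPS prior is fitted on the
#' full database's (count, expected) pairs), subgroup signal tables, and
#' time-to-onset analysis with Weibull fits, Kaplan--Meier curves, and the
#' cross-drug log-rank test. Stage-by-stage record counts are kept in the
#' returned manifest; identical configuration and seed reproduce identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `manifest`
#'   (stage counts, config hash, package version, output paths),
#'   `descriptive`, `annual`, `screens` (per drug x stratum),
#'   `tto` (summaries, fits, curves, log-rank), and in synthetic mode
#'   `ledger`.
#' @export
run_faers_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config()",
      class = "faersignal_config_error"
    )
  }
  stage <- function(what) inform(paste0("[faersignal] ", what))

  ledger <- NULL
  if (config$mode == "synthetic") {
    stage("generating synthetic dataset")
    ds <- generate_faers(config$generator)
    tables <- ds$tables
    ledger <- ds$ledger
  } else {
    stage(paste("reading", config$input_dir))
    tables <- read_faers_quarter(config$input_dir)
  }
  n_raw <- nrow(tables$demo)

  stage("deduplicating cases")
  clean <- dedup_faers(tables)
  n_dedup <- nrow(clean$demo)

  stage("filtering primary-suspect target mentions")
  ps <- filter_primary_suspect(clean$drug, config$synonym_map)
  n_ps <- nrow(distinct(ps, primaryid, normalized_name))

  stage("building analytic records")
  analytic <- build_analytic(clean, config$synonym_map, unit = config$unit)
  pairs <- build_pair_table(clean, config$synonym_map)
  n_analytic <- nrow(analytic)
  target_drugs <- sort(unique(analytic$drug))

  descriptive <- if (nrow(analytic)) descriptive_summary(analytic) else NULL
  annual <- if (nrow(analytic)) annual_counts(analytic) else NULL

  stage("fitting MGPS prior on the full database")
  all_tab <- contingency_tables(pairs, unit = config$unit, min_a = 0L)
  prior <- fit_mgps_prior(all_tab$a,
    (all_tab$a + all_tab$b) * (all_tab$a + all_tab$c) / all_tab$n_total
  )

  stage("screening the SOC per drug")
  strata <- list(subgroup())
  if (config$by_sex) {
    strata <- c(strata, list(subgroup("female"), subgroup("male")))
  }
  if (config$by_age) {
    strata <- c(strata, lapply(
      c("under45", "45to59", "over59"),
      function(a) subgroup("all", a)
    ))
  }
  screens <- list()
  for (dg in target_drugs) {
    for (st in strata) {
      key <- paste(dg, st$sex, st$age, sep = ".")
      screens[[key]] <- screen_soc(
        pairs, dg, config$pt_soc_map,
        soc = config$soc,
        ime_terms = config$ime_terms,
        exclude_terms = config$exclude_terms,
        prior = prior, criteria = config$criteria,
        stratum = st, unit = config$unit
      )
    }
  }

  stage("time-to-onset analysis")
  tto <- list(samples = list(), summaries = NULL, fits = list(),
              curves = list(), logrank = NULL)
  for (dg in target_drugs) {
    smp <- compute_tto(analytic, dg, config$tto_pt,
      zero_day = config$zero_day
    )
    tto$samples[[dg]] <- smp
    if (nrow(smp)) {
      tto$summaries <- bind_rows(
        tto$summaries,
        dplyr::bind_cols(tibble(drug = dg, pt = config$tto_pt),
                         tto_summary(smp))
      )
      tto$curves[[dg]] <- km_curve(smp)
    }
    if (nrow(smp) >= 3 && diff(range(smp$days)) > 0) {
      tto$fits[[dg]] <- fit_weibull(smp)
    }
  }
  if (length(tto$samples) == 2 && all(vapply(tto$samples, nrow, 1L) > 0)) {
    tto$logrank <- logrank_test(
      tto$samples[[1]], tto$samples[[2]]
    )
  }

  manifest <- list(
    package_version = as.character(packageVersion("faersignal")),
    mode = config$mode,
    counts = tibble(
      stage = c("raw", "deduplicated", "ps_filtered_cases",
                "analytic_records"),
      n = c(n_raw, n_dedup, n_ps, n_analytic)
    ),
    target_drugs = target_drugs,
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    outputs = character(0)
  )

  result <- structure(
    list(
      manifest = manifest, descriptive = descriptive, annual = annual,
      screens = screens, prior = prior, tto = tto, ledger = ledger,
      analytic = analytic, pairs = pairs
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$outdir)) {
    result$manifest$outputs <- write_pipeline_outputs(result, config$outdir)
  }
  result
}

write_pipeline_outputs <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  put <- function(tb, nm) {
    if (is.null(tb) || !nrow(tb)) return(invisible(NULL))
    p <- file.path(outdir, paste0(nm, ".tsv"))
    readr::write_tsv(tb, p)
    paths[[nm]] <<- p
  }
  put(result$descriptive, "descriptive_summary")
  put(result$annual, "annual_counts")
  for (key in names(result$screens)) {
    put(result$screens[[key]]$volcano, paste0("volcano_", key))
    put(result$screens[[key]]$signals, paste0("signals_", key))
  }
  put(result$tto$summaries, "tto_summary")
  if (length(result$tto$fits)) {
    fits <- purrr::imap(result$tto$fits, function(f, nm) {
      dplyr::bind_cols(tibble(drug = nm), glance_weibull_row(f))
    }) %>% bind_rows()
    put(fits, "weibull_fits")
  }
  for (nm in names(result$tto$curves)) {
    put(as_tibble(result$tto$curves[[nm]]), paste0("km_", nm))
  }
  put(result$tto$logrank, "logrank")
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(
      package_version = result$manifest$package_version,
      mode = result$manifest$mode,
      config_hash = result$manifest$config_hash,
      counts = result$manifest$counts,
      outputs = as.list(paths)
    ),
    manifest_path,
    auto_unbox = TRUE, pretty = TRUE
  )
  paths[["manifest"]] <- manifest_path
  paths
}

glance_weibull_row <- function(f) {
  tibble(
    n = f$n, scale = f$scale, scale_lo95 = f$scale_lo95,
    scale_hi95 = f$scale_hi95, shape = f$shape,
    shape_lo95 = f$shape_lo95, shape_hi95 = f$shape_hi95,
    loglik = f$loglik, failure_type = f$failure_type
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$manifest$counts)
  cat("  screens:", length(x$screens),
      " tto fits:", length(x$tto$fits), "\n")
  invisible(x)
}

#' Bundled example term lists
#'
#' Small example inputs shipped with the package for the synthetic study
#' world: a target-drug synonym map, an IME subset, and breast-related
#' exclusion terms. They are illustrative subsets, not the regulatory
#' lists, which must be supplied by the user for real analyses.
#'
#' @return `default_synonym_map()`: tibble (`synonym`, `generic`);
#'   the term-list helpers return character vectors.
#' @export
default_synonym_map <- function() {
  read_synonym_map(
    system.file("extdata", "example_drug_synonyms.txt",
      package = "faersignal", mustWork = TRUE
    )
  )
}

#' @rdname default_synonym_map
#' @export
default_ime_terms <- function() {
  read_term_list(
    system.file("extdata", "example_ime_terms.txt",
      package = "faersignal", mustWork = TRUE
    )
  )
}

#' @rdname default_synonym_map
#' @export
default_breast_terms <- function() {
  read_term_list(
    system.file("extdata", "example_breast_terms.txt",
      package = "faersignal", mustWork = TRUE
    )
  )
}
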