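#' Screen one system organ class for a drug
#'
#' Builds, for every preferred term of the SOC reported at least once with
#' the drug, the full-database 2x2 table, the four disproportionality
#' statistics, an association p-value (Pearson chi-squared when all
#' expected cells are >= 5, otherwise Fisher's exact test, two-sided) and
#' its Benjamini--Hochberg adjustment across the SOC's terms for that
#' drug. Returns a volcano table (all terms, including excluded ones) and
#' a signal table (terms meeting the signal rule, exclusion terms removed,
#' IME-flagged).
#'
#' @param pairs Full-database pair table from [build_pair_table()].
#' @param drug Target drug name.
#' @param soc_pt_map Tibble with columns `pt`, `soc`.
#' @param soc System organ class under study (default: reproductive system
#'   and breast disorders).
#' @param ime_terms Character vector of important-medical-event preferred
#'   terms (may be empty).
#' @param exclude_terms Preferred terms removed from the signal table (but
#'   kept in the volcano table), e.g. breast-related terms.
#' @param prior Optional [fit_mgps_prior()] object; when supplied the
#'   signal table carries EBGM columns and the MGPS rule participates in
#'   the concordance count.
#' @param criteria A [signal_criteria()] object.
#' @param stratum A [subgroup()] key.
#' @param unit Counting unit (see [build_contingency()]).
#' @return A list of class `soc_screen` with elements `volcano` (tibble:
#'   `pt`, `n`, `ror`, `log2_ror`, `p_value`, `p_fdr`, `excluded`) and
#'   `signals` (tibble in signal-table layout, sorted by `n` descending).
#' @export
screen_soc <- function(pairs, drug, soc_pt_map,
                       soc = "Reproductive system and breast disorders",
                       ime_terms = character(0),
                       exclude_terms = character(0),
                       prior = NULL,
                       criteria = signal_criteria(),
                       stratum = subgroup(),
                       unit = "record") {
  soc_pt_map <- as_tibble(soc_pt_map)
  if (!all(c("pt", "soc") %in% names(soc_pt_map))) {
    abort("`soc_pt_map` must have columns `pt`, `soc`")
  }
  soc_pts <- soc_pt_map$pt[soc_pt_map$soc == soc]
  empty_volcano <- tibble(
    pt = character(0), n = integer(0), ror = numeric(0),
    log2_ror = numeric(0), p_value = numeric(0), p_fdr = numeric(0),
    excluded = logical(0)
  )
  if (!length(soc_pts)) {
    return(structure(list(volcano = empty_volcano, signals = empty_volcano),
      class = "soc_screen"
    ))
  }
  sub <- restrict_stratum(pairs, stratum)
  tab <- contingency_tables(sub,
    drugs = drug, pts = soc_pts,
    unit = unit, min_a = 1L
  )
  tab$sex <- stratum$sex
  tab$age <- stratum$age
  if (!nrow(tab)) {
    return(structure(list(volcano = empty_volcano, signals = empty_volcano),
      class = "soc_screen"
    ))
  }
  stats <- disproportionality_stats(tab, prior = prior) %>%
    mutate(
      p_value = pair_pvalue(a, b, c, d),
      p_fdr = p.adjust(p_value, method = "BH"),
      log2_ror = log2(ror),
      excluded = tolower(pt) %in% tolower(exclude_terms)
    ) %>%
    apply_signal_criteria(criteria) %>%
    arrange(dplyr::desc(n), pt)

  volcano <- stats %>%
    select(pt, n, ror, log2_ror, p_value, p_fdr, excluded)

  signal_cols <- c(
    "drug", "pt", "n", "ror", "ror_lo95", "ror_hi95",
    "prr", "prr_lo95", "prr_hi95", "chi2", "ic", "ic025",
    "ebgm", "ebgm05", "ime", "algorithms_met", "n_algorithms"
  )
  signals <- stats %>%
    filter(is_signal, !excluded) %>%
    mutate(ime = flag_ime(pt, ime_terms)) %>%
    select(any_of(signal_cols))

  structure(list(volcano = volcano, signals = signals, drug = drug,
                 soc = soc, stratum = stratum),
    class = "soc_screen"
  )
}

#' @export
print.soc_screen <- function(x, ...) {
  cat("<soc_screen>", x$drug, "/", x$soc, "\n")
  cat("  volcano terms:", nrow(x$volcano),
      " signals:", nrow(x$signals), "\n")
  invisible(x)
}
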