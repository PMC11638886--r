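#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a d) / (b c)` with the 95% interval
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell leaves
#' the estimate undefined (`NA`) unless the Haldane--Anscombe correction is
#' requested, which adds 0.5 to every cell of every table.
#'
#' @param a,b,c,d Cell counts (vectorized): `a` drug & event, `b` drug &
#'   other events, `c` other drugs & event, `d` neither.
#' @param correction `"none"` (default) or `"haldane"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with columns `ror`, `ror_lo95`, `ror_hi95`.
#' @examples
#' ror_stats(10, 90, 100, 9900)
#' @export
ror_stats <- function(a, b, c, d, correction = c("none", "haldane"),
                      conf_level = 0.95) {
  correction <- arg_match(correction)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (correction == "haldane") {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble(
    ror = est,
    ror_lo95 = exp(log(est) - z * se),
    ror_hi95 = exp(log(est) + z * se)
  )
}

#' Proportional reporting ratio, Wald interval, and Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with 95% interval
#' `exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. The
#' chi-squared statistic is the Pearson statistic on the 2x2 table, without
#' continuity correction by default.
#'
#' @inheritParams ror_stats
#' @param yates Apply the Yates continuity correction to the chi-squared
#'   statistic (default `FALSE`).
#' @return Tibble with columns `prr`, `prr_lo95`, `prr_hi95`, `chi2`.
#' @examples
#' prr_stats(10, 90, 100, 9900)
#' @export
prr_stats <- function(a, b, c, d, yates = FALSE, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ok <- a > 0 & (a + b) > 0 & c > 0 & (c + d) > 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  margins_ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  delta <- abs(a * d - b * c)
  if (yates) delta <- pmax(0, delta - n / 2)
  chi2 <- ifelse(
    margins_ok,
    n * delta^2 / ((a + b) * (c + d) * (a + c) * (b + d)),
    NA_real_
  )
  tibble(
    prr = est,
    prr_lo95 = exp(log(est) - z * se),
    prr_hi95 = exp(log(est) + z * se),
    chi2 = chi2
  )
}

#' BCPNN information component with lower credible bound
#'
#' Under the gamma-posterior formulation of the Bayesian confidence
#' propagation neural network, the relative reporting rate has posterior
#' `Gamma(shape = a + 0.5, rate = E + 0.5)` where `E = (a+b)(a+c)/N` is the
#' expected count under independence. The information component is
#' `IC = log2((a + 0.5) / (E + 0.5))` and `IC025` is the base-2 log of the
#' 2.5th posterior percentile.
#'
#' @param a Observed pair count (vectorized).
#' @param expected Expected count `E` under independence.
#' @return Tibble with columns `ic`, `ic025`.
#' @examples
#' bcpnn_ic(10, 2)
#' @export
bcpnn_ic <- function(a, expected) {
  ok <- expected > 0 & a >= 0
  ic <- ifelse(ok, log2((a + 0.5) / (expected + 0.5)), NA_real_)
  q <- ifelse(
    ok,
    qgamma(0.025, shape = a + 0.5, rate = expected + 0.5),
    NA_real_
  )
  tibble(ic = ic, ic025 = log2(q))
}

#' Per-pair association p-value
#'
#' Pearson chi-squared (uncorrected) when all expected cells are at least
#' 5, otherwise the two-sided Fisher exact test.
#'
#' @inheritParams ror_stats
#' @return Numeric vector of p-values.
#' @export
pair_pvalue <- function(a, b, c, d) {
  purrr::pmap_dbl(list(a, b, c, d), function(a, b, c, d) {
    m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
    if (any(!is.finite(m)) || any(m < 0) || sum(m) == 0) {
      return(NA_real_)
    }
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected == 0)) {
      return(NA_real_)
    }
    if (all(expected >= 5)) {
      suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    } else {
      fisher.test(m)$p.value
    }
  })
}

#' Signal criteria
#'
#' Detection thresholds: the headline rule flags a pair as a signal when it
#' has at least `min_reports` reports and the ROR lower 95% bound exceeds
#' 1. The per-algorithm rules used for four-algorithm concordance are the
#' standard literature thresholds: `PRR >= 2` with `chi2 >= 4` and
#' `n >= 3`; `IC025 > 0`; `EBGM05 >= 2`.
#'
#' @param min_reports Minimum report count (default 3).
#' @param ror_lo_min ROR lower-bound threshold (default 1).
#' @param prr_min,chi2_min PRR-rule thresholds (defaults 2 and 4).
#' @param ic025_min BCPNN threshold (default 0, strict).
#' @param ebgm05_min MGPS threshold (default 2).
#' @return A list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_reports = 3, ror_lo_min = 1,
                            prr_min = 2, chi2_min = 4,
                            ic025_min = 0, ebgm05_min = 2) {
  stopifnot(
    min_reports >= 1, ror_lo_min > 0, prr_min > 0, chi2_min >= 0,
    ebgm05_min > 0
  )
  structure(
    list(
      min_reports = min_reports, ror_lo_min = ror_lo_min,
      prr_min = prr_min, chi2_min = chi2_min,
      ic025_min = ic025_min, ebgm05_min = ebgm05_min
    ),
    class = "signal_criteria"
  )
}

#' Compute all disproportionality statistics for contingency rows
#'
#' Appends the four statistics and their interval estimates to a table of
#' 2x2 counts: ROR and PRR with Wald intervals and the Pearson
#' chi-squared; the BCPNN information component with its lower credible
#' bound; and, when an MGPS prior is supplied, the empirical-Bayes
#' geometric mean with its 5th posterior percentile. Undefined statistics
#' (zero cells) are `NA`.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (one row per
#'   drug--event--stratum), e.g. from [contingency_tables()].
#' @param prior Optional [fit_mgps_prior()] object for EBGM columns.
#' @param correction,yates Passed to [ror_stats()] / [prr_stats()].
#' @return `tables` with columns `expected`, `ror*`, `prr*`, `chi2`, `ic`,
#'   `ic025` (and `ebgm`, `ebgm05` when a prior is given) appended, plus
#'   `n` (a copy of `a`).
#' @export
disproportionality_stats <- function(tables, prior = NULL,
                                     correction = "none", yates = FALSE) {
  tables <- as_tibble(tables)
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(tables))) {
    abort("`tables` must have columns a, b, c, d")
  }
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c); dd <- as.numeric(tables$d)
  n_tot <- a + b + cc + dd
  expected <- ifelse(n_tot > 0, (a + b) * (a + cc) / n_tot, NA_real_)
  out <- dplyr::bind_cols(
    tables,
    tibble(n = a, expected = expected),
    ror_stats(a, b, cc, dd, correction = correction),
    prr_stats(a, b, cc, dd, yates = yates),
    bcpnn_ic(a, expected)
  )
  if (!is.null(prior)) {
    eb <- ebgm_mgps(a, expected, prior)
    out <- dplyr::bind_cols(out, eb)
  }
  out
}

#' Apply signal criteria
#'
#' Evaluates the headline signal rule (`n >= min_reports` and ROR lower
#' bound above threshold) and the four per-algorithm rules; statistics that
#' are undefined (`NA`) fail their rule.
#'
#' @param stats Tibble from [disproportionality_stats()].
#' @param criteria A [signal_criteria()] object.
#' @return `stats` with logical columns `sig_ror`, `sig_prr`, `sig_bcpnn`,
#'   `sig_mgps`, integer `n_algorithms`, character `algorithms_met`, and
#'   logical `is_signal`.
#' @export
apply_signal_criteria <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  stats <- as_tibble(stats)
  met <- function(x) !is.na(x) & x
  n <- stats$n %||% stats$a
  sig_ror <- met(n >= criteria$min_reports &
    stats$ror_lo95 > criteria$ror_lo_min)
  sig_prr <- met(stats$prr >= criteria$prr_min &
    stats$chi2 >= criteria$chi2_min & n >= criteria$min_reports)
  sig_bcpnn <- met(stats$ic025 > criteria$ic025_min)
  sig_mgps <- if ("ebgm05" %in% names(stats)) {
    met(stats$ebgm05 >= criteria$ebgm05_min)
  } else {
    rep(FALSE, nrow(stats))
  }
  alg <- cbind(ROR = sig_ror, PRR = sig_prr, BCPNN = sig_bcpnn,
               MGPS = sig_mgps)
  stats %>%
    mutate(
      sig_ror = sig_ror, sig_prr = sig_prr,
      sig_bcpnn = sig_bcpnn, sig_mgps = sig_mgps,
      n_algorithms = as.integer(rowSums(alg)),
      algorithms_met = apply(alg, 1, function(r) {
        paste(colnames(alg)[r], collapse = ",")
      }),
      is_signal = sig_ror
    )
}

#' Flag important medical events
#'
#' Case-insensitive exact preferred-term match against a user-supplied IME
#' term list.
#'
#' @param pt Character vector of preferred terms.
#' @param ime_terms Character vector of IME preferred terms.
#' @return Logical vector.
#' @examples
#' flag_ime(c("Erectile dysfunction", "Nausea"), "erectile dysfunction")
#' @export
flag_ime <- function(pt, ime_terms) {
  if (!length(ime_terms)) {
    return(rep(FALSE, length(pt)))
  }
  tolower(stringr::str_trim(pt)) %in%
    tolower(stringr::str_trim(ime_terms))
}
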