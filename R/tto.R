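#' Compute time-to-onset samples with exclusion accounting
#'
#' Time-to-onset is the number of whole days from therapy start
#' (`START_DT`, THER file) to adverse-event occurrence (`EVENT_DT`, DEMO
#' file). A record contributes only when both dates are present at day
#' precision and the event does not precede the start; every excluded
#' record is tallied by reason, so retained + excluded equals the input
#' count. Same-day onsets are mapped to day 1 by default (onset days are
#' reported with a 1-day minimum), or excluded when `zero_day =
#' "exclude"`.
#'
#' @param analytic Analytic records from [build_analytic()] carrying
#'   `event_dt` and `start_dt`.
#' @param drug,pt Target drug and preferred term.
#' @param zero_day `"map_to_1"` (default) or `"exclude"`.
#' @return A tibble of class `tto_sample` with columns `primaryid`,
#'   `drug`, `pt`, `days`, and an `exclusions` attribute (tibble of
#'   `reason`, `n`) readable with [tto_exclusions()].
#' @export
compute_tto <- function(analytic, drug, pt,
                        zero_day = c("map_to_1", "exclude")) {
  zero_day <- arg_match(zero_day)
  target_drug <- drug
  target_pt <- pt
  rows <- analytic %>%
    filter(drug == target_drug, pt == target_pt) %>%
    distinct(primaryid, .keep_all = TRUE)

  ev <- parse_faers_date(rows$event_dt)
  st <- parse_faers_date(rows$start_dt)
  reason <- rep(NA_character_, nrow(rows))
  reason[ev$raw == "" | st$raw == ""] <- "missing_date"
  partial <- is.na(reason) &
    (ev$precision %in% c("month", "year") |
      st$precision %in% c("month", "year"))
  reason[partial] <- "partial_date"
  invalid <- is.na(reason) &
    (ev$precision == "invalid" | st$precision == "invalid")
  reason[invalid] <- "invalid_date"
  days <- as.numeric(ev$date - st$date)
  reason[is.na(reason) & days < 0] <- "event_precedes_start"
  if (zero_day == "exclude") {
    reason[is.na(reason) & days == 0] <- "zero_day"
  } else {
    days[!is.na(days) & days == 0] <- 1
  }

  keep <- is.na(reason)
  tally <- tibble(reason = reason[!keep]) %>%
    count(reason, name = "n") %>%
    arrange(reason)
  out <- tibble(
    primaryid = rows$primaryid[keep],
    drug = target_drug, pt = target_pt,
    days = days[keep]
  )
  attr(out, "exclusions") <- tally
  attr(out, "n_input") <- nrow(rows)
  class(out) <- c("tto_sample", class(out))
  out
}

#' Exclusion tally of a time-to-onset sample
#'
#' @param sample A `tto_sample` from [compute_tto()].
#' @return Tibble with columns `reason`, `n`.
#' @export
tto_exclusions <- function(sample) {
  attr(sample, "exclusions") %||% tibble(reason = character(0),
                                         n = integer(0))
}

# quartile position (n+1)p; integer positions take the order statistic,
# fractional positions average the two adjacent ones (yields half-integer
# quartiles on even-position data)
quartile_avg <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  pos <- (n + 1) * p
  lo <- max(1L, floor(pos))
  hi <- min(n, ceiling(pos))
  if (lo == hi) x[lo] else (x[lo] + x[hi]) / 2
}

#' Summarize a time-to-onset sample
#'
#' Median, quartiles, minimum and maximum of onset days. The default
#' quartile convention positions quartiles at `(n+1)p` and averages the
#' two adjacent order statistics at fractional positions (producing
#' half-integer quartiles such as 20.5); `convention = "interpolation"`
#' uses linear interpolation at the same positions
#' (`stats::quantile` type 6).
#'
#' @param sample A `tto_sample`, or a numeric vector of onset days.
#' @param convention `"averaging"` (default) or `"interpolation"`.
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `min`, `max`.
#' @examples
#' tto_summary(c(1, 2, 3, 4, 5))
#' @export
tto_summary <- function(sample, convention = c("averaging", "interpolation")) {
  convention <- arg_match(convention)
  days <- if (is.numeric(sample)) sample else sample$days
  if (!length(days)) abort("empty time-to-onset sample")
  qs <- if (convention == "averaging") {
    vapply(c(0.25, 0.5, 0.75), function(p) quartile_avg(days, p), numeric(1))
  } else {
    unname(quantile(days, c(0.25, 0.5, 0.75), type = 6))
  }
  tibble(
    n = length(days), median = qs[2], q1 = qs[1], q3 = qs[3],
    min = min(days), max = max(days)
  )
}

weibull_negll <- function(theta, t) {
  # theta = (log scale, log shape)
  alpha <- exp(theta[1])
  beta <- exp(theta[2])
  -sum(stats::dweibull(t, shape = beta, scale = alpha, log = TRUE))
}

#' Fit a two-parameter Weibull to onset days
#'
#' Maximum-likelihood fit of the Weibull density
#' `f(t) = (beta/alpha) (t/alpha)^(beta-1) exp(-(t/alpha)^beta)` with 95%
#' Wald intervals computed on the log-parameters from the observed
#' information matrix and exponentiated back (respecting positivity). The
#' optimizer is deterministic, started from moment-style values. With
#' `shape_fixed` the shape is held constant and the scale has the closed
#' form `(mean(t^beta))^(1/beta)` (the sample mean when `beta = 1`).
#'
#' @param sample A `tto_sample` or numeric vector of onset days (> 0).
#' @param shape_fixed Optional fixed shape parameter.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `weibull_fit`: list with `scale`, `scale_lo95`,
#'   `scale_hi95`, `shape`, `shape_lo95`, `shape_hi95`, `n`, `loglik`,
#'   `converged`, `failure_type`.
#' @export
fit_weibull <- function(sample, shape_fixed = NULL, conf_level = 0.95) {
  t <- if (is.numeric(sample)) sample else sample$days
  t <- t[is.finite(t)]
  if (length(t) < 3) abort("need at least 3 onset values to fit a Weibull")
  if (any(t <= 0)) abort("onset days must be positive")
  if (diff(range(t)) == 0) {
    abort("degenerate sample: all onset values identical")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)

  if (!is.null(shape_fixed)) {
    stopifnot(shape_fixed > 0)
    beta <- shape_fixed
    alpha <- mean(t^beta)^(1 / beta)
    # observed information for log(alpha) at the profile maximum
    info <- beta^2 * sum((t / alpha)^beta) / 1 # d2(-ll)/d(log a)2 = b^2 sum((t/a)^b)
    se_la <- sqrt(1 / info)
    ll <- -weibull_negll(c(log(alpha), log(beta)), t)
    fit <- list(
      scale = alpha,
      scale_lo95 = exp(log(alpha) - z * se_la),
      scale_hi95 = exp(log(alpha) + z * se_la),
      shape = beta, shape_lo95 = beta, shape_hi95 = beta,
      n = length(t), loglik = ll, converged = TRUE
    )
  } else {
    # moment-style start: shape from the log-sample spread, then the
    # profile scale
    s <- stats::sd(log(t))
    beta0 <- if (is.finite(s) && s > 0) min(max(1.2 / s, 0.05), 50) else 1
    alpha0 <- mean(t^beta0)^(1 / beta0)
    opt <- suppressWarnings(optim(c(log(alpha0), log(beta0)), weibull_negll,
      t = t,
      method = "BFGS", hessian = TRUE, control = list(maxit = 500)
    ))
    vc <- tryCatch(solve(opt$hessian), error = function(e) {
      matrix(NA_real_, 2, 2)
    })
    se <- sqrt(pmax(diag(vc), 0))
    est <- exp(opt$par)
    fit <- list(
      scale = est[1],
      scale_lo95 = exp(opt$par[1] - z * se[1]),
      scale_hi95 = exp(opt$par[1] + z * se[1]),
      shape = est[2],
      shape_lo95 = exp(opt$par[2] - z * se[2]),
      shape_hi95 = exp(opt$par[2] + z * se[2]),
      n = length(t), loglik = -opt$value,
      converged = opt$convergence == 0
    )
  }
  fit$failure_type <- classify_failure(fit$shape_lo95, fit$shape_hi95)
  structure(fit, class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("<weibull_fit>\n")
  cat(sprintf(
    "  scale %.4g (95%% CI %.4g-%.4g)\n",
    x$scale, x$scale_lo95, x$scale_hi95
  ))
  cat(sprintf(
    "  shape %.4g (95%% CI %.4g-%.4g)  ->  %s\n",
    x$shape, x$shape_lo95, x$shape_hi95, x$failure_type
  ))
  cat(sprintf("  n = %d, logLik = %.2f\n", x$n, x$loglik))
  invisible(x)
}

#' Classify the Weibull failure type from the shape-parameter CI
#'
#' A shape CI entirely below 1 indicates decreasing hazard ("early"
#' failure); a CI containing 1 indicates constant hazard ("random"); a CI
#' entirely above 1 indicates increasing hazard ("wear_out"). The three
#' branches are exhaustive and mutually exclusive over valid intervals.
#'
#' @param lo,hi Lower and upper 95% bounds for the shape, or a
#'   `weibull_fit` as `lo` (then `hi` is ignored).
#' @return `"early"`, `"random"`, or `"wear_out"` (vectorized).
#' @examples
#' classify_failure(0.42, 0.88)
#' @export
classify_failure <- function(lo, hi = NULL) {
  if (inherits(lo, "weibull_fit")) {
    hi <- lo$shape_hi95
    lo <- lo$shape_lo95
  }
  dplyr::case_when(
    hi < 1 ~ "early",
    lo > 1 ~ "wear_out",
    TRUE ~ "random"
  )
}

#' Kaplan--Meier cumulative incidence of onset
#'
#' With every report contributing an observed onset (no censoring in this
#' design), the Kaplan--Meier cumulative incidence `1 - S(t)` reduces to
#' the empirical CDF; the estimator is computed through
#' [survival::survfit()] for fidelity to the survival-analysis
#' presentation.
#'
#' @param sample A `tto_sample` or numeric vector of onset days.
#' @return Tibble of class `km_curve` with columns `day`,
#'   `cum_incidence`, `n_risk`, `n_event` and attribute `n`.
#' @export
km_curve <- function(sample) {
  days <- if (is.numeric(sample)) sample else sample$days
  if (!length(days)) abort("empty sample")
  sf <- survival::survfit(
    survival::Surv(days, rep(1, length(days))) ~ 1
  )
  out <- tibble(
    day = sf$time, cum_incidence = 1 - sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event
  )
  attr(out, "n") <- length(days)
  class(out) <- c("km_curve", class(out))
  out
}

#' Read cumulative incidence off a Kaplan--Meier curve
#'
#' Returns the step-function value at each requested day (0 before the
#' first event).
#'
#' @param curve A `km_curve`.
#' @param at Numeric vector of days.
#' @return Numeric vector of cumulative incidences.
#' @examples
#' km_incidence_at(km_curve(c(10, 20, 30, 40)), 30)
#' @export
km_incidence_at <- function(curve, at) {
  f <- stats::stepfun(curve$day, c(0, curve$cum_incidence), right = FALSE)
  f(at)
}

#' Two-group log-rank test on onset times
#'
#' Standard log-rank statistic over the pooled event times with p-value
#' from the chi-squared distribution on 1 degree of freedom, computed via
#' [survival::survdiff()]. Invariant to group labeling and within-group
#' observation order.
#'
#' @param days_a,days_b Numeric vectors of onset days (or `tto_sample`s).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(days_a, days_b) {
  da <- if (is.numeric(days_a)) days_a else days_a$days
  db <- if (is.numeric(days_b)) days_b else days_b$days
  if (!length(da) || !length(db)) {
    abort("both groups must have at least one event")
  }
  grp <- factor(c(rep("a", length(da)), rep("b", length(db))))
  sd <- survival::survdiff(
    survival::Surv(c(da, db), rep(1, length(da) + length(db))) ~ grp
  )
  tibble(
    statistic = sd$chisq, df = 1,
    p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n_a = length(da), n_b = length(db)
  )
}
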