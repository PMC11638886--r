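# log of the negative-binomial marginal of a gamma-Poisson count:
# a ~ Poisson(lambda E), lambda ~ Gamma(shape = alpha, rate = beta)
# => a ~ NB(size = alpha, prob = beta / (beta + E))
lnb <- function(a, alpha, beta, e) {
  dnbinom(a, size = alpha, prob = beta / (beta + e), log = TRUE)
}

# stable log( p exp(l1) + (1-p) exp(l2) )
log_mix <- function(l1, l2, p) {
  mx <- pmax(l1, l2)
  mx + log(p * exp(l1 - mx) + (1 - p) * exp(l2 - mx))
}

mgps_negll <- function(theta, a, e) {
  alpha1 <- exp(theta[1]); beta1 <- exp(theta[2])
  alpha2 <- exp(theta[3]); beta2 <- exp(theta[4])
  p <- plogis(theta[5])
  ll <- log_mix(lnb(a, alpha1, beta1, e), lnb(a, alpha2, beta2, e), p)
  if (any(!is.finite(ll))) {
    return(1e12)
  }
  -sum(ll)
}

#' Fit the MGPS two-gamma mixture prior
#'
#' The multi-item gamma-Poisson shrinker models each observed pair count
#' `a` as Poisson with mean `lambda E`, where the relative reporting rate
#' `lambda` follows a two-component gamma mixture prior
#' `p Gamma(alpha1, beta1) + (1-p) Gamma(alpha2, beta2)`. The five
#' hyperparameters are estimated by maximizing the marginal
#' negative-binomial mixture likelihood over all database (count,
#' expected) pairs, using multi-start Nelder--Mead followed by a BFGS
#' polish; the optimization is deterministic. After fitting, components
#' are ordered so that component 1 has the larger prior mean
#' `alpha / beta`.
#'
#' @param a Integer vector of observed pair counts.
#' @param expected Numeric vector of expected counts `E > 0`.
#' @param starts Optional list of numeric length-5 start vectors
#'   `(alpha1, beta1, alpha2, beta2, p_mix)` on the natural scale; defaults
#'   to a fixed grid including the classic DuMouchel start
#'   `(0.2, 0.1, 2, 4, 1/3)`.
#' @return Object of class `mgps_prior`: a list with `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `p_mix`, `loglik`, `converged`, `n_pairs`.
#' @references DuMouchel W (1999) Bayesian data mining in large frequency
#'   tables, with an application to the FDA spontaneous reporting system.
#'   The American Statistician 53(3):177-190.
#' @export
fit_mgps_prior <- function(a, expected, starts = NULL) {
  ok <- is.finite(a) & is.finite(expected) & expected > 0 & a >= 0
  a <- a[ok]
  e <- expected[ok]
  if (length(a) < 2) {
    abort("need at least 2 (count, expected) pairs to fit the MGPS prior")
  }
  if (length(a) < 100) {
    warn("fewer than 100 pairs; MGPS hyperparameter estimates may be unstable")
  }
  if (is.null(starts)) {
    starts <- list(
      c(0.2, 0.1, 2, 4, 1 / 3),
      c(0.5, 0.5, 1, 1, 0.5),
      c(0.1, 0.05, 5, 5, 0.2),
      c(1, 2, 0.3, 0.1, 0.5),
      c(2, 2, 0.2, 0.2, 0.8)
    )
  }
  to_theta <- function(s) c(log(s[1:4]), qlogis(s[5]))
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      {
        nm <- optim(to_theta(s), mgps_negll,
          a = a, e = e,
          method = "Nelder-Mead", control = list(maxit = 2000)
        )
        optim(nm$par, mgps_negll,
          a = a, e = e,
          method = "BFGS", control = list(maxit = 500)
        )
      },
      error = function(err) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("MGPS prior optimization failed from all starts")
  th <- best$par
  pars <- list(
    alpha1 = exp(th[1]), beta1 = exp(th[2]),
    alpha2 = exp(th[3]), beta2 = exp(th[4]),
    p_mix = plogis(th[5])
  )
  # canonical component order: component 1 has the larger prior mean
  if (pars$alpha1 / pars$beta1 < pars$alpha2 / pars$beta2) {
    pars <- list(
      alpha1 = pars$alpha2, beta1 = pars$beta2,
      alpha2 = pars$alpha1, beta2 = pars$beta1,
      p_mix = 1 - pars$p_mix
    )
  }
  structure(
    c(pars, list(
      loglik = -best$value, converged = any_conv, n_pairs = length(a)
    )),
    class = "mgps_prior"
  )
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("<mgps_prior>  two-component gamma mixture\n")
  cat(sprintf(
    "  comp1: Gamma(%.4g, %.4g)  weight %.3f\n",
    x$alpha1, x$beta1, x$p_mix
  ))
  cat(sprintf(
    "  comp2: Gamma(%.4g, %.4g)  weight %.3f\n",
    x$alpha2, x$beta2, 1 - x$p_mix
  ))
  cat(sprintf(
    "  logLik %.2f on %d pairs; converged: %s\n",
    x$loglik, x$n_pairs, x$converged
  ))
  invisible(x)
}

#' Simulate (count, expected) pairs from an MGPS prior
#'
#' Draws relative reporting rates from the two-gamma mixture and counts
#' from the conditional Poisson, for prior-recovery studies.
#'
#' @param n Number of pairs.
#' @param prior An `mgps_prior` or a list with `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `p_mix`.
#' @param expected Expected counts (recycled); default log-uniform on
#'   \[0.1, 1000\].
#' @return Tibble with columns `a`, `expected`.
#' @export
simulate_mgps_pairs <- function(n, prior, expected = NULL) {
  if (is.null(expected)) {
    expected <- exp(runif(n, log(0.1), log(1000)))
  }
  expected <- rep_len(expected, n)
  comp1 <- runif(n) < prior$p_mix
  lambda <- ifelse(
    comp1,
    rgamma(n, shape = prior$alpha1, rate = prior$beta1),
    rgamma(n, shape = prior$alpha2, rate = prior$beta2)
  )
  tibble(a = stats::rpois(n, lambda * expected), expected = expected)
}

#' Empirical-Bayes geometric mean and 5th posterior percentile
#'
#' Given the fitted prior, the posterior of the relative reporting rate
#' for a pair with count `a` and expected `E` is again a two-component
#' gamma mixture with components `Gamma(alpha_j + a, beta_j + E)` and
#' weights proportional to the prior weight times the marginal
#' negative-binomial likelihood. `EBGM = 2^(E[log2 lambda | a])` uses the
#' digamma closed form per component; `EBGM05` is the 5th percentile of
#' the posterior mixture, root-found on the mixture CDF.
#'
#' @param a Observed pair counts (vectorized).
#' @param expected Expected counts under independence.
#' @param prior An `mgps_prior` from [fit_mgps_prior()].
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @export
ebgm_mgps <- function(a, expected, prior) {
  if (!all(c("alpha1", "beta1", "alpha2", "beta2", "p_mix") %in%
    names(prior))) {
    abort("`prior` must carry alpha1, beta1, alpha2, beta2, p_mix")
  }
  if (any(!is.finite(unlist(prior[c(
    "alpha1", "beta1", "alpha2", "beta2", "p_mix"
  )])))) {
    abort("`prior` has non-finite hyperparameters")
  }
  # E = 0 is admissible only with a = 0 (the posterior is then the prior)
  ok <- is.finite(a) & is.finite(expected) & a >= 0 &
    (expected > 0 | a == 0)
  l1 <- lnb(a, prior$alpha1, prior$beta1, expected)
  l2 <- lnb(a, prior$alpha2, prior$beta2, expected)
  # posterior weight of component 1, computed stably on the logit scale
  q1 <- plogis(qlogis(prior$p_mix) + l1 - l2)
  s1 <- prior$alpha1 + a
  r1 <- prior$beta1 + expected
  s2 <- prior$alpha2 + a
  r2 <- prior$beta2 + expected
  elog <- q1 * (digamma(s1) - log(r1)) + (1 - q1) * (digamma(s2) - log(r2))
  ebgm <- exp(elog)

  ebgm05 <- vapply(seq_along(a), function(i) {
    if (!ok[i]) {
      return(NA_real_)
    }
    qs <- c(
      qgamma(0.05, shape = s1[i], rate = r1[i]),
      qgamma(0.05, shape = s2[i], rate = r2[i])
    )
    lo <- min(qs)
    hi <- max(qs)
    if (hi - lo < 1e-12) {
      return(lo)
    }
    f <- function(x) {
      q1[i] * pgamma(x, shape = s1[i], rate = r1[i]) +
        (1 - q1[i]) * pgamma(x, shape = s2[i], rate = r2[i]) - 0.05
    }
    uniroot(f, c(lo, hi), tol = 1e-10, extendInt = "upX")$root
  }, numeric(1))

  tibble(ebgm = ifelse(ok, ebgm, NA_real_), ebgm05 = ebgm05)
}
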