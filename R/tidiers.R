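#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Weibull fit
#'
#' @param x A `weibull_fit` from [fit_weibull()].
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble(
    term = c("scale", "shape"),
    estimate = c(x$scale, x$shape),
    conf.low = c(x$scale_lo95, x$shape_lo95),
    conf.high = c(x$scale_hi95, x$shape_hi95)
  )
}

#' Glance at a Weibull fit
#'
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `logLik`, `converged`, `failure_type`.
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble(
    n = x$n, logLik = x$loglik, converged = x$converged,
    failure_type = x$failure_type
  )
}

#' Tidy an MGPS prior
#'
#' @param x An `mgps_prior` from [fit_mgps_prior()].
#' @param ... Unused.
#' @return Tibble with one row per hyperparameter.
#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "p_mix"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$p_mix)
  )
}

#' Glance at an MGPS prior
#'
#' @param x An `mgps_prior`.
#' @param ... Unused.
#' @return One-row tibble: `n_pairs`, `logLik`, `converged`.
#' @export
glance.mgps_prior <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, logLik = x$loglik, converged = x$converged)
}
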