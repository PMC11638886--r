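test_that("EBGM has the digamma closed form under a degenerate prior", {
  prior <- list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, p_mix = 1)
  out <- ebgm_mgps(0, 0, prior)
  expect_equal(out$ebgm, exp(digamma(1))) # = exp(-0.57722) ~ 0.5615
  expect_equal(round(out$ebgm, 4), 0.5615)
  # and the 5th percentile is the prior's
  expect_equal(out$ebgm05, qgamma(0.05, 1, 1))
})

test_that("shrinkage vanishes for large counts", {
  prior <- list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                p_mix = 1 / 3)
  out <- ebgm_mgps(1e5, 2e4, prior)
  expect_equal(out$ebgm, 1e5 / 2e4, tolerance = 1e-3)
})

test_that("posterior quantiles match a Monte-Carlo oracle", {
  prior <- list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                p_mix = 1 / 3)
  set.seed(505)
  grid <- expand.grid(a = c(1, 10, 200), e = c(0.5, 10, 300))
  out <- ebgm_mgps(grid$a, grid$e, prior)
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; e <- grid$e[i]
    l1 <- dnbinom(a, size = prior$alpha1,
                  prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
    l2 <- dnbinom(a, size = prior$alpha2,
                  prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
    q1 <- plogis(qlogis(prior$p_mix) + l1 - l2)
    n_mc <- 2e5
    comp <- runif(n_mc) < q1
    draws <- ifelse(comp,
      rgamma(n_mc, prior$alpha1 + a, rate = prior$beta1 + e),
      rgamma(n_mc, prior$alpha2 + a, rate = prior$beta2 + e)
    )
    mc05 <- quantile(draws, 0.05)
    expect_lt(abs(out$ebgm05[i] / mc05 - 1), 0.02)
    expect_lt(abs(log(out$ebgm[i]) - mean(log(draws))), 0.02)
  }
  expect_true(all(out$ebgm05 < out$ebgm))
})

test_that("hyperparameters are recovered from simulated pairs", {
  truth <- list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                p_mix = 1 / 3)
  set.seed(606)
  pairs <- simulate_mgps_pairs(15000, truth)
  fit <- suppressWarnings(
    fit_mgps_prior(pairs$a, pairs$expected,
                   starts = list(c(0.5, 0.5, 1, 1, 0.5)))
  )
  # component 1 is the larger-mean (elevated-risk) component by convention
  expect_lt(abs(fit$alpha1 / truth$alpha1 - 1), 0.25)
  expect_lt(abs(fit$beta1 / truth$beta1 - 1), 0.25)
  expect_lt(abs(fit$alpha2 / truth$alpha2 - 1), 0.25)
  expect_lt(abs(fit$beta2 / truth$beta2 - 1), 0.25)
  expect_lt(abs(fit$p_mix - truth$p_mix), 0.05)
  expect_true(fit$converged)
})

test_that("one-component data is recovered as an effectively single gamma", {
  set.seed(707)
  n <- 20000
  e <- exp(runif(n, log(0.1), log(1000)))
  lambda <- rgamma(n, shape = 2, rate = 4)
  a <- rpois(n, lambda * e)
  fit <- fit_mgps_prior(a, e)
  # the fitted mixture's lambda distribution must match the single gamma
  # (the weight split between coincident components is not identified)
  p_grid <- seq(0.05, 0.95, by = 0.05)
  q_true <- qgamma(p_grid, shape = 2, rate = 4)
  mix_cdf <- function(x) {
    fit$p_mix * pgamma(x, fit$alpha1, rate = fit$beta1) +
      (1 - fit$p_mix) * pgamma(x, fit$alpha2, rate = fit$beta2)
  }
  expect_lt(max(abs(mix_cdf(q_true) - p_grid)), 0.03)
})

test_that("too few pairs is an error", {
  expect_error(fit_mgps_prior(1, 1), "at least 2")
})

test_that("EBGM never overshoots the raw ratio under a null-fitted prior", {
  set.seed(808)
  n <- 5000
  e <- exp(runif(n, log(0.5), log(200)))
  a <- rpois(n, e) # pure null: lambda = 1
  fit <- fit_mgps_prior(a, e, starts = list(c(1, 1, 1, 1, 0.5)))
  idx <- which(a >= 1)[1:1000]
  out <- ebgm_mgps(a[idx], e[idx], fit)
  # allowance 1/(2a): the log-concavity bias of the posterior geometric
  # mean, which can exceed a near-zero raw log ratio
  expect_true(all(
    abs(log(out$ebgm)) <= abs(log(a[idx] / e[idx])) + 1 / (2 * a[idx]) + 1e-6
  ))
})
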