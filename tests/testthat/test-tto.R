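test_that("onset days are calendar differences with exclusion accounting", {
  an <- tto_fixture(
    event = c("20230110", "20221220", "202301", "", "20230101", "20230105"),
    start = c("20230101", "20230101", "20230101", "20230101", "20230101",
              "20230101")
  )
  smp <- compute_tto(an, "duloxetine", "Erectile dysfunction")
  # row 1: 9 days; row 5: same-day mapped to 1; row 6: 4 days
  expect_equal(sort(smp$days), c(1, 4, 9))
  tally <- tto_exclusions(smp)
  expect_equal(
    setNames(tally$n, tally$reason),
    c(event_precedes_start = 1L, missing_date = 1L, partial_date = 1L)
  )
  # retained + excluded = input
  expect_equal(nrow(smp) + sum(tally$n), 6)
})

test_that("zero-day onsets can be excluded instead of mapped", {
  an <- tto_fixture(event = c("20230101"), start = c("20230101"))
  smp <- compute_tto(an, "duloxetine", "Erectile dysfunction",
                     zero_day = "exclude")
  expect_equal(nrow(smp), 0)
  expect_equal(tto_exclusions(smp)$reason, "zero_day")
})

test_that("quartiles follow the averaging convention", {
  s <- tto_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 1.5)
  expect_equal(s$q3, 4.5)
  s1 <- tto_summary(7)
  expect_equal(unlist(s1[c("median", "q1", "q3", "min", "max")],
                      use.names = FALSE), rep(7, 5))
  # n = 17 places the lower quartile at position 4.5: half-integers arise
  set.seed(9)
  x <- sort(sample(1:1200, 17))
  s17 <- tto_summary(x)
  expect_equal(s17$q1, (x[4] + x[5]) / 2)
  expect_equal(s17$median, x[9])
  expect_error(tto_summary(numeric(0)), "empty")
})

test_that("Weibull MLE recovers known parameters and agrees with an
           independent fitter", {
  set.seed(2024)
  x <- rweibull(2000, shape = 0.65, scale = 110)
  fit <- fit_weibull(x)
  expect_lt(abs(fit$scale / 110 - 1), 0.05)
  expect_lt(abs(fit$shape / 0.65 - 1), 0.05)
  expect_true(fit$converged)
  expect_true(fit$scale_lo95 < fit$scale & fit$scale < fit$scale_hi95)
  # cross-check point estimates against fitdistrplus
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(fit$scale, unname(ref$estimate["scale"]), tolerance = 1e-4)
})

test_that("with shape fixed at 1 the scale estimate is the sample mean", {
  set.seed(11)
  x <- rexp(500, rate = 1 / 50)
  fit <- fit_weibull(x, shape_fixed = 1)
  expect_equal(fit$scale, mean(x))
  expect_equal(fit$shape, 1)
})

test_that("three distinct values yield the true likelihood maximum", {
  x <- c(2, 10, 50)
  fit <- fit_weibull(x)
  expect_true(fit$converged)
  expect_true(all(is.finite(c(fit$scale_lo95, fit$scale_hi95,
                              fit$shape_lo95, fit$shape_hi95))))
  # grid-search oracle: no (scale, shape) beats the reported optimum
  grid <- expand.grid(
    scale = exp(seq(log(1), log(200), length.out = 60)),
    shape = exp(seq(log(0.1), log(5), length.out = 60))
  )
  ll <- mapply(function(a, b) {
    sum(dweibull(x, shape = b, scale = a, log = TRUE))
  }, grid$scale, grid$shape)
  expect_gte(fit$loglik, max(ll) - 1e-6)
  expect_error(fit_weibull(c(5, 5, 5)), "degenerate")
})

test_that("failure typing partitions the shape-CI space", {
  expect_equal(classify_failure(0.42, 0.88), "early")
  expect_equal(classify_failure(0.9, 1.2), "random")
  expect_equal(classify_failure(1.05, 1.6), "wear_out")
  # exhaustive and mutually exclusive over random valid CIs
  set.seed(3)
  lo <- runif(200, 0.1, 2)
  hi <- lo + runif(200, 0.01, 1)
  cls <- classify_failure(lo, hi)
  expect_true(all(cls %in% c("early", "random", "wear_out")))
  expect_equal(cls == "early", hi < 1)
  expect_equal(cls == "wear_out", lo > 1)
})

test_that("KM cumulative incidence equals the empirical CDF when uncensored", {
  days <- c(10, 20, 30, 40)
  cv <- km_curve(days)
  expect_equal(km_incidence_at(cv, 30), 0.75)
  expect_equal(km_incidence_at(cv, 5), 0)
  expect_equal(km_incidence_at(cv, 100), 1)
  # 6 of 17 onsets within 30 days -> 35.29%
  d17 <- c(rep(10, 6), rep(100, 11))
  expect_equal(round(100 * km_incidence_at(km_curve(d17), 30), 2), 35.29)
  # ECDF identity on random samples
  set.seed(14)
  x <- sample(1:50, 60, replace = TRUE)
  cv <- km_curve(x)
  f <- ecdf(x)
  expect_equal(cv$cum_incidence, unname(f(cv$day)), tolerance = 1e-12)
  expect_true(all(diff(cv$cum_incidence) >= 0))
})

test_that("log-rank is symmetric, order-invariant, and matches the
           first-principles statistic", {
  x <- c(1, 5, 9, 14, 30)
  expect_equal(logrank_test(x, x)$statistic, 0, tolerance = 1e-12)
  expect_equal(logrank_test(x, x)$p_value, 1, tolerance = 1e-9)
  set.seed(21)
  y <- round(rweibull(40, 0.7, 100)) + 1
  z <- round(rweibull(35, 1.2, 40)) + 1
  r1 <- logrank_test(y, z)
  r2 <- logrank_test(sample(y), sample(z))
  expect_equal(r1, r2)
  # group labeling invariance
  expect_equal(logrank_test(z, y)$statistic, r1$statistic)
  # independent oracle
  expect_equal(r1$statistic, logrank_stat_oracle(y, z), tolerance = 1e-8)
  expect_error(logrank_test(numeric(0), y), "at least one")
})
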