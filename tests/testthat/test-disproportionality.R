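test_that("ROR matches closed-form evaluation with a symmetric log CI", {
  r <- ror_stats(5, 5, 5, 5)
  expect_equal(r$ror, 1)
  expect_equal(log(r$ror_lo95), -log(r$ror_hi95))

  # frozen hand evaluation: lnROR = 2.3979, SE = 0.34816
  r <- ror_stats(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  expect_equal(r$ror_lo95, exp(log(11) - qnorm(0.975) *
    sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)))
  expect_lt(abs(r$ror_lo95 - 5.56), 0.02)
  expect_lt(abs(r$ror_hi95 - 21.76), 0.02)

  # zero cells leave the signal undefined
  expect_true(all(is.na(ror_stats(0, 10, 10, 100))))
  # ... unless the Haldane correction is requested
  expect_false(anyNA(ror_stats(0, 10, 10, 100, correction = "haldane")))
})

test_that("PRR and Pearson chi-squared match independent evaluation", {
  # independence: equal reporting proportions
  r <- prr_stats(10, 90, 30, 270)
  expect_equal(r$prr, 1)
  expect_equal(r$chi2, 0)

  r <- prr_stats(10, 90, 100, 9900)
  expect_equal(r$prr, 10)
  oracle <- unname(suppressWarnings(chisq.test(
    matrix(c(10, 90, 100, 9900), 2, 2, byrow = TRUE),
    correct = FALSE
  ))$statistic)
  expect_equal(r$chi2, oracle)
  # frozen hand evaluation with E11 = 100*110/10100
  expect_equal(round(r$chi2, 2), 74.45)

  # degenerate margins are undefined
  expect_true(is.na(prr_stats(3, 0, 0, 10)$prr))
})

test_that("information component follows the gamma-posterior form", {
  expect_equal(bcpnn_ic(10, 10)$ic, 0)
  expect_equal(bcpnn_ic(10, 2)$ic, log2(10.5 / 2.5))
  expect_equal(round(bcpnn_ic(10, 2)$ic, 4), 2.0704)
  expect_true(is.na(bcpnn_ic(5, 0)$ic))

  # Monte-Carlo oracle for the lower credible bound
  set.seed(404)
  for (case in list(c(a = 3, e = 0.8), c(a = 50, e = 20),
                    c(a = 500, e = 700))) {
    draws <- rgamma(2e5, shape = case["a"] + 0.5, rate = case["e"] + 0.5)
    mc <- log2(quantile(draws, 0.025))
    expect_lt(abs(bcpnn_ic(case["a"], case["e"])$ic025 - mc), 0.02)
  }
})

test_that("signal evaluation applies the reporting rule and concordance", {
  crit <- signal_criteria()
  stats <- tibble::tibble(
    n = c(135, 2, 50), a = n,
    ror_lo95 = c(1.1, 8.0, 0.99),
    prr = c(1.31, 9, 1), chi2 = c(9.64, 50, 0),
    ic025 = c(-1.28, 2, -1), ebgm05 = c(1.13, 4, 0.9)
  )
  out <- apply_signal_criteria(stats, crit)
  expect_equal(out$is_signal, c(TRUE, FALSE, FALSE))
  # first row: only the ROR rule holds (PRR < 2, IC025 < 0, EBGM05 < 2)
  expect_equal(out$algorithms_met[1], "ROR")
  # row 2: n = 2 fails the report-count gate of both the ROR and PRR rules
  expect_equal(out$n_algorithms[2], 2L)
  expect_false(out$sig_prr[2])
  expect_true(out$sig_bcpnn[2] && out$sig_mgps[2])
  # undefined statistics fail their rules
  und <- apply_signal_criteria(
    tibble::tibble(n = 10, a = 10, ror_lo95 = NA_real_, prr = NA_real_,
                   chi2 = NA_real_, ic025 = NA_real_, ebgm05 = NA_real_),
    crit
  )
  expect_false(und$is_signal)
  expect_equal(und$n_algorithms, 0L)
})

test_that("PRR and ROR order by the sample odds ratio", {
  set.seed(77)
  n <- 2000
  a <- sample(1:300, n, TRUE)
  b <- sample(1:3000, n, TRUE)
  cc <- sample(1:3000, n, TRUE)
  d <- sample(1:30000, n, TRUE)
  ror <- ror_stats(a, b, cc, d)$ror
  prr <- prr_stats(a, b, cc, d)$prr
  or_ge_1 <- a * d >= b * cc
  expect_true(all(prr[or_ge_1] <= ror[or_ge_1] + 1e-12))
  expect_true(all(prr[!or_ge_1] >= ror[!or_ge_1] - 1e-12))
})

test_that("interval bounds bracket their point estimates", {
  set.seed(88)
  a <- sample(1:200, 500, TRUE)
  b <- sample(1:2000, 500, TRUE)
  cc <- sample(1:2000, 500, TRUE)
  d <- sample(1:20000, 500, TRUE)
  tab <- tibble::tibble(a = a, b = b, c = cc, d = d)
  st <- disproportionality_stats(tab)
  expect_true(all(st$ror_lo95 < st$ror & st$ror < st$ror_hi95))
  expect_true(all(st$prr_lo95 < st$prr & st$prr < st$prr_hi95))
  expect_true(all(st$ic025 < st$ic))
})

test_that("IME flagging is case-insensitive exact matching", {
  imes <- c("Erectile dysfunction", "Retrograde ejaculation")
  expect_true(flag_ime("Erectile dysfunction", imes))
  expect_true(flag_ime("ERECTILE DYSFUNCTION", imes))
  expect_false(flag_ime("Erectile", imes))
  expect_false(flag_ime("Erectile dysfunction", character(0)))
})
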