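test_that("invalid configurations are rejected with the offending field named", {
  expect_error(faers_config(n_cases = 0), "n_cases")
  expect_error(
    faers_config(drugs = tibble::tibble(name = "x", prob = 1.5)),
    "drugs"
  )
  expect_error(
    faers_config(signals = tibble::tibble(
      drug = "nosuch", pt = "Nausea", rr = 2
    )),
    "signals"
  )
  expect_error(
    faers_config(tto_models = tibble::tibble(
      drug = "duloxetine", pt = "Erectile dysfunction",
      scale = -1, shape = 0.5
    )),
    "tto_models"
  )
  expect_error(faers_config(duplicate_rate = 1), "duplicate_rate")
  expect_error(
    faers_config(date_window = as.Date(c("2020-01-01", "2019-01-01"))),
    "date_window"
  )
})

test_that("identical config and seed reproduce identical output", {
  cfg <- small_config(n_cases = 500, seed = 9)
  d1 <- generate_faers(cfg)
  d2 <- generate_faers(cfg)
  expect_identical(d1$tables, d2$tables)
  expect_identical(d1$ledger, d2$ledger)
})

test_that("without duplicates every CASEID appears once and dedup is a no-op", {
  cfg <- small_config(
    n_cases = 800, seed = 3, duplicate_rate = 0,
    signals = tibble::tibble(
      drug = character(0), pt = character(0), rr = numeric(0)
    ),
    missingness = list(
      sex = 0, age = 0, weight = 0, event_dt = 0, country = 0,
      occupation = 0
    )
  )
  ds <- generate_faers(cfg)
  expect_equal(anyDuplicated(ds$tables$demo$caseid), 0)
  clean <- dedup_faers(ds$tables)
  expect_equal(clean$demo, ds$tables$demo)
  expect_equal(nrow(ds$ledger$duplicate_map), 0)
})

test_that("each case has exactly one PS mention and at least one reaction", {
  ds <- generate_faers(small_config(n_cases = 600, seed = 5))
  ps <- dplyr::filter(ds$tables$drug, role_cod == "PS")
  # margin conservation: PS mentions = unique cases + duplicate versions
  expect_equal(nrow(ps),
               ds$ledger$n_cases + nrow(ds$ledger$duplicate_map))
  expect_equal(anyDuplicated(ps$primaryid), 0)
  reac_per_case <- dplyr::count(ds$tables$reac, primaryid)
  expect_setequal(ds$tables$demo$primaryid, reac_per_case$primaryid)
  expect_true(all(reac_per_case$n >= 1))
})

test_that("an injected RR=50 pair dominates the realized odds ratio", {
  cfg <- small_config(
    n_cases = 20000, seed = 17,
    signals = tibble::tibble(
      drug = "duloxetine", pt = "Retrograde ejaculation", rr = 50
    ),
    duplicate_rate = 0
  )
  ds <- generate_faers(cfg)
  # brute-force recount of the realized 2x2 table from the raw tables
  ps <- dplyr::filter(ds$tables$drug, role_cod == "PS")
  cases_drug <- ps$primaryid[ps$drugname == "duloxetine"]
  cases_pt <- unique(
    ds$tables$reac$primaryid[ds$tables$reac$pt == "Retrograde ejaculation"]
  )
  all_cases <- ds$tables$demo$primaryid
  a <- length(intersect(cases_drug, cases_pt))
  b <- length(setdiff(cases_drug, cases_pt))
  cc <- length(setdiff(cases_pt, cases_drug))
  dd <- length(all_cases) - a - b - cc
  expect_gt((a * dd) / (b * cc), 10)
})

test_that("duplicate versions are always older per the FDA ordering", {
  ds <- generate_faers(small_config(n_cases = 3000, seed = 23,
                                    duplicate_rate = 0.25))
  dmap <- ds$ledger$duplicate_map
  expect_gt(nrow(dmap), 0)
  demo <- ds$tables$demo
  old <- demo[match(dmap$superseded_primaryid, demo$primaryid), ]
  new <- demo[match(dmap$surviving_primaryid, demo$primaryid), ]
  expect_true(all(old$caseid == new$caseid))
  expect_true(all(
    old$fda_dt < new$fda_dt |
      (old$fda_dt == new$fda_dt & old$primaryid < new$primaryid)
  ))
})

test_that("generated onset days follow the configured Weibull", {
  # make the modelled pair near-certain so one run yields >= 5000 draws
  cfg <- faers_config(
    n_cases = 12000, seed = 31,
    drugs = tibble::tibble(name = c("drugx", "other"), prob = c(0.6, 0.4)),
    events = tibble::tibble(
      pt = c("EventX", "Nausea"), soc = c("S", "S"), prob = c(0.9, 0.1)
    ),
    signals = tibble::tibble(drug = "drugx", pt = "EventX", rr = 9),
    tto_models = tibble::tibble(
      drug = "drugx", pt = "EventX", scale = 110, shape = 0.65
    ),
    duplicate_rate = 0, partial_date_rate = 0,
    missingness = list(
      sex = 0, age = 0, weight = 0, event_dt = 0, country = 0,
      occupation = 0
    )
  )
  ds <- generate_faers(cfg)
  ps <- dplyr::filter(ds$tables$drug, role_cod == "PS",
                      drugname == "drugx")
  hit <- intersect(
    ps$primaryid,
    ds$tables$reac$primaryid[ds$tables$reac$pt == "EventX"]
  )
  demo <- ds$tables$demo
  ther <- ds$tables$ther
  ev <- as.Date(demo$event_dt[match(hit, demo$primaryid)], "%Y%m%d")
  st <- as.Date(ther$start_dt[match(hit, ther$primaryid)], "%Y%m%d")
  days <- as.numeric(ev - st)
  expect_gte(length(days), 5000)
  # onset = ceiling of a Weibull draw: compare the ECDF at integer days
  # with the continuous CDF
  ks <- max(abs(ecdf(days)(sort(unique(days))) -
    pweibull(sort(unique(days)), shape = 0.65, scale = 110)))
  expect_lt(ks, 0.05)
})

test_that("ASCII quarters round-trip and reject embedded delimiters", {
  dir <- withr::local_tempdir()
  ds <- generate_faers(small_config(n_cases = 300, seed = 12))
  paths <- write_faers_quarter(ds, dir, quarter = "24Q1")
  expect_true(all(file.exists(paths)))
  back <- read_faers_quarter(dir)
  for (nm in names(ds$tables)) {
    expect_equal(nrow(back[[nm]]), nrow(ds$tables[[nm]]), info = nm)
  }
  # identical generation writes byte-identical files
  dir2 <- withr::local_tempdir()
  write_faers_quarter(generate_faers(small_config(n_cases = 300, seed = 12)),
                      dir2, quarter = "24Q1")
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]),
                     readLines(file.path(dir2, basename(paths[[nm]]))))
  }
  bad <- list(demo = tibble::tibble(primaryid = 1, note = "a$b"))
  expect_error(write_faers_quarter(bad, dir), "delimiter",
               class = "faersignal_validation_error")
})

test_that("an empty dataset writes header-only files", {
  dir <- withr::local_tempdir()
  empty <- list(demo = tibble::tibble(
    primaryid = numeric(0), caseid = numeric(0), fda_dt = character(0)
  ))
  paths <- write_faers_quarter(empty, dir)
  expect_equal(length(readLines(paths[["demo"]])), 1)
})
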