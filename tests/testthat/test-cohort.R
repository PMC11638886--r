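# a fixed pair-table fixture: drug total 1000, pt total 50, overlap 10,
# database total 100000 records
fixture_pairs <- function() {
  tibble::tibble(
    primaryid = seq_len(100000),
    drug = c(rep("target", 1000), rep("other", 99000)),
    pt = c(
      rep("EventX", 10), rep("EventY", 990), # target drug rows
      rep("EventX", 40), rep("EventY", 98960) # other drug rows
    ),
    sex = rep(c("male", "female"), 50000),
    age_band = "45to59"
  )
}

test_that("contingency cells follow the 2x2 layout on a fixed fixture", {
  tab <- build_contingency(fixture_pairs(), "target", "EventX")
  expect_equal(unlist(tab[c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 990, 40, 98960))
  expect_equal(tab$n_total, 100000)
  expect_false(tab$degenerate)
})

test_that("stratified margins equal an independent brute-force recount", {
  pairs <- fixture_pairs()
  male <- dplyr::filter(pairs, sex == "male")
  tab <- build_contingency(pairs, "target", "EventX",
                           stratum = subgroup("male"))
  oracle <- brute_contingency(male, "target", "EventX")
  expect_equal(unlist(tab[c("a", "b", "c", "d")], use.names = FALSE),
               unname(oracle))
  expect_equal(tab$n_total, nrow(male))
})

test_that("vectorized tables match per-pair construction and brute force", {
  set.seed(55)
  pairs <- tibble::tibble(
    primaryid = sample(3000, 8000, replace = TRUE),
    drug = sample(paste0("d", 1:6), 8000, replace = TRUE),
    pt = sample(paste0("e", 1:10), 8000, replace = TRUE),
    sex = sample(c("male", "female", "unknown"), 8000, replace = TRUE),
    age_band = sample(c("under45", "45to59", "over59", NA), 8000, TRUE)
  ) %>% dplyr::distinct(primaryid, drug, pt, .keep_all = TRUE)
  tabs <- contingency_tables(pairs, drugs = c("d1", "d2"))
  for (i in sample(nrow(tabs), 5)) {
    oracle <- brute_contingency(pairs, tabs$drug[i], tabs$pt[i])
    expect_equal(unlist(tabs[i, c("a", "b", "c", "d")], use.names = FALSE),
                 unname(oracle))
  }
  # full-table identity a+b+c+d = N
  expect_true(all(tabs$a + tabs$b + tabs$c + tabs$d == tabs$n_total))
  # sum of a over all PTs of a drug = the drug's reaction-record total
  all_tabs <- contingency_tables(pairs, drugs = "d1")
  expect_equal(sum(all_tabs$a), sum(pairs$drug == "d1"))
})

test_that("sex subgroup cells sum to at most the overall cell", {
  ds <- generate_faers(small_config(n_cases = 3000, seed = 19))
  clean <- dedup_faers(ds$tables)
  pairs <- build_pair_table(clean, default_synonym_map())
  overall <- contingency_tables(pairs, drugs = "duloxetine")
  by_sex <- contingency_tables(pairs, drugs = "duloxetine", by_sex = TRUE) %>%
    dplyr::filter(sex != "all") %>%
    dplyr::summarise(a = sum(a), .by = c(drug, pt))
  joined <- dplyr::inner_join(overall, by_sex, by = c("drug", "pt"),
                              suffix = c("", "_sexsum"))
  expect_true(all(joined$a_sexsum <= joined$a))
})

test_that("analytic records conserve counts and expose the counting unit", {
  ds <- generate_faers(small_config(n_cases = 2500, seed = 8))
  clean <- dedup_faers(ds$tables)
  an <- build_analytic(clean, default_synonym_map())
  expect_equal(attr(an, "counting_unit"), "record")
  # one analytic case row per PS target case under case counting
  ps <- filter_primary_suspect(clean$drug, default_synonym_map())
  expect_equal(
    nrow(dplyr::distinct(an, primaryid, drug)),
    nrow(dplyr::distinct(ps, primaryid, normalized_name))
  )
  # a case with k reactions contributes k records
  k <- dplyr::count(clean$reac, primaryid)
  an_k <- dplyr::count(an, primaryid)
  merged <- dplyr::inner_join(an_k, k, by = "primaryid",
                              suffix = c("_an", "_reac"))
  expect_true(all(merged$n_an == merged$n_reac))
})

test_that("a missing target drug yields an empty result with a warning", {
  ds <- generate_faers(small_config(n_cases = 200, seed = 4))
  clean <- dedup_faers(ds$tables)
  map <- tibble::tibble(synonym = "nosuchdrug", generic = "nosuchdrug")
  expect_warning(an <- build_analytic(clean, map), "no primary-suspect")
  expect_equal(nrow(an), 0)
})

test_that("descriptive percentages recompute from counts, half-up at 1 dp", {
  an <- tibble::tibble(
    primaryid = 1:10, caseid = 1:10, drug = "duloxetine", pt = "Nausea",
    sex = c(rep("female", 7), rep("male", 3)),
    age_years = c(44.9, 45, 59, 59.1, NA, NA, NA, NA, NA, NA),
    age_band = age_band(age_years),
    weight_kg = NA_real_, country = "US", occupation = "MD",
    outcomes = "unknown", fda_dt = "20200101", event_dt = "",
    start_dt = "", end_dt = "", report_year = 2020L
  )
  ds <- descriptive_summary(an)
  fem <- dplyr::filter(ds, block == "sex", level == "female")
  expect_equal(fem$n, 7)
  expect_equal(fem$pct, 70.0)
  bands <- dplyr::filter(ds, block == "age_band")
  expect_equal(
    setNames(bands$n, bands$level)[c("under45", "45to59", "over59")],
    c(under45 = 1L, `45to59` = 2L, over59 = 1L)
  )
  wt <- dplyr::filter(ds, block == "weight")
  expect_equal(wt$level, "unknown")
  expect_equal(wt$pct, 100.0)
  # every block's counts sum to the drug total
  totals <- dplyr::filter(ds, block == "total")$n
  for (bl in c("sex", "age_band", "weight", "occupation",
               "serious_outcome")) {
    expect_equal(sum(dplyr::filter(ds, block == bl)$n), totals, info = bl)
  }
})

test_that("annual counts key on report year and conserve dated totals", {
  an <- tibble::tibble(
    primaryid = 1:3, drug = "venlafaxine", pt = "Nausea",
    report_year = c(2004L, 2004L, 2015L)
  )
  out <- annual_counts(an, unit = "record")
  expect_equal(out$year, c(2004L, 2015L))
  expect_equal(out$n, c(2L, 1L))
  expect_equal(nrow(annual_counts(an[0, ], unit = "record")), 0)
})
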