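# Shared fixtures and independent oracles used across the suite.

# tiny generator configuration for fast tests
small_config <- function(n_cases = 2000, seed = 42, ...) {
  faers_config(n_cases = n_cases, seed = seed, ...)
}

# a database pair table with one injected target signal
screen_fixture <- function(seed = 121, rr = 5, n_cases = 15000) {
  cfg <- small_config(
    n_cases = n_cases, seed = seed,
    signals = tibble::tibble(
      drug = "duloxetine", pt = "Sexual dysfunction", rr = rr
    )
  )
  ds <- generate_faers(cfg)
  clean <- dedup_faers(ds$tables)
  build_pair_table(clean, default_synonym_map())
}

# a minimal analytic-like table for TTO tests
tto_fixture <- function(event, start, drug = "duloxetine",
                        pt = "Erectile dysfunction") {
  tibble::tibble(
    primaryid = seq_along(event), drug = drug, pt = pt,
    event_dt = event, start_dt = start
  )
}

# independent nested-loop contingency recount (record unit)
brute_contingency <- function(pairs, drug, pt) {
  a <- b <- cc <- dd <- 0L
  for (i in seq_len(nrow(pairs))) {
    di <- pairs$drug[i] == drug
    ei <- pairs$pt[i] == pt
    if (di && ei) a <- a + 1L
    else if (di) b <- b + 1L
    else if (ei) cc <- cc + 1L
    else dd <- dd + 1L
  }
  c(a = a, b = b, c = cc, d = dd)
}

# independent log-rank statistic from first principles: at each distinct
# event time sum (O1 - E1) with hypergeometric variance
logrank_stat_oracle <- function(x, y) {
  times <- sort(unique(c(x, y)))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n1 <- sum(x >= t)
    n2 <- sum(y >= t)
    d1 <- sum(x == t)
    d2 <- sum(y == t)
    n <- n1 + n2
    d <- d1 + d2
    if (n < 2 || d == 0) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# hand step-up Benjamini-Hochberg (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
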