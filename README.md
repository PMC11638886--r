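# faersignal

Pharmacovigilance signal detection for spontaneous adverse-event
reporting data, built tidyverse-style: every stage takes a data frame
and returns a tibble, so the whole pipeline composes with the pipe.

Spontaneous-reporting databases such as the FDA Adverse Event Reporting
System (FAERS) collect millions of voluntary drug adverse-event reports.
Because there is no denominator of drug users, safety questions are
asked *disproportionally*: is event *e* reported with drug *d* more
often than the database as a whole would predict? `faersignal`
implements that workflow end to end for analysts and
pharmacoepidemiologists:

* **Ingest** of `'$'`-delimited FAERS quarterly ASCII tables (DEMO,
  DRUG, REAC, THER, OUTC, INDI), including legacy ISR-era schemas, with
  malformed rows counted rather than silently dropped.
* **Deduplication** by the FDA rule: per CASEID keep the latest FDA
  receipt date, ties broken by the larger PRIMARYID.
* **Primary-suspect restriction** of drug mentions through a
  user-supplied synonym map (brand and generic names → analysis name).
* **Cohort description**: sex, age bands (&lt; 45, 45–59, &gt; 59),
  weight bands, reporter occupation, serious outcomes, top reporting
  countries, annual report counts.
* **Disproportionality** on the 2×2 table (a, b; c, d) with N = a+b+c+d
  and E = (a+b)(a+c)/N:
  * ROR = ad/bc with Wald 95% CI;
  * PRR = [a/(a+b)]/[c/(c+d)] with Wald CI and uncorrected Pearson χ²;
  * BCPNN information component IC = log₂((a+½)/(E+½)) with IC025 the
    exact 2.5th percentile of the Gamma(a+½, E+½) posterior;
  * MGPS empirical-Bayes geometric mean under DuMouchel's two-gamma
    mixture prior fitted on the whole database, with EBGM05 the 5th
    posterior percentile.
  * Signal rule: n ≥ 3 reports and ROR lower bound > 1; four-algorithm
    concordance (PRR ≥ 2 ∧ χ² ≥ 4 ∧ n ≥ 3, IC025 > 0, EBGM05 ≥ 2).
* **SOC screening**: per-term χ²/Fisher p-values with
  Benjamini–Hochberg adjustment across the organ class, volcano tables,
  IME flagging, and configurable exclusion lists.
* **Time-to-onset**: day-precision EVENT_DT − START_DT with per-reason
  exclusion tallies, median/IQR by the averaging quartile convention,
  two-parameter Weibull MLE with Wald CIs on log-parameters and
  early/random/wear-out failure typing, Kaplan–Meier cumulative
  incidence, and the log-rank test.
* A **seeded synthetic-report generator** (`generate_faers()`) with a
  ground-truth ledger — injected relative risks, Weibull onset models,
  duplicate maps — so every stage is testable without the
  multi-gigabyte FAERS download.

## Worked example

```r
library(faersignal)
library(dplyr)

ds    <- generate_faers(faers_config(n_cases = 20000, seed = 101))
clean <- dedup_faers(ds$tables)
pairs <- build_pair_table(clean, default_synonym_map())

contingency_tables(pairs, drugs = "duloxetine",
                   pts = "Sexual dysfunction") %>%
  disproportionality_stats()
#>    n expected   ror ror_lo95 ror_hi95   prr    chi2    ic ic025
#> 1 99   26.997 4.361    3.498    5.436 4.218 203.796 1.855 1.557
```

99 duloxetine reports of sexual dysfunction against 27 expected under
independence: the reporting odds ratio is 4.36 (95% CI 3.50–5.44), the
information component 1.86 with a lower credible bound of 1.56 — a
signal under every rule (the default configuration injects this pair at
relative risk 5.2, so this is the machinery recovering known truth).

Time-to-onset for venlafaxine erectile dysfunction from the same run:

```r
an  <- build_analytic(clean, default_synonym_map())
smp <- compute_tto(an, "venlafaxine", "Erectile dysfunction")
tto_summary(smp)
#>       n median    q1    q3   min   max
#> 1    34    148  39.5  970.     1  5240
fit_weibull(smp)
#> <weibull_fit>
#>   scale 409.1 (95% CI 204.9-817.1)
#>   shape 0.5128 (95% CI 0.3953-0.6653)  ->  early
#>   n = 34, logLik = -242.94
```

The shape estimate 0.51 with CI entirely below 1 classifies the onset
kinetics as early failure — risk concentrated after treatment start and
declining (the generator's true onset model for this pair is
Weibull(scale 500.55, shape 0.49)).

The one-call version — generation, dedup, screening with all four
algorithms, subgroups, TTO, and delimited-text outputs:

```r
res <- run_faers_pipeline(pipeline_config(
  generator = default_faers_config(), outdir = "out", seed = 7
))
res$screens[["duloxetine.all.all"]]$signals
plot_volcano(res$screens[["duloxetine.all.all"]])
plot_km(res$tto$curves)
```

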