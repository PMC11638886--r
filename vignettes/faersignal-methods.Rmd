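---
title: "Methods: disproportionality and time-to-onset signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`faersignal` implements the standard pharmacovigilance workflow for
spontaneous-reporting databases of the FAERS family: case deduplication,
primary-suspect restriction, drug–event contingency construction,
disproportionality statistics with interval estimates, FDR-screened
volcano output per system organ class, and time-to-onset analysis. This
vignette documents the models, the defaults, and the numerical choices,
and states what the synthetic validation does and does not demonstrate.

## The disproportionality model

For a drug–event pair the database is cross-classified into the 2×2
table

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

with `N = a+b+c+d` and expected count under independence
`E = (a+b)(a+c)/N`. Four statistics are computed per pair:

* **ROR** `= ad/bc`, 95% Wald interval
  `exp(ln ROR ± z·sqrt(1/a+1/b+1/c+1/d))`.
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, Wald interval
  `exp(ln PRR ± z·sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, accompanied by
  the Pearson χ² on the 2×2 without continuity correction (Yates
  available by flag; the common `PRR ≥ 2 ∧ χ² ≥ 4 ∧ n ≥ 3` rule is
  defined on the uncorrected statistic).
* **BCPNN information component**: the relative reporting rate λ has
  posterior `Gamma(a + 0.5, E + 0.5)`; `IC = log2((a+0.5)/(E+0.5))` and
  `IC025` is the base-2 log of the exact 2.5th posterior percentile
  (`qgamma`), not a normal approximation.
* **MGPS/EBGM**: λ has the DuMouchel two-component gamma mixture prior
  `p·Gamma(α₁, β₁) + (1−p)·Gamma(α₂, β₂)`. The five hyperparameters are
  estimated by maximizing the marginal likelihood, a mixture of
  negative binomials `NB(a; α_j, β_j/(β_j+E))`, over all database
  (a, E) pairs. The posterior is again a gamma mixture with components
  `Gamma(α_j + a, β_j + E)` and weights proportional to prior weight ×
  marginal likelihood; `EBGM = exp(E[ln λ | a])` via the digamma closed
  form, and `EBGM05` is the 5th percentile of the posterior mixture,
  root-found on its CDF to `1e-10`.

Zero cells leave ROR/PRR undefined (`NA`) rather than inflated; a
Haldane 0.5 correction is available by flag but is off by default
because pairs reaching the reporting threshold (`n ≥ 3`) always have
`a > 0`, and manufacturing finite estimates for `c = 0` pairs creates
artificial signals.

**Signal rule.** A pair is a signal when it has at least 3 reports and
the ROR lower 95% bound exceeds 1. Four-algorithm concordance uses the
standard thresholds `PRR ≥ 2 ∧ χ² ≥ 4 ∧ n ≥ 3`, `IC025 > 0`,
`EBGM05 ≥ 2`; all are configurable through `signal_criteria()`.

**Screening.** `screen_soc()` evaluates every preferred term of one
system organ class for one drug; the per-pair p-value is the Pearson χ²
when all four expected cells are ≥ 5 and the two-sided Fisher exact
test otherwise, and the Benjamini–Hochberg adjustment is applied across
the SOC's terms for that drug (the volcano's multiplicity family).
Exclusion terms (e.g. breast-related terms when the question is
reproductive toxicity in the narrow sense) stay in the volcano table
but are removed from the signal table.

## Counting conventions and subgroups

The counting unit is exposed as a parameter because AE totals in
spontaneous-reporting summaries are genuinely ambiguous between unique
cases and case–reaction records. The default is the **reaction record**
(each case–PT pair counts once): summing `a` over a drug's PTs then
equals the drug's reaction-record total, which is the convention that
makes the margins self-consistent. `"case"` mode counts unique reports
instead; both are tested.

Subgroups are sex (female, male) and age bands `< 45`, `45–59` (both
ends inclusive), `> 59`; records with unknown sex or age are excluded
from the respective stratified analyses but retained overall. Subgroup
contingency tables restrict **both** margins to the stratum (the
comparator is the stratum's database, not the full database) — the
stricter, self-consistent reading of subgroup disproportionality.

The comparator population for `c` and `d` is the full deduplicated
database of all other drugs, the standard full-database design. The
MGPS prior is likewise fitted on the full database's observed
(a, E) pairs (zero-count drug–event combinations are not enumerated;
with the dense synthetic databases used here the observed pairs carry
essentially all the likelihood information, and enumeration of the
all-drugs × all-terms cross product does not scale to real databases).

## Deduplication and ingest

FAERS re-submits versions of a case; per CASEID the survivor is the
record with the latest FDA receipt date, ties broken by the larger
PRIMARYID. Records with missing FDA dates are treated as the oldest
possible so any dated version supersedes them (the rule presumes a
date; keeping the dated record is the conservative choice). The
operation is idempotent and order-independent, and child-table rows of
superseded versions are dropped.

The ASCII reader accepts the `'$'`-delimited quarterly dialect, maps
legacy ISR-era column names (`ISR` → `primaryid`, `CASE` → `caseid`)
to one canonical schema, rejects rows with the wrong field count
(counted and reported, never silently dropped), and errors on missing
mandatory tables or unrecognizable schemas. Drug-name matching for the
primary-suspect filter is deterministic: case-folding, punctuation and
dosage/formulation-token stripping, then exact lookup in the
user-supplied synonym map. No fuzzy matching — auditable behavior is
worth more than recall here, and the synonym map externalizes the
mapping policy.

Ages are converted to years (`YR`×1, `DEC`×10, `MON`÷12, `WK`÷52.1775,
`DY`÷365.25, `HR`÷8766) with results outside (0, 150) set unknown;
weights to kg (`LBS`×0.453592, `GMS`÷1000) with a 700 kg plausibility
bound. Dates are parsed as `YYYY[MM[DD]]` with precision tracking;
impossible dates are a value (`invalid`), never an exception.

## Time-to-onset

Onset is `EVENT_DT − START_DT` in whole days, using the earliest
day-precision therapy episode of the primary-suspect mention. Records
are excluded — with a per-reason tally so that retained + excluded
equals input — when either date is missing, partial (month/year
precision), invalid, or when the event precedes the start. Same-day
onsets map to day 1 by default (onset tables conventionally report a
1-day minimum, and same-day onsets are clinically real); `"exclude"`
is available.

Summaries use the averaging quartile convention: the quartile sits at
position `(n+1)p`, fractional positions average the two adjacent order
statistics. This is what produces half-integer quartiles (e.g. 20.5)
on integer day data; type-6 interpolation is available by flag.

The Weibull fit maximizes the two-parameter likelihood in
`(log α, log β)` via BFGS from a deterministic moment-style start
(`β₀ = 1.2/sd(log t)`, clamped to [0.05, 50]; `α₀` the profile
maximizer given `β₀`). Wald 95% intervals come from the observed
information on the log-parameters and are exponentiated, which
respects positivity and gives asymmetric intervals on the natural
scale. With `shape_fixed` the scale has the closed form
`(mean(t^β))^(1/β)` — the sample mean for `β = 1`. Failure typing from
the shape CI: entirely below 1 → early failure (decreasing hazard);
containing 1 → random; entirely above 1 → wear-out. Degenerate samples
(all values equal) are an error.

All onset observations are events (reports without a usable onset are
excluded upstream), so Kaplan–Meier cumulative incidence reduces to
the empirical CDF; it is nevertheless computed through
`survival::survfit` for fidelity to the survival-analysis
presentation, and the log-rank comparison uses `survival::survdiff`
with the χ²₁ reference.

## The synthetic-data generator

`generate_faers()` draws a multi-table FAERS-like database with known
ground truth. Per case: one primary-suspect drug from the configured
marginal distribution; a Poisson(1.5)+1 number of distinct reaction
terms sampled without replacement with weights
`baseline(pt) × RR(drug, pt)` — in the rare-event limit the expected
cross-product ratio of the realized 2×2 table equals the configured
RR, which is what makes recovery testable; onset days as the ceiling
of a Weibull draw (minimum 1 day) for modelled pairs and exponential
(mean 90 days) otherwise; demographics with configurable per-field
missingness; dates truncated to month or year precision at a
configurable rate; non-primary-suspect mentions added as noise purely
to exercise role filtering; and superseded duplicate versions that are
always *older* (strictly smaller FDA date, or equal date with smaller
PRIMARYID), so dedup ground truth is exact. Identical configuration
and seed reproduce byte-identical output.

The default configuration is the package's study world, chosen once:
two target SNRIs (duloxetine ~4.5% and venlafaxine ~4% of reports)
against comparator drugs and a background pool; thirty preferred terms
across five organ classes with rare reproductive terms and common
general terms; injected reproductive-toxicity signals at relative
risks between 1.3 and 10.7, the magnitude range reported for these
drugs; Weibull onset models with scale/shape 110/0.65 and 500.55/0.49
(sub-unity shapes, early-failure kinetics); an 8% duplicate rate, 5%
partial-date rate, and missingness near observed FAERS levels (age
38%, weight 72%, event date 35%, sex 8%); reporting window 2004–2023.

**What passing tests show — and don't.** The generator samples events
independently given the drug with tilted weights. It does not model
stimulated reporting, masking/competition between drugs, duplicate
reports with *conflicting* content, reporting-delay drift, or coding
noise in preferred terms. Tests on this world validate the
*arithmetic and inferential machinery* (counts, estimates, intervals,
error rates, recovery of injected truth) — they do not validate
robustness to the reporting biases of real spontaneous data, which no
synthetic null can confer.

## Numerical choices

* MGPS optimization: Nelder–Mead (2000 iterations) then BFGS polish,
  from a fixed multi-start grid including the classic
  `(0.2, 0.1, 2, 4, 1/3)`; best incumbent wins; components are
  relabelled so component 1 has the larger prior mean (mixtures are
  label-symmetric). Convergence status and log-likelihood are
  reported.
* `EBGM05` root-finding brackets the mixture quantile by the two
  component quantiles (the mixture CDF is a convex combination, so the
  5% point must lie between them).
* Percentages print half-up at one decimal; blocks always include an
  `unknown` level so counts sum to the drug total. Serious outcomes
  count each report once by its most severe code
  (DE > LT > HO > DS > CA > RI > OT).
* Ties in dedup cannot remain after the PRIMARYID tie-break because
  PRIMARYIDs are unique.

## Validation scales

The shipped validation exercises the pipeline at: 10⁴ randomized
tables against closed-form oracles; 10⁶-draw Monte-Carlo posterior
quantiles on a 20-point (a, E) grid; MGPS recovery from 5×10⁴
simulated pairs; null calibration on ten 5×10⁴-case no-signal
databases; twenty seeded end-to-end runs with an injected RR = 5 pair;
10³ randomized duplicate patterns; Weibull recovery at n = 2000 and
coverage over 500 replicates at n = 100. These sizes were chosen so
Monte-Carlo error is comfortably below the tolerances being asserted.

## Known limitations

* Real FAERS ingestion is schema-mapped for the ASCII dialect only; XML
  quarters are out of scope, as is MedDRA coding of verbatim text.
* The MedDRA PT→SOC hierarchy and the EMA important-medical-event list
  are licensed resources; the package consumes them as user-supplied
  term lists and ships only small illustrative subsets for the
  synthetic world.
* Disproportionality quantifies reporting association, not risk; no
  denominator of drug users exists in spontaneous data, and none of
  the statistics here should be read as incidence.
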