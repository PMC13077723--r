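---
title: "Methods: disproportionality signal detection on spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem and the data model

Spontaneous-reporting systems collect case reports of suspected adverse
drug reactions. A report carries demographics, one or more drugs each with
a role code (primary suspect `PS`, secondary suspect `SS`, concomitant
`C`, interacting `I`), one or more reaction terms coded as MedDRA
Preferred Terms (PTs), outcome codes, a reporter occupation, and therapy
dates. Because the same case may be re-submitted in updated versions, a
case is identified by `caseid` and a version counter; only the latest
version should be counted. There is no denominator of exposed patients,
so absolute incidence cannot be estimated; instead, *disproportionality
analysis* asks whether a (drug, event) pair is reported more often than
expected from the rest of the database.

The unit of counting throughout the package is the **report** (the
deduplicated case): for an event E and a target drug, `a` counts cases in
which the target drug holds the `PS` role and E is present, `b` the
remaining target-PS cases, `c` all other cases with E, and `d` the rest.
Consequently `a + b` (the number of target-PS cases) and
`n = a + b + c + d` are constant across events, and a case contributes at
most once to each cell no matter how many times a PT repeats within it.
The comparator is all other cases in the ingested corpus, not a
restricted drug class. Exposure is defined by the `PS` role alone,
mirroring standard practice of focusing inclusion on reports where the
drug of interest is the primary suspect.

## The four statistics

All four estimators act on the same 2×2 table.

**ROR.** `(a·d)/(b·c)` with the log-scale Wald interval
`exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d))`. Undefined when any cell is
zero; the package returns `NA` rather than silently correcting, because a
zero-`a` pair can never pass the `a ≥ 3` gate anyway and continuity
corrections distort the interval. A Haldane–Anscombe +0.5 correction is
available behind an explicit flag.

**PRR and χ².** `PRR = a(c+d)/(c(a+b))`. No single interval convention is
universal for PRR; the package uses the standard log-Wald form with
standard error `√(1/a − 1/(a+b) + 1/c − 1/(c+d))`. The chi-square is the
Yates continuity-corrected statistic
`n(|ad−bc| − n/2)² / ((a+b)(a+c)(c+d)(b+d))` with the correction term
floored at zero before squaring — the standard convention when
`|ad−bc| < n/2`, and the one a library implementation
(`chisq.test(correct = TRUE)`) uses, which the tests exploit as an
independent oracle.

**BCPNN information component.** The closed-form Bayesian estimate of
`log₂` observed/expected. With `C = n`, `Cx = a+b`, `Cy = a+c`, `Cxy = a`
and hyperparameters `α₁ = β₁ = 1`, `α = β = 2`, `γ₁₁ = 1`, the prior
coupling parameter is derived as
`γ = γ₁₁(C+α)(C+β)/((Cx+α₁)(Cy+β₁))`, which centres the prior so that an
empty table gives exactly `E(IC) = 0`. `E(IC)`, `V(IC)` and
`IC − 2SD = E(IC) − 2√V(IC)` follow the conventional closed forms
(implemented term by term; the test suite checks them against an
independent log-space transcription to 1e−12). The lower bound reported
in the results column `ic025` is this `−2SD` bound, not a posterior
2.5th-percentile quantile; the two differ slightly for small counts, and
the `−2SD` form is the one defined alongside the criteria used here.

**MGPS EBGM.** The gamma-Poisson shrinker operates on observed counts
`a_i` and expected counts `E_i = (a_i+b_i)(a_i+c_i)/n_i` over the whole
corpus of pairs. The relative reporting ratio λ has prior
`P·Gamma(α₁, β₁) + (1−P)·Gamma(α₂, β₂)` (shape/rate); with
`a | λ ~ Poisson(λE)` the marginal is a mixture of negative binomials and
the posterior is again a two-component gamma mixture. `EBGM` is the
posterior geometric mean `exp(E[ln λ | a])`, computed from digamma
functions; `EBGM05` is the 5th percentile of the posterior mixture, found
by root-finding on the mixture CDF (absolute tolerance 1e−10, bracketed
by the component quantiles). The exact forms for this estimator are a
package design decision following the standard two-component model; no
single printed reference convention was being matched. Hyperparameters
default to fitting by maximum marginal likelihood: a deterministic
quasi-Newton (`nlminb` on log/logit-transformed parameters) from the
conventional start `(0.2, 0.1, 2, 4, 1/3)`. An all-zero corpus has no
interior optimum and is rejected with advice to supply a fixed prior.

**Signal criteria.** All four algorithms share the `a ≥ 3` gate. ROR
signals when additionally `ROR ≥ 2` and the lower CI bound exceeds 1; PRR
when `PRR ≥ 2` and `χ² ≥ 4`; BCPNN when `IC − 2SD > 0`; EBGM when
`EBGM05 > 2`. Ratio thresholds are inclusive and bound thresholds strict,
matching how the criteria are conventionally printed; the EBGM05 cut has
no universal convention and 2 (the customary value) is overridable.
Undefined statistics never signal. Both the conjunction (`all_of`) and
disjunction (`any_of`) of the four flags are exported; neither is claimed
as *the* combined rule, since multi-algorithm "cross-validation" is not
operationalized consistently in the literature.

## The synthetic reporting system

The generator exists so that every downstream stage can be tested against
known ground truth. Per case:

1. each drug enters independently with its prevalence (default 25 drugs
   at 0.05); one included drug, chosen uniformly, carries the `PS` role;
2. each event occurs as an independent Bernoulli draw at its base rate
   (default 160 events at 0.01, i.e. 1.6 expected reaction terms per
   case, a realistic multiplicity for spontaneous reports); for an
   injected pair the probability becomes `min(1, RR × base rate)` when the
   case's PS drug matches — injection through the `PS` role only, matching
   the inclusion rule used at analysis time;
3. a case that draws no event receives a filler term ("Drug
   ineffective") outside the modeled vocabulary.

The independent-Bernoulli design (rather than drawing a per-case PT count
first) is deliberate: it keeps every modeled event's marginal exact, so
an injected pair has the closed-form generative odds ratio
`odds(min(1, RR·p)) / odds(p)` — e.g. RR = 10 at base rate 0.01 gives
exactly 11 — which the tests compare against the sampled ROR. The filler
term guarantees each case at least one reaction without perturbing any
modeled contingency cell.

Demographic marginals (sex, age band, weight band, reporter occupation,
country, route, outcome), field-level missingness rates and the
time-to-onset bucket distribution default to the published profile of
ketorolac (Toradol) primary-suspect reports shipped in
`reference_demographics()` — e.g. 68% female, 27% missing age, 73% onset
within 7 days — so a simulated corpus is demographically realistic for
this drug class. Duplicates re-emit a chosen fraction of cases as
`caseversion` 2 with a receipt date 0–90 days later and **nothing else
changed**, which makes deduplication exactly testable: the retained set
must equal the pre-duplication ledger.

What the generator does *not* emulate: reporting heterogeneity over time,
masking/competition bias between signals, correlated events within a
case, free-text drug names, and multi-source duplicates that differ in
content. Passing recovery tests on this generator therefore demonstrates
correctness of the counting and estimation machinery, not robustness to
those real-data pathologies.

## Ingestion conventions

* **Dialect**: `$`-delimited, one header line, empty field = missing.
  Malformed rows (wrong field count) are counted and dropped with a
  warning up to a tolerance (default 1% per file); beyond it, parsing
  fails with row numbers. They are never silently ignored.
* **Dedup key**: keep the lexicographic maximum of `(caseversion,
  fda_dt, primaryid)` per `caseid`, output sorted by `caseid`. Public
  sources rarely state their exact reconciliation rule; this key matches
  common FAERS practice, is deterministic, and makes the operation
  idempotent.
* **Ages** normalize to years via unit codes `YR/DEC/MON/WK/DY/HR`
  (months = 1/12 year; weeks and days via 365.25-day years); unknown
  codes give missing.
* **Drug matching** is exact on normalized names (uppercase, trimmed,
  inner whitespace collapsed) against a synonym set — reproducibility is
  preferred over recall; no fuzzy matching.
* **Time to onset** is event date minus the PS drug's therapy start in
  whole days. Negative intervals are implausible and become missing (not
  zero), so they cannot inflate the `<7 days` bucket; the count of such
  rows is retained.
* **Multi-axial PTs** resolve to their unique primary SOC by default
  (`policy = "primary_only"`), under which SOC labels partition each
  case's PT multiset; `policy = "all"` is available. Published SOC-level
  report tables behave like a partition of reports, which motivates the
  default.

## Descriptive tables

Count-(percent) tables use the *displayed-category* denominator: the sum
of the shown category counts, with missing values excluded unless an
explicit `Unknown` row is displayed (the default for age, weight,
reporter and time-to-onset). Percentages are rounded **half-up** at two
decimals — this convention reproduces every checkable reference cell
exactly (e.g. 144/197 = 73.096 → 73.10), where banker's rounding would
not in general. Band boundaries are lower-inclusive half-open intervals
(`[18, 45)`, `[45, 65)`, …); printed band labels are typically ambiguous
at the boundary and the half-open convention is adopted and documented.
Medians and quartiles use type-7 linear interpolation (the R default).

## Numerical choices and problem sizes

Cell counts are coerced to doubles before forming products (margin
products overflow 32-bit integers around n ≈ 10⁵). The MGPS marginal
likelihood is evaluated with log-sum-exp; posterior log-means use
digamma rather than quadrature. The test suite validates EBGM against an
independent quadrature oracle (log-scale integration of the posterior
density) at 1e−6, BCPNN against direct evaluation at 1e−12, and χ²
against the library statistic at 1e−9 relative.

The simulation-based checks use corpora the package generates in seconds:
single runs of 2×10⁴–2×10⁵ reports for calibration and oracle-equality
checks, and twenty seeded replicates of 10⁵ reports for the end-to-end
recovery study, in which an injected RR = 10 pair must be flagged by all
four algorithms and ranked first by EBGM in at least 18 of 20 replicates
while the `any_of` false-positive rate across null pairs stays below 15%.
These sizes give stable Monte-Carlo behaviour for the rates being
checked while keeping the full suite fast on a single CPU.

## Known limitations

* Crude (unstratified) disproportionality only — no age/sex strata, no
  stratified expected counts for MGPS, no multiple-testing adjustment.
* The legacy (pre-2012Q4) quarterly field layout is not parsed.
* Drug identification relies entirely on the synonym list.
* Signals are statistical reporting associations, not causal claims, and
  inherit every bias of spontaneous reporting (underreporting, media
  effects, confounding by indication).
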