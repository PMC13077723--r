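# faersignal

Disproportionality signal detection for spontaneous adverse-event reports.

Spontaneous-reporting databases such as the FDA Adverse Event Reporting
System (FAERS) collect case reports of suspected drug adverse events, but
carry no denominator of exposed patients. Pharmacovigilance therefore
screens for *disproportionality*: drug–event pairs reported more often than
the background of all other reports would predict. `faersignal` implements
that workflow end to end for analysts and methodologists:

* a **synthetic report generator** that emits FAERS-shaped corpora with
  injected drug–event associations of known relative risk, duplicate case
  versions and field-level missingness, so every pipeline stage can be
  validated against ground truth;
* **ingestion** of the quarterly `$`-delimited ASCII dialect
  (DEMO/DRUG/REAC/OUTC/RPSR/THER), case **deduplication** (latest
  `caseversion`, tie-broken by receipt date then `primaryid`) and
  **primary-suspect filtering** on a drug synonym list;
* **PT→SOC aggregation** via a two-column MedDRA-style surrogate table;
* per-event **2×2 contingency tables** at report level;
* the four standard **disproportionality statistics** with their signal
  criteria;
* **Table-style descriptive summaries**: count-(percent) tables with
  explicit denominators, banded age / weight / time-to-onset, and
  median (Q1, Q3) rows.

## The statistics

For a drug–event pair, with `a` = reports carrying both the target drug
(as primary suspect) and the event, `b` = target-drug reports without the
event, `c` = other reports with the event, `d` = the rest, and
`n = a+b+c+d`:

* **ROR** = `(a·d)/(b·c)`, 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
  signal when `a ≥ 3`, `ROR ≥ 2` and the lower bound exceeds 1.
* **PRR** = `a(c+d)/(c(a+b))` with the Yates-corrected
  `χ² = n(|ad−bc|−n/2)²/((a+b)(a+c)(c+d)(b+d))`; signal when `a ≥ 3`,
  `PRR ≥ 2` and `χ² ≥ 4`.
* **BCPNN information component**: closed-form Bayesian shrinkage of
  `log₂` observed/expected with priors `α₁=β₁=1`, `α=β=2`, `γ₁₁=1`;
  signal when `a ≥ 3` and `IC − 2SD > 0`.
* **MGPS EBGM**: empirical-Bayes gamma-Poisson shrinkage. The relative
  reporting ratio λ has a two-component gamma mixture prior fitted to the
  whole corpus by maximum marginal likelihood; `EBGM = 2^E[log₂ λ | a]`
  is the posterior geometric mean and `EBGM05` its 5th percentile; signal
  when `a ≥ 3` and `EBGM05 > 2`.

## Worked example

Simulate 50,000 reports with one injected association (drug 1 → event 1,
relative risk 10), 10% duplicate case versions, and run the full pipeline:

```r
library(faersignal)

cfg <- generator_config(
  n_reports = 50000,
  injected_signals = list(signal_spec(drug_id = 1, event_id = 1,
                                      relative_risk = 10)),
  duplicate_fraction = 0.1,
  seed = 42)
rs  <- generate_reports(cfg)
ana <- run_signal_analysis(rs, "DRUG_01", level = "pt")
ana
#> <faers_analysis>
#>   raw demo rows: 55000 | deduplicated: 50000 | primary-suspect: 2102
#>   events analyzed: 161 | any-algorithm signals: 7

head(ana$results[, c("event", "case_reports", "ror", "prr", "chisq",
                     "ic", "ic025", "ebgm", "ebgm05")], 3)
#>       event case_reports   ror  prr  chisq    ic ic025 ebgm ebgm05
#> 1 EVENT_001          202 10.35 9.45 1087.8 2.758 2.520 6.97  6.966
#> 2 EVENT_031           36  1.84 1.82   11.7 0.784 0.289 1.00  0.987
#> 3 EVENT_011           35  1.82 1.80   11.0 0.771 0.268 1.00  0.987
```

The injected pair is ranked first by EBGM. Its sample ROR (10.35) sits
near the generative odds ratio of 11 implied by the configuration
(event probability 0.10 under exposure vs 0.01 otherwise), and the
Bayesian estimates (IC 2.76, EBGM 6.97) show the expected shrinkage
toward the null relative to the raw ratios. Descriptive summaries use
count-(percent) layout over an explicit denominator:

```r
summarize_categorical(ana$ps_cases, "tto_band")
#>   variable category count percent
#> 1 tto_band       <7  1499   71.31
#> 2 tto_band     7-28   129    6.14
#> 3 tto_band    28-60    62    2.95
#> 4 tto_band     >=60    51    2.43
#> 5 tto_band  Unknown   361   17.17
```

The generator's demographic defaults are calibrated to the published
profile of ketorolac (Toradol) reports (see
`reference_demographics()`), which is why roughly 70% of onsets fall
within 7 days of therapy start.

A thin command-line wrapper over the same functions is provided at
`inst/scripts/faersignal-cli.R` (`simulate` and `analyze` subcommands).

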