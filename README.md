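# reliefwatch

Analysis of electronically monitored beta-agonist use and medical-review
seeking in high-risk asthma.

Electronic inhaler monitors record the date and time, to the second, of
every actuation. In patients at risk of severe asthma exacerbations this
stream answers two questions that self-report cannot: how often patients
exceed the reliever-use thresholds at which their asthma action plan tells
them to seek medical review, and whether they actually obtain that review.
`reliefwatch` implements the full analysis pipeline for a two-arm trial of
a single maintenance-and-reliever budesonide/formoterol regimen (SMART)
versus fixed-dose budesonide/formoterol with salbutamol reliever
(Standard):

* **Day classification.** Each monitored calendar day is flagged as high,
  marked or extreme beta-agonist use. For SMART these are strict
  thresholds on total budesonide/formoterol actuations (>12, >16, >20,
  i.e. >8/>12/>16 as-needed actuations beyond the four maintenance doses);
  for Standard they are >16, >24, >32 salbutamol actuations per day. Flags
  nest: every extreme day is also a marked and a high day.
* **Review linkage.** An overuse day counts as *without medical review*
  unless a review (primary care, after-hours or hospital) falls on the
  index day or the next day (48-h rule), or the day lies in a stand-down
  window: the index day, the review day and the 7 days after a review,
  restarted by any further review inside it.
* **Severe exacerbations.** Systemic corticosteroid courses of >=3 days
  anchor exacerbation episodes (Day 0 = first day of therapy); courses
  separated by <7 days merge. Medication use is profiled over Day -14 to
  +14, excluding repeat episodes whose Day 0 lies within 28 days of the
  previous included one, with a >=100-actuations-in-3-h dose-dumping
  screen.
* **Statistics.** Between-arm contrasts as contingency-table relative
  risks with log-scale Wald intervals, `RR = (a/n_a)/(b/n_b)`,
  `SE = sqrt(1/a - 1/n_a + 1/b - 1/n_b)`, and as rate ratios from Poisson
  regression with a `log(exposure days)` offset and quasi-Poisson
  over-dispersion scaling (Pearson chi-square / df).
* **Synthetic cohorts.** A generator (`cohort_config()`,
  `generate_cohort()`) simulates the four input tables — participants,
  actuations, reviews, corticosteroid courses — with the trial's
  structure (151/152 participants, 168 days, clustered overuse episodes,
  peri-exacerbation use ramps, exacerbation rates 35/151 vs 66/152), so
  every stage runs and can be validated at desk scale.

## Worked example

The published contingency table for "at least one episode of high use"
(84/151 SMART vs 68/152 Standard) reproduces directly:

```r
library(reliefwatch)
relative_risk(84, 151, 68, 152)
#> Relative risk (Wald) 1.24 (95% CI 0.99-1.56), p = 0.0599
```

A full synthetic run, from raw event tables to report tables:

```r
cohort <- generate_cohort(cohort_config(n_smart = 60, n_standard = 60,
                                        n_days = 112), seed = 42)
res <- run_pipeline(cohort$actuations, cohort$reviews, cohort$ocs,
                    cohort$participants, out_dir = "report")
res$table2$HIGH[c(1, 5), c("outcome", "smart", "standard")]
#> 1 At least one episode of high use   45 (75%)   38 (63%)
#> 2 Proportion of high use days without medical review within 48 h ...
#>   0.92 (0.17); 1 (0.9375-1); ...     0.98 (0.08); 1 (1-1); ...
dplyr::filter(res$comparisons, outcome == "severe_exacerbations")
#>   severe_exacerbations  QUASIPOISSON_RATE_RATIO  0.833  0.472  1.47 ...
```

The first rows say 75% of the simulated SMART arm and 63% of the Standard
arm had at least one high-use day, and that among those participants a
mean of 92% and 98% of their high-use days passed without medical review
within 48 h — the behavioural signature the pipeline is built to measure.
The last line is the between-arm severe-exacerbation rate ratio with its
dispersion-scaled 95% interval. `run_pipeline()` writes
`table2_{high,marked,extreme}.csv`, `comparisons.csv`, `episodes.csv`,
`window_profiles.csv`, `overuse_review.csv`, `dose_dump_flags.csv` and a
provenance log to `report/`.

A thin command-line wrapper is installed with the package
(`inst/scripts/reliefwatch.R`) with `simulate` and `run` subcommands.

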