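---
title: "Measuring beta-agonist overuse and delayed medical review from inhaler monitor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring beta-agonist overuse and delayed medical review from inhaler monitor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reliefwatch)
```

## The measurement problem

Asthma action plans instruct patients to obtain medical review when their
reliever use crosses a stated daily limit. Mortality surveys implicate both
beta-agonist overuse and delay in seeking review in fatal outcomes, but
self-reported use is unreliable in exactly the patients who overuse.
Electronic inhaler monitors remove the reporting problem: every actuation
is logged to the second. What remains is an *analysis* problem — turning a
raw actuation stream, a list of medical-review attendances and a list of
systemic corticosteroid courses into defensible per-day overuse flags,
review-linkage outcomes, exacerbation episodes and between-arm statistics.
`reliefwatch` implements that pipeline for a two-arm design: single
maintenance-and-reliever budesonide/formoterol (SMART) versus fixed-dose
budesonide/formoterol plus salbutamol reliever (Standard).

## Day classification

Days are calendar days, midnight to midnight, in one study-local time zone
(`tz` argument, default UTC). Review attendances and corticosteroid
courses are recorded as dates, so a calendar-day boundary keeps all three
streams commensurable; the alternative — rolling 24-hour windows anchored
at each actuation — would produce overuse "days" that cannot be linked to
date-based review records without further convention. Days with no events
are explicit zero records because downstream proportions need exposure
days in the denominator.

Thresholds (`threshold_config()`) are strict inequalities at three nested
levels, 1x, 1.5x and 2x the action-plan limit:

| level   | SMART (total bud/form per day) | Standard (salbutamol per day) |
|---------|--------------------------------|-------------------------------|
| high    | >12                            | >16                           |
| marked  | >16                            | >24                           |
| extreme | >20                            | >32                           |

Two conventions deserve comment. First, SMART thresholds apply to the
day's *total* budesonide/formoterol actuations rather than to the excess
over maintenance doses actually taken: the limits are defined as >8/>12/>16
as-needed actuations *beyond four maintenance doses*, and the total-count
form (12/16/20) is the only operationalisation that stays well defined
when maintenance adherence is imperfect. A `smart_mode = "excess"` escape
hatch thresholds `total - maintenance_actuations_per_day` instead; with
the default maintenance load the two modes coincide on day totals. Second,
Standard-arm classification uses salbutamol only. Some Standard-arm
patients demonstrably use their maintenance inhaler as a reliever, so this
undercounts their overuse; it is kept because the two inhalers' thresholds
are not additive and the salbutamol-only rule is the one the action plan
states.

Flags are cumulative (extreme implies marked implies high), so day counts
at the three levels nest, and raising any threshold can only reduce
counts. Both properties are enforced by tests.

## Linking overuse to medical review

For each overuse day (the *index day*) the participant's review record is
searched for an attendance on the index day or the next day — a 48-hour
window, matching the "within 1 to 2 days" instruction of the Standard
action plan and applied identically to both arms so that the outcome is
comparable.

A patient who has just been reviewed should not have subsequent overuse
held against them, so protection extends over a *stand-down* window: the
index day, the review day and the 7 days following the review (7 days
being the conventional separation between distinct severe-exacerbation
episodes). A further review inside an open stand-down restarts the 7-day
clock. Because every review date opens its own window, the restart is
implemented as the union of `[r, r+7]` over all review dates `r`, plus
index days whose linked review falls the next day; chained reviews extend
protection seamlessly. Three boundary decisions are implemented as stated
rules and covered by tests:

* the index day is protected even when its linked review occurs the next
  day;
* any review restarts the window, whether or not that review was itself
  triggered by overuse;
* a review more than one day before an overuse day does not retroactively
  excuse it, except through its own still-open stand-down window.

The per-day outcome is
`counted_as_unreviewed = overuse & !reviewed_within_48h & !in_standdown`.
Per-participant proportions divide unreviewed days by *all* overuse days
at the level (stand-down-protected days stay in the denominator), and are
undefined — excluded from cohort means — for participants with no overuse
day. The set-based ledger is verified against an independent per-day
brute-force scan on 10^4 random fixtures.

## Severe exacerbations and peri-exacerbation windows

A severe exacerbation is anchored by a systemic corticosteroid course of
at least 3 days; Day 0 is the first day of therapy. Courses shorter than
3 days are dropped first; the survivors merge when the gap from the end of
one course to the start of the next is under 7 days (a gap of exactly 7
separates), with overlapping courses merged under a warning.
Hospital-presentation exacerbations enter as corticosteroid course records
prepared upstream; the pipeline does not ingest encounter data separately.

Medication use is extracted at offsets −14 to +14 around Day 0. Offsets
outside the participant's monitoring period are marked unobserved, never
zero-filled. Repeat episodes whose Day 0 falls within 28 days of the
previous *included* episode's Day 0 are excluded from the window analysis
(an interval of exactly 28 days satisfies the minimum) but still count as
exacerbation events; episodes without monitor data can be excluded by id
with reason `no_monitor_data`, and such episodes do not anchor the
28-day rule. Day 0 itself is treated as *post*-exacerbation: the
pre-exacerbation overuse fraction counts offsets −14 to −1 strictly.

Profile summaries are per-offset medians with interquartile ranges over
included episodes. Dose dumping — emptying a canister rather than
inhaling — is flagged when any 3-hour window (anchored at an event,
endpoints inclusive) contains 100 or more actuations of one medication;
overlapping flagged windows coalesce. Flags annotate the record but do
not remove days from the profiles. The sliding-window detector is checked
against an O(n^2) pair scan on random fixtures.

## Statistics

Binary outcomes ("at least one episode of ...") are compared as relative
risks from the 2x2 table with the log-scale Wald interval; this
reproduces the published intervals to two decimals, which is why the Wald
(rather than score or exact) form is used. Day counts and exacerbation
counts are compared as rate ratios from Poisson regression with a
`log(exposure)` offset; over-dispersion is handled by scaling standard
errors with the square root of the Pearson dispersion (quasi-Poisson
convention, matching the era's SAS GENMOD practice), not by a negative
binomial. "Days of treatment exposure" is taken as each participant's
monitored days (`monitor_end - monitor_start + 1`) — the only exposure
measure derivable from the inputs — and is configurable. Either arm
having zero events triggers a continuity correction (0.5 per cell or per
arm total) with an explicit flag. No multiplicity adjustment is applied,
matching the exploratory design.

Numerical conventions: quantiles average at discontinuities
(`type = 2`), so the IQR of counts {2, 4, 6} is 2–6, as trial reports
print them; report cells round half away from zero (2 decimals for
ratios and proportions, integer percentages) while machine outputs
(`comparisons.csv`) keep full precision; the SD of a single observation
is reported as 0 rather than NA so singleton strata still print.

## The synthetic cohort generator

`generate_cohort()` simulates the four input tables with the statistical
structure the analysis assumes, at the trial's scale by default: 151
SMART and 152 Standard participants monitored 168 days. It exists so the
pipeline, its edge cases and its parameter-recovery behaviour can be
exercised without access to monitor data; its defaults were set once,
against the published cohort's shape, and the validation suite treats
them as fixed study conditions.

* **Baseline demand.** As-needed reliever use is near-Poisson around 2
  actuations/day (the cohort's baseline self-reported use). Quiet-day
  counts are deliberately thin-tailed: nine or more reliever actuations
  on an otherwise unremarkable day would itself be an overuse day, and
  overuse is modelled explicitly rather than as distributional accident.
  Maintenance doses are Binomial(4, 0.8) per day (imperfect adherence).
* **Overuse episodes** arrive as multi-day blocks (geometric duration,
  mean 3 days) with a strongly skewed between-participant block count
  (negative binomial; rates 1.2/2.9 per study, sizes 0.8/0.22 for
  SMART/Standard), reproducing the long right tail of observed overuse-day
  counts (medians of 1–2 days but ranges into the hundreds). Each block
  day is assigned high/marked/extreme magnitude and its count forced into
  the corresponding arm-specific band.
* **Review seeking** is an onset hazard: with probability 0.06 the *first
  unprotected day* of an overuse run leads to review at a lag of 0–1
  days. An earlier per-day formulation (every overuse day an independent
  coin) was rejected on analytic grounds: with 3-day blocks and the
  restartable stand-down, each triggered review excuses two to four
  clustered days, capping the achievable cohort mean unreviewed
  proportion near 0.87 regardless of other settings — below the ~0.94
  the review probability is meant to imply. Under the onset-hazard model
  the expected unreviewed proportion per episode is `1 - p` by
  construction, and the probability-1 and probability-0 limits give
  proportions of exactly 0 and 1. Background (non-overuse) reviews occur
  at 0.001/day — unscheduled attendances are rare, and protocol visits
  are not medical-review events.
* **Exacerbations** per participant are Poisson at the arm rates 35/151
  and 66/152 per study (rate ratio 0.534), each anchoring a 3–7 day
  corticosteroid course, with Day 0s at least 35 days apart so courses
  never merge. Around each Day 0, reliever demand follows arm-specific
  ramps: SMART use rises from 5 days before Day 0 and stays high to +5
  before decaying by +10; Standard salbutamol is mildly elevated for two
  weeks, spikes the day before Day 0, and decays by +10.

What the generator does *not* emulate: seasonality, weekday structure,
monitor malfunction or missing days (every in-period day is treated as
observed, matching the pipeline's own assumption), behavioural feedback
from reviews onto subsequent use, within-participant correlation between
overuse propensity and exacerbation risk, and any pharmacokinetics.
Passing tests on synthetic cohorts therefore demonstrate the *algorithms*
— classification, ledger accounting, episode bookkeeping, estimator
behaviour — not fidelity of any particular real-world dataset.

## Validation strategy and problem sizes

The suite validates at three tiers. Worked examples assert the published
contingency-table statistics exactly (to printed precision) from their
printed inputs. Property checks run the ledger against a brute-force
oracle on 10^4 random fixtures (60-day grids, up to 10 reviews) and the
dose-dump detector against an O(n^2) scan on random burst fixtures.
Parameter recovery runs the full pipeline on 200 replicated default-scale
cohorts and requires the mean exacerbation rate-ratio estimate within
0.05 of the configured 0.534, and the cohort mean unreviewed proportion
within [0.90, 0.97]; module-level tests use 40-per-arm, 84-day cohorts,
sizes chosen to exercise every code path in seconds.

## Known limitations

* The raw-data day counts, their per-participant distributions and the
  peri-exacerbation medians of the original trial are reproducible only
  from the original monitor streams; the package reproduces their printed
  *statistics* from printed inputs and their *structure* from synthetic
  cohorts.
* With equal per-participant exposure, the exacerbation rate ratio from
  the printed totals (35/151 vs 66/152) is 0.534; the published 0.54 was
  fitted with per-participant "adjusted days of treatment exposure" not
  recoverable from the publication, so point estimates can differ in the
  second decimal.
* The 48-hour review window is calendar-based (index day or next day): an
  overuse episode at 23:50 followed by review 26 hours later is "within
  window", one at 00:10 followed 47 hours later is not. This mirrors the
  date-based review records.
* Classification of a review's clinical content, action-plan document
  generation, and bronchodilator dose-equivalence conversion beyond the
  fixed thresholds are out of scope.
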