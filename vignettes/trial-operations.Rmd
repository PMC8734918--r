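---
title: "Operational analytics for multisite trials: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational analytics for multisite trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialops)
```

## What this package models

trialops implements the computational layer of a clinical-trial management
workflow for a multisite randomized trial: accrual monitoring and
forecasting, stratified table-driven randomization, a scheduled operational
report suite, and automated data-quality checks with a query lifecycle.
The running example throughout is a three-site pregnancy trial — sites
activate at staggered dates, each is expected to enroll 2–3 participants
per week, participants enroll before 20 weeks gestation, and the study
targets roughly 900–1200 enrollments over four years — but every constant
involved is a configurable parameter, not an assumption baked into the
code.

## Accrual inequality: the Gini index

Uneven enrollment across sites erodes the generalizability a multisite
design is supposed to buy. The package summarizes accrual disparity with
the Gini coefficient over per-site enrollment totals $x_1, \dots, x_n$:

$$G = \frac{\sum_{i=1}^n \sum_{j=1}^n |x_i - x_j|}{2 n^2 \bar{x}},$$

the unweighted mean-absolute-difference form, whose maximum for $n$ sites
is $(n-1)/n$. Two variants circulate in the literature; the other applies
the small-sample factor $n/(n-1)$. We deliberately ship the *uncorrected*
form: for three sites with totals (489, 359, 252) it gives $G = 0.1436$,
the conventional figure for that accrual pattern, whereas the corrected
variant gives 0.215 and would flip the qualitative conclusion. The
classification threshold follows the accrual-inequality literature:
$G < 0.2$ (strictly) reads as *low* inequality, and multisite trials
average around $G = 0.33$. `classify_inequality()` applies the threshold
strictly, so $G = 0.2$ exactly is *not* low.

```{r}
accrual_inequality(c(489, 359, 252))
```

## Completion forecasting: a Poisson–gamma model

The forecast answers the question every steering call asks: *when will we
reach the enrollment target?* We model pooled enrollment as a homogeneous
Poisson process with daily rate $\lambda$ and place a conjugate
Gamma$(a_0, b_0)$ prior on $\lambda$. Observing $n$ enrollments over $t$
exposure days gives the posterior

$$\lambda \mid \text{data} \sim \mathrm{Gamma}(a_0 + n,\; b_0 + t).$$

With $m$ participants still to enroll, the remaining accrual time given
$\lambda$ is a sum of $m$ exponential waiting times, i.e.
$\mathrm{Gamma}(m, \lambda)$. Integrating over the posterior yields the
posterior-predictive completion-time distribution, which
`predict_completion()` samples by Monte Carlo: draw
$\lambda^{(k)} \sim \mathrm{Gamma}(a_0+n, b_0+t)$, then
$T^{(k)} \sim \mathrm{Gamma}(m, \lambda^{(k)})$. The point forecast is the
median draw and the 95% prediction interval the 2.5th/97.5th percentiles —
a *prediction* interval on the realized completion date, not a credible
interval on its expectation, because operational planning cares about the
date that will actually happen.

Numerical choices:

* **Prior** — default $(a_0, b_0) = (0.001, 0.001)$, vague enough that the
  forecast is dominated by observed accrual after the first weeks. Both
  parameters are exposed for sensitivity analysis.
* **Pooling** — the study-level forecast pools all sites into one rate;
  `predict_completion_by_site()` offers per-site forecasts using each
  site's activation date as its exposure start. Whether to condition on
  per-site or pooled rates is genuinely open; pooled is the default
  because the study-level completion date is the quantity steering
  decisions use, and a hierarchical site-effects model is out of scope.
* **Rounding** — forecast dates are rounded to whole days with ties going
  to the *later* day: the data have daily granularity and a later
  completion estimate is the conservative direction for planning.
* **Draws and seed** — at least 1000 draws are required (default 20 000);
  the forecast is deterministic given the seed, and the sampler restores
  the caller's RNG state.
* **Degenerate input** — if the target is already met, the median and both
  interval endpoints collapse to the as-of date.

Calibration is a testable property because the model can be confronted
with data generated from its own assumptions: across 500 simulated
constant-rate trials (rate 0.5/day, forecasting the 60th enrollment after
observing 30), the empirical coverage of the nominal 95% interval lands
within [0.92, 0.98] in the test suite. This checks internal coherence; on
real accrual data with drift or seasonality, coverage is not guaranteed —
see *Limitations*.

## Accrual windows

Weekly accrual tables use three windows: the **current calendar month**
(day 1 of the as-of month through the as-of date), the **past 30 days**
(the closed 29-days-back window), and the **study total**. The two short
windows deliberately overlap; no ordering between them is asserted
anywhere, and each is defined (and tested) as a literal date filter. Sites
with a zero count in a window are omitted from that window's rows,
matching the usual presentation where a site that has not enrolled this
month simply does not appear.

## Randomization

All randomness lives in the pre-generated table. An entry is
`(site_id, stratum_key, sequence_no, arm, schedule_version, assigned_to)`;
at enrollment the participant consumes the lowest
`(schedule_version, sequence_no)` unconsumed entry matching their site and
stratum. This makes assignment fully deterministic given the table —
replaying the enrollment log reproduces every assignment — which is the
property audits need.

* **Stratum keys** are canonical strings: factor names sorted
  lexicographically, joined as `name=level` with `|`. The schema stays
  generic because stratification variables differ per protocol.
* **Adaptive schedules** (e.g. from interim-analysis adaptations) are
  *appended* per site with a strictly increasing `schedule_version`; the
  computation that produces them is external to this package. Appending
  supersedes the site's unconsumed lower-version entries, which are never
  consumed afterwards. Supersession is derived, not stored: on load, any
  unconsumed entry below its site's newest version is superseded, keeping
  the CSV format to the six columns above.
* **Consumption invariant** — consumed entries form a prefix *within each
  schedule version* of a site×stratum cell (a global prefix across
  versions is impossible once a partially consumed schedule is
  superseded).
* The permuted-block generator in the simulator (`generate_block_table()`,
  default block size 4, configurable ratio) exists to produce plausible
  test tables; block randomization is a testing convenience, not a claim
  about any particular trial's design.

## Operational reports

Each report is a `report_document` — named sections of plain data frames —
rendered to Markdown and JSON, both byte-deterministic for a given dataset
and date. Inclusion rules are intentionally simple date filters so that an
independent brute-force filter can (and in the tests does) reproduce every
row set:

* **Resupply**: run-out = last dispense date + days supplied; flag date =
  run-out − `lead_days` (default 14, the two-week rule); a participant
  appears once the flag date arrives, while still actively treated. Only
  the latest dispense defines run-out. Actively treated participants with
  no dispense on file are flagged "never dispensed" rather than silently
  dropped.
* **Delivery watch list**: estimated delivery date within
  `[as_of, as_of + horizon_days]`, default horizon 60 days (a literal
  reading of "the next couple of months", exposed as a knob); participants
  missing an estimated date land in an exceptions section.
* **Adverse events**: onset in `(since, as_of]` *or* still unreviewed;
  serious events first.
* **Sign-off**: completed participants not yet signed off.
* **Cadences** (`reports_due()`): weekly reports on Monday, twice-weekly
  on Monday+Thursday, twice-monthly on the 1st and 15th, and the AE report
  immediately when a serious event arrives. The weekday/day-of-month
  anchors are documented defaults, not claims — only the cadences
  themselves are fixed by convention.
* **Blinding hygiene**: no report prints a treatment-arm label at all (the
  tests assert no cell equals an arm label); arm totals are available
  separately via `arm_balance()` for unblinded summaries.
* The `accrual_report()` treats `as_of` as a snapshot date and ignores
  later enrollment events, so a mid-trial report can be regenerated from
  the final database. Participant status counts are the one exception:
  statuses are stored as current state, not dated transitions, so that
  section always reflects the statuses as recorded in the table.

## Data quality

"Edit, logic and range checks" are interpreted as three concrete
categories: *edit* = format and required-field checks (empty required
fields; placeholder junk like the literal `"NA"`, `"N/A"`, whitespace-only
values; unparseable numerics), *range* = numeric bounds and category
membership, *logic* = named cross-field predicates registered in a rule
table (`default_logic_rules()`), not a free-form expression language —
testability over generality. Absent values are empty strings in the CSV
interchange; the literal string `"NA"` is data entered by a human and is
flagged as a `format_error`.

Each violation opens one query; queries move `open → sent → resolved`
(weekly batch send; resolving an unsent query is an error), and the
dataset lock gate (`check_lock_ready()`) passes only when every query is
resolved. Re-detection does not duplicate unresolved queries; a resolved
query whose violation persists reopens under a new id.

Quality metrics round the deviation rate to 4 decimals and loss to
follow-up to the nearest whole percent (ties upward) with all enrolled
participants as the denominator: 2 deviations among 1100 gives 0.0018,
and 68 losses gives 6%.

## The simulator

`simulate_trial()` generates the full nine-table dataset the analytics
consume. What it emulates: staggered activation (offsets 0, 91, 152 days);
per-site daily Poisson enrollment with rates drawn once per site from
Uniform(2, 3)/7 per day; gestational age at enrollment ~ Uniform(8, 20)
weeks (capped strictly below the 20-week limit); estimated delivery at
enrollment + (40 − GA) weeks; actual delivery at EDD + Normal(0, 10 days),
truncated to at least a week after enrollment; 30-day dispense cycles
(chosen to exercise the 14-day resupply lead rule); Bernoulli dropout
(default 6%) and protocol deviations (default 2/1100); and per-field eCRF
error injection (default 1%) with every corruption's location and kind
logged to an answer key, so `run_checks()` can be scored for *exact*
agreement. Each injected corruption is chosen so exactly one rule fires
(e.g. an out-of-range gestational age is injected *below* the range so the
20-week logic rule stays quiet).

The gestational-age and delivery-noise distributions are invented for
plausibility — no source specifies them — and the generator makes no
attempt at clinical realism of pregnancy outcomes or treatment effects:
passing tests demonstrate that the plumbing and the statistics are
correct under the stated stochastic model, not that the model describes
any real trial. The fixed-totals preset (`sim_config_fixed_totals()`)
truncates the three sites' event streams at 489/359/252 participants, so
reproducing those totals in the accrual report tests table plumbing by
construction, not luck.

Determinism: everything flows from one integer seed through a scoped RNG,
so a fixed seed reproduces the dataset byte-for-byte through a
write/read/write cycle.

## Problem sizes in the test suite

The suite favors many small simulated trials over few large ones: report
oracle-equivalence runs 100 fixtures of ~25 participants, answer-key
agreement 50 fixtures of ~40, forecast calibration 500 single-site trials
of 60 enrollments with 2000 draws each, and the full-scale 1100-participant
configuration is exercised a dozen seeds deep. These sizes give stable
pass/fail behavior at sub-minute cost; all headline quantities are
size-independent.

## Limitations

* The accrual model is homogeneous: no seasonality, no site random
  effects, no rate drift. The model interface (posterior object in,
  prediction out) is the seam where a richer model would plug in.
* The adaptive re-randomization *computation* is out of scope by design;
  the engine only consumes externally produced schedules.
* The data-quality engine validates field-level and registered cross-field
  rules; it does not attempt source-document verification (the human half
  of a two-pass review), email transport, or medical coding.
* Report delivery is out of scope: documents carry a recipients hint and
  are written to disk.
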