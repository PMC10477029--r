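---
title: "Weight-gain-based ROP screening: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-gain-based ROP screening: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropscreen)
```

This vignette is the package's account of its science: the screening
rules it implements, the conventions it had to fix where the source
descriptions are silent, the statistics behind the evaluation stage, what
the synthetic cohort generator does and does not emulate, and the known
limitations.

## The screening problem

Premature infants at risk of retinopathy of prematurity (ROP) undergo
serial retinal examinations, but only a small fraction — typically 3–6% of
those screened — develop type-1 disease requiring treatment. Early
postnatal weight gain tracks serum IGF-1, whose prolonged deficit precedes
sight-threatening ROP, so several algorithms use the weight trajectory
(together with gestational age and birth weight) to flag high-risk infants
and, prospectively, to spare the rest their examinations. The package
treats ROP outcomes as *inputs* (ETROP categories: none, mild, type 2,
type 1, plus a treatment flag); it performs no grading or imaging.

All gestational ages are stored in completed days (`weeks*7 + days`), and
postmenstrual age is `ga_days + postnatal_day`. Weight series are ordered
`(day, weight)` pairs anchored at birth with at most one weight per day
and a day-0 entry equal to the birth weight.

## Day-numbering convention

The day-window rules ("gain by the 28th day", "between day 10 and 19")
never state whether birth is day 0 or day 1. The package stores series
with birth = day 0 and defaults to interpreting rule days in the same
convention, so "day 28" means 28 elapsed days of life; a
`birth_day_index` switch (0 or 1, on every evaluator and in the pipeline
config) remaps all day-window rules for cohorts charted 1-based. Default
0 was chosen because it makes "weight gain by the 28th day" equal the gain
over 28 elapsed days, the reading consistent with "daily gain rate"
arithmetic.

## Nearest-day substitution

Weights are not charted on every nominal rule day. The G-ROP description
states the substitution rule explicitly — use the nearest measurement
within 2 days — and no alternative rule is stated for the other
algorithms, which were run from the same weekly charted weights. The
package therefore applies the ±2-day nearest-measurement rule as the
default for *all* resolved endpoints (G-ROP windows, the CO-ROP day-28
weight, CHOPROP weekly endpoints), overridable per algorithm via
`tolerance_days`. Two further choices the sources leave open:

* **Ties** (two measurements equidistant from the target) break toward the
  *earlier* day. In a gaining infant the earlier weight is lower, which can
  only push a gain criterion toward alarming — the conservative direction
  for a screening test, protecting sensitivity at the price of specificity.
* **No rescaling.** When substitution shortens or lengthens a nominal
  window (e.g. days 9–21 standing in for 10–19), the raw weight difference
  is compared against the fixed gram threshold unchanged, because the rule
  sets are stated as raw-gain thresholds. The resolved days are recorded in
  the `window_gain` result so an analyst can audit or re-derive rescaled
  gains if they prefer.

An endpoint with nothing within tolerance is *absent*; a rule criterion
with an absent gain counts as "not met", and a record that could not have
been fully checked without alarming is marked not evaluable rather than
silently counted as a negative.

## The four algorithms

**G-ROP** alarms on any of six criteria: (1) BW < 1051 g, (2) GA < 28
weeks, (3) gain day 10–19 < 120 g, (4) gain day 20–29 < 180 g, (5) gain
day 30–39 < 170 g, (6) hydrocephalus. All bounds are strict as written.
Every infant is entered (there is no separate gate). The alarm day is the
earliest day the fired criterion is determinable: birth for criteria 1, 2
and 6, the window's end day for 3–5.

**CO-ROP** alarms when GA ≤ 30+0 weeks (inclusive, "less than or equal
to"), BW < 1501 g (exclusive), and the day-28 gain over birth weight is
≤ 650 g. "Should not gain more than 650 g" is read as: a gain of exactly
650 g alarms, 651 g does not. The GA/BW clauses are part of the alarm
rule, not an entry gate: an infant failing them is a determinate
non-alarm, matching the usage in which all screened infants are entered.

**CHOPROP** gates on GA < 31 weeks or BW < 1501 g, then evaluates
`plogis(intercept + beta_ga*GA + beta_bw*BW + beta_wg*rate)` weekly from
the end of week 2 (days 14, 21, 28, ... in the default convention),
alarming the first time risk ≥ 0.014 — the cutoff is inclusive, as the
published ">/= 0.014" states. The rate is the weekly daily-gain rate:
(current weight − weight a week earlier)/7, so the day-14 evaluation uses
the day 7→14 change and the first week's change is never consulted. An
infant with no resolvable week-2 endpoint is not evaluable (the score
requires a documented end-of-week-2 weight); later unresolvable weeks are
skipped. The published coefficient set is **not** shipped: it is cited
but not printed in the validation literature this package follows, and
embedding invented numbers as authoritative defaults would be worse than
requiring the user to transcribe the real ones. Coefficients, their GA
unit (days or weeks) and the cutoff are configuration
(`read_choprop_model()`); the example file in `inst/extdata/` is labelled
synthetic and exists to exercise the pipeline. Whether the original study
evaluated weeks from birth or from charting dates is unknowable from the
description; weekly-from-birth is implemented.

**WINROP** is a proprietary online service; its internal longitudinal
model is deliberately out of scope. The package implements its entry gate
(GA < 32 weeks, irrespective of BW), an export helper that truncates the
weight series at 40 weeks postmenstrual age (the service accepts no later
weights), and a label adapter that joins externally obtained alarm
verdicts back into the evaluation, marking unlabeled eligible infants as
not evaluable.

## Evaluation statistics

For each endpoint (type 1, type 2, treated, any ROP) the entered infants —
eligible, evaluable, not excluded — are cross-classified against the
alarm. Proportions (sensitivity, specificity, PPV, NPV) carry Wilson
score intervals without continuity correction; `z` is the exact normal
quantile at the configured level (default 0.95), never a hard-coded 1.96.
Likelihood ratios LR+ = sens/(1−spec), LR− = (1−sens)/spec carry
delta-method intervals on the log scale,
`exp(ln LR ± z·se)` with
`se²(ln LR−) = sens/((1−sens)(tp+fn)) + (1−spec)/(spec(tn+fp))` and the
analogous form for LR+. The Wilson method is stated for "all
calculations" in the benchmark this package follows, but a score interval
does not apply to a ratio of proportions; the log method is adopted
because it exactly reproduces the benchmark's printed LR− interval
(0.13–0.78 from the 20/24, 253/484 table). Degenerate tables are pinned,
not dropped: sensitivity 1 gives LR− = 0 with lower bound 0 and an upper
bound from a half-count-corrected sensitivity; specificity 1 gives an
infinite LR+ reported as absent with a reason, and any metric with an
empty denominator is `NA` with a reason string.

`reconstruct_confusion()` inverts published summaries: with n and the
positives known, `tp = round(sens% * n_pos)` and
`tn = round(spec% * n_neg)` recover the integer counts uniquely at
one-decimal printing precision for cohorts of this size. Two published
inconsistencies surface when doing so and are deliberately *not*
reproduced: the benchmark's non-alarmed WINROP count (252) disagrees with
its own table's tn+fn (257), and its CO-ROP type-1 NPV lower bound
(98.3%) disagrees with Wilson on 162/162 (97.7%, which happens to equal
the bound printed for the treated-ROP row). The package computes both
sides; `exam_reduction()` always reports the alarm-derived count.

The exam-reduction analysis counts entered infants who never alarmed —
the examinations a deployment would save — as a percentage of entered
infants, with a breakdown of the type-1, type-2 and treated infants the
strategy would have missed.

## The synthetic cohort generator

No public patient-level data exist for this problem, so the generator is
a first-class module. It emulates:

* **Outcome mix** — groups drawn with probabilities 175/531, 292/531,
  40/531, 24/531 (none, mild, type 2, type 1); all type-1 infants
  treated, type-2 treated with probability 5/40.
* **Demographics** — per-group GA and BW from truncated normals at the
  benchmark's group means/SDs and observed ranges (GA SDs printed as
  whole weeks are taken as 14 days). Truncation is by rejection, not
  clipping, to avoid probability atoms at the bounds. GA and BW are
  coupled through a Gaussian copula with latent correlation 0.5
  (configurable): the benchmark's tables show a joint GA/BW gradient
  across groups, and uncorrelated draws would produce implausible
  combinations such as 24-week, 1400 g infants. Because several
  truncation ranges are asymmetric about the mean, the realized group
  means sit slightly off the nominal values (about +25 g for the
  smallest-BW group, under 0.2 group SDs everywhere); the test suite
  checks recovery against the truncated model's analytic expectation.
* **Trajectories** — piecewise: linear loss to 93% of birth weight by
  day 4, linear regain by day 12 (the typical physiologic loss/regain
  pattern), then daily increments `Normal(rate, 6 g)` with the infant's
  rate drawn from the group's rate distribution. Daily charting with 5%
  random missingness; follow-up to about 40 weeks postmenstrual age.
* **Group gain rates** — ~28, 23, 19 and 12 g/day for none/mild/type-2/
  type-1. These four numbers are *generator inventions*, not published
  values: they encode the IGF-1 surrogacy premise (slower growth, worse
  outcome) and were chosen once so that default cohorts qualitatively
  reproduce the benchmark's ordering of specificities. With the type-1
  group's GA range entirely below 28 weeks (as in the benchmark, where
  100% of type-1 infants were < 28 weeks), G-ROP's criterion 2 alone
  guarantees 100% type-1 sensitivity — the same mechanism the benchmark
  reports — and the low gain rate keeps their windowed gains below the
  gram thresholds as a second route.

The generator does **not** emulate: gestational-age-specific growth
references (Fenton/INTERGROWTH z-scores), oxygen-exposure or IGF-1
physiology, transfer-in infants with missing early weights, seasonal or
secular trends, or twins/multiples correlation. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline arithmetic*
is correct under the stated generative assumptions, not that any
algorithm will attain the same operating characteristics on a real
population — which is exactly why such algorithms require local
validation.

## Numerical and testing choices

Seeds: every stochastic routine accepts or inherits a seed; a fixed seed
gives byte-identical cohort files and reports. Weights are integers
(grams), so file round-trips are exact. The test suite exercises the
Wilson interval against a root-finding oracle on the score equation, the
G-ROP evaluator against an independently coded six-criterion brute-force
oracle on 10,000 random sparse records, the Bayes identities
`ppv/(1−ppv) = prev-odds · LR+` and `(1−npv)/npv = prev-odds · LR−` on
every table, and distribution recovery on a 50,000-infant draw — sizes
chosen to make binomial standard errors small relative to the tolerances
being checked while keeping the default suite comfortably fast on one
CPU. Smaller property loops (hundreds of cases) cover monotonicity: G-ROP
alarms are monotone under decreasing GA, BW or gains; CO-ROP under
decreasing day-28 gain; the CHOPROP alarm day is non-decreasing in the
cutoff.

## Limitations

* CHOPROP results are only as good as the transcribed coefficients; the
  package validates their presence and finiteness but cannot validate
  their provenance.
* WINROP verdicts are external inputs; the package cannot detect label
  errors beyond missingness.
* The exclusion machinery flags records (nonphysiologic weight gain,
  insufficient weights, missing outcome) rather than deleting them, but
  the judgement of *which* conditions distort weight gain remains with
  the data preparer.
* Day-level weight data are assumed; the generator and the tolerance
  rules cover weekly charting, but cohorts with sparser cadence will see
  many non-evaluable verdicts, mirroring the real-world data-loss problem
  these algorithms face.
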