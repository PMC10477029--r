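# ropscreen

Weight-gain-based screening algorithms for retinopathy of prematurity
(ROP), with a complete diagnostic-evaluation stage and a calibrated
synthetic neonatal cohort generator.

## The problem

ROP is a proliferative disease of the developing retinal vasculature in
premature infants. Conventional screening examines every infant below a
gestational-age/birth-weight cutoff (e.g. GA < 31 weeks and/or BW <
1250 g), but only a few percent of screened infants ever develop
treatment-requiring (type 1) disease, so most examinations — which are
stressful for the infant and costly for the service — are spent on
low-risk babies. Because early postnatal weight gain is a clinical
surrogate for serum IGF-1, whose deficit precedes severe ROP, several
alarm algorithms use the postnatal weight trajectory to flag the high-risk
minority. This package implements the rule- and score-based algorithms,
the weight-series primitives they share, and the statistics used to judge
them, for analysts validating such algorithms on a local cohort.

## What is implemented

**Alarm algorithms** (each returns eligibility, evaluability, alarm status,
triggering criteria and alarm day per infant):

- **G-ROP** — alarm on any of six criteria: BW < 1051 g; GA < 28 weeks;
  weight gain day 10–19 < 120 g; day 20–29 < 180 g; day 30–39 < 170 g;
  hydrocephalus. Missing endpoint days use the nearest measurement within
  ±2 days.
- **CO-ROP** — alarm when GA ≤ 30 weeks, BW < 1501 g, and net gain by
  day 28 is ≤ 650 g.
- **CHOPROP** — eligibility GA < 31 weeks or BW < 1501 g; a logistic risk
  `plogis(β₀ + β₁·GA + β₂·BW + β₃·rate)` on the weekly daily-gain rate
  (current minus previous week's weight, over 7), evaluated from the end
  of week 2, alarming when risk ≥ 0.014. Week-1 weight change is never
  used. Coefficients are **required configuration** (they are not
  distributed here); a clearly-labelled synthetic example set ships in
  `inst/extdata/choprop_model_synthetic.yaml`.
- **WINROP** — the proprietary online model is *not* reimplemented; the
  package provides its entry gate (GA < 32 weeks), a weight-series export
  capped at 40 weeks postmenstrual age, and an adapter for externally
  obtained alarm labels.

**Evaluation** — confusion tables per endpoint (type 1, type 2, treated,
any ROP), sensitivity/specificity/PPV/NPV with Wilson score intervals

    center = (p̂ + z²/2n) / (1 + z²/n),   half-width = z·√(p̂(1−p̂)/n + z²/4n²) / (1 + z²/n)

likelihood ratios LR+ = sens/(1−spec), LR− = (1−sens)/spec with
delta-method ("log method") intervals `exp(ln LR ± z·se)`, and an
exam-reduction analysis (how many entered infants never alarm, and which
outcomes they carry). `reconstruct_confusion()` recovers exact 2×2 counts
from published n / sensitivity / specificity summaries.

**Synthetic cohorts** — `sample_cohort()` draws outcome groups, jointly
correlated truncated-normal GA/BW per group, treatment flags and piecewise
weight trajectories (physiologic loss to a nadir, regain, then noisy daily
gain) calibrated to a published 531-infant screened cohort, so the whole
pipeline is testable without patient data.

## Worked example

```r
library(ropscreen)

cohort <- sample_cohort(531, seed = 20)
cohort
#> <rop_cohort> 531 infants, 41375 weight measurements
#>   outcomes: none=176, mild=286, type2=45, type1=24; treated=29
#>   median GA 28+2, median BW 1105 g

alarms <- screen_cohort(cohort, c("grop", "corop"))
report <- evaluate_all(cohort, alarms)
format_report(report[report$endpoint %in% c("type1", "all"), ])
#> == endpoint: type1 ==
#>   grop (n=531): sensitivity 100.0% (86.2-100.0); specificity 37.7% (33.6-42.0); ...
#>   corop (n=531): sensitivity 100.0% (86.2-100.0); specificity 29.6% (25.8-33.7); ...
#> == endpoint: all ==
#>   grop (n=531): exam_reduction_count 191; exam_reduction_percent 36.0%
#>   corop (n=531): exam_reduction_count 150; exam_reduction_percent 28.2%
```

Every synthetic type-1 infant is below 28 weeks GA, so G-ROP's criterion 2
catches them all: sensitivity 100% with Wilson CI 86.2–100% (the 24/24
interval), while 36% of infants would be spared an examination.

Working from published summaries instead of raw data:

```r
ct <- reconstruct_confusion(508, 24, 83.3, 52.3, "type1", "winrop")
ct
#> <confusion_table> winrop x type1 (n=508): tp=20 fp=231 fn=4 tn=253
diagnostic_metrics(ct)[, c("metric", "point", "lower", "upper")]
#>        metric  point  lower upper
#> 1 sensitivity 0.8333 0.6415 0.933
#> 2 specificity 0.5227 0.4782 0.567
#> 3         ppv 0.0797 0.0522 0.120
#> 4         npv 0.9844 0.9607 0.994
#> 5 lr_positive 1.7460 1.4270 2.136
#> 6 lr_negative 0.3188 0.1298 0.783
```

A command-line pipeline (`inst/cli/ropscreen.R simulate|screen|evaluate
--config cfg.yaml`) chains generation → screening → evaluation with file
handoffs, so externally obtained WINROP labels can be injected between the
screen and evaluate stages.

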