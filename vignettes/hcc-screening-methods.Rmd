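---
title: "Screening algorithms for HCC surveillance: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening algorithms for HCC surveillance: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccscreen)
```

## The problem

Cirrhosis patients under HCC surveillance accumulate serial α-fetoprotein
(AFP) measurements, usually alongside routine liver labs (ALT, platelets).
A screening algorithm must decide, visit by visit, whether to refer the
patient for diagnostic imaging. Evaluating such algorithms is not a
single-time-point classification problem: a case's screens near diagnosis
mean something different from screens years earlier, false positives
accumulate per patient over time, and algorithms that use history behave
differently at a patient's first and fifth visit. `hccscreen` implements
two history- and covariate-aware screening rules, the fixed-threshold
baseline, and the longitudinal evaluation framework that makes them
comparable.

## Data model

A cohort is three tables. `patients` holds the case indicator δ, the
endpoint `d` (months from the HCV index date to HCC diagnosis for cases,
to end of study for controls) and baseline age. `visits` holds AFP tests
(`t` in months, AFP in ng/ml, AFP > 0 required). `labs` holds ALT/PLT
records. `prepare_screens()` produces the per-screen analysis table:
same-day duplicates are collapsed to the anti-log2 of the mean of log2
values; each AFP visit picks up the most recent ALT and PLT drawn in the
closed window `[t - 6, t]` months (a same-day lab counts; one at exactly
six months counts; visits missing either analyte are flagged ineligible
for the laboratory model but stay available to AFP-only rules); the
annualized change `dafp_rate = Δlog2(AFP) / (Δt/12)` is defined only when
the previous AFP is at most 12 months old; and the outcome `D` is 1 exactly
when `d < t + 6` and δ = 1 (strict inequality). Age at a visit is
`baseline_age + t/12`.

One asymmetry is deliberate: the laboratory risk model truncates its
covariates (AFP, ALT, PLT) at 1 before the log transform, but the PEB
machinery consumes untruncated log2(AFP). The hierarchical model below is
a model for log2(AFP) itself; flooring at 1 ng/ml puts a point mass at
zero on roughly 3% of control measurements when θ̄ ≈ 2.9, which biases
both variance components downward by 5–8% and would silently degrade the
shrinkage weight. Since valid AFP is positive by inclusion, no floor is
needed there.

## The PEB rule

With control-model parameters (θ̄, σ², τ²), standardize
`Z = (log2(AFP) − θ̄)/√(σ² + τ²)`. The marginal law of Z in controls is
standard normal, so the fixed-threshold rule `Z > z_{1−f₀}` has per-screen
false positive rate f₀. The PEB rule replaces the population center with a
patient-specific posterior mean: at screen `j`, with `Z̄` the mean of the
`j − 1` prior standardized values,

```
B_j   = τ² / (σ²/(j−1) + τ²)        (B_1 = 0)
μ̂    = B_j · Z̄
flag  ⇔ Z > μ̂ + z_{1−f₀} · √(1 − B₁ B_j)
```

Because `Z − μ̂` is Gaussian with mean 0 and variance `1 − B₁B_j` under
the null for every `j`, the rule holds f₀ exactly at each screen index —
the first screen is literally the fixed-threshold rule, and later screens
shrink toward the patient's own level, which is where the reduction in
repeated false positives for stably-elevated patients comes from. The
continuous score `Φ((Z − μ̂)/√(1 − B₁B_j))` is exported for percentile
curves; the boolean rule is exactly `score > 1 − f₀`.

Parameters are estimated once on training-cohort controls (REML
random-intercept fit via `lme4`), restricted to screens with AFP < 400
ng/ml — screens at or above the OR-rule cut-off are never adjudicated by
the algorithm — and then frozen for validation; there is no online
updating. Screens already positive under the OR rule *do* enter the later
history mean by default (the history in the rule is defined over all prior
standardized values); `exclude_or_history = TRUE` flips this. Variance
components at the boundary (τ̂² = 0) degrade gracefully: B₁ = 0 and the
rule collapses to the fixed threshold, with a warning.

## The six-month risk model

The laboratory-based algorithm is a logistic model for `D` on a design of
continuous piecewise-linear (hinge) bases with fixed knots: log2(AFP) with
knots at 2, 7, 9; log2(ALT) at log2 of 20, 50, 100, 200; platelets at 35;
age at 50; and the annualized AFP change at −8, 0, 2, 9, gated by its
observability indicator (the complementary term `1 − ΔAFPobs` enters as a
main effect, and the whole change basis is zeroed when no recent prior AFP
exists). All hinges use strict indicators `(x − k)·I(x > k)`, so each
basis is continuous at its knots — asserted numerically in the tests.

Two points the displayed model leaves open were resolved as follows:

* **Interactions.** The AFP×ALT and AFP×PLT terms multiply two basis
  vectors of unequal length. The default expansion is the full outer
  product (4×5 = 20 and 4×2 = 8 columns), the standard spline-interaction
  expansion; `interactions = "linear"` restricts to the product of the
  linear terms for a leaner 21-column design.
* **Intercept.** Every per-iteration fit includes an intercept; a
  no-intercept logistic on these bases has no sensible null.

Fitting uses cross-sectional resampling to respect the longitudinal
structure: in each of K = 100 iterations one visit is drawn per training
patient and a plain maximum-likelihood logistic fit is run; prediction
averages the K per-iteration risks on the probability scale, so the
predicted risk is always inside (0, 1) and invariant to iteration order.
Training is restricted to AFP < 400 ng/ml screens (and, for the full
covariate set, lab-eligible screens). Iterations that separate or fail to
converge — routine when few `D = 1` visits are drawn — are refitted with a
small ridge penalty (α = 0, λ = 10⁻⁴, fitted along a short decreasing
λ path with constant columns dropped) and counted in the diagnostics.
Iteration k draws its visits from an independent substream of the model
seed, so changing K does not reshuffle earlier draws.

## OR rule, calibration, percentile curves

Every algorithm is wrapped in the OR rule: a screen is positive when
AFP ≥ 400 ng/ml (boundary inclusive) or the algorithm's score exceeds its
threshold (strict). `calibrate_threshold()` returns the smallest observed
score threshold whose achieved screening-level FPR does not exceed the
target, together with the achieved value (ties can push it strictly below
the target) and the floor contributed by the AFP ≥ 400 screens alone; an
unreachable target is an error, not a silent clamp. Calibration can use
the training split (the honest prospective protocol, the default in
`run_experiment()`) or the validation split, which reproduces the usual
fixed-FPR reporting convention where the validation FPR equals the target
exactly; both modes exist because fixed-FPR tables in the literature are
conventionally of the second kind.

Risk percentiles use mid-ranks — the fraction of scored screens strictly
below plus half the tied mass — which keeps the control-only identity
`FPR = 1 − percentile` exact, a property the tests pin. Performance
curves are evaluated at every attainable threshold (each unique score), so
reading the curve at the percentile where FPR = 0.10 reproduces the
directly calibrated fixed-FPR table row identically rather than to grid
tolerance. Decile risk splits scored screens into equal-count score
deciles, estimates the fraction followed by diagnosis within τ₁ months in
each, and smooths through decile midpoints with a natural cubic spline
(`stats::spline`); empty deciles are omitted with a warning.

## Longitudinal evaluation

A detection window (τ₁, τ₂) declares case screens in `[d − τ₁, d − τ₂]`
(both ends inclusive) true-positive-eligible; case screens strictly before
`d − τ₁` count as false-positive opportunities; screens in `(d − τ₂, d]`
are excluded (a positive there is too late to change management when
τ₂ = 3). The standard labels are A1 (6, 0), B1 (12, 0), C1 (24, 0),
D1 (max follow-up, 0) and their τ₂ = 3 counterparts A2–D2.

All four measures are natural plug-in (empirical proportion) estimators of
their defining conditional probabilities, and the tests verify them
against brute-force enumeration on small cohorts for every window:

* **TPR** is patient-level: among cases with at least one screen in the
  window, the fraction with at least one positive screen there. Cases
  never screened inside the window leave the denominator — which is why
  fixed-FPR tables show different case counts per window.
* **FPR** is screening-level: positives among all control screens plus
  case screens before `d − τ₁`.
* **PPV/NPV** are screening-level. By default, excluded-region screens
  still reach the denominators through their positivity status — the
  displayed conditionals condition only on the screen's result — with
  `include_excluded = FALSE` available to drop them entirely. The same
  switch governs the NPV denominator, whose treatment of excluded-region
  negatives the definitions leave open.
* **Burden** is the fraction of patients (with ≥ 1 FP-eligible screen)
  who accrue more than two positive FP-eligible screens.
* **First-positive timing** compares, per algorithm pair and per case with
  at least one window screen and at least one algorithm positive, who
  flagged first; an algorithm with no window positive is assigned the
  diagnosis time itself.

## The synthetic cohort generator

`sim_config()` defaults are the study conditions the methods assume, not
tuning knobs. Controls: random-intercept log2(AFP) with θ̄ = 2.92,
τ² = 1.90, σ² = 0.71 (ICC 0.73). Visit counts fall in categories
1 / 2 / 3–4 / >4 with probabilities 28.5 / 23.1 / 26.4 / 22.0%; inter-visit
gaps are gamma with mean 11.67 and SD 11.0 months (gamma chosen as the
simplest positive law with two free moments); the follow-up horizon is
108 months. ALT is lognormal around a mean log2 level of 6.14 (marginal SD
1.03, split into between- and within-patient parts); platelets are
truncated normal around 147.97 (SD 78.88, in thousands); each analyte is
drawn near each visit with probability 0.95 at a uniform offset of up to
3 months before it. Baseline age is N(52.87, 7.28²).

Cases follow the control model until a changepoint at `d − L`,
L ~ Uniform(0, 24) months, after which mean log2(AFP) rises linearly at
0.15 per month — the simplest mechanism with a tunable effect size, chosen
because no case trajectory model is established for this setting and the
test surface is parameter recovery plus directional comparisons, not
absolute sensitivity values. The slope default puts the mean elevation at
diagnosis near 1.8 log2 units, matching the observed gap between case and
control baseline AFP levels. Diagnosis is anchored to the screening
schedule — `d` is the last scheduled visit plus an exponential delay (mean
3 months, capped at 12) — because surveillance diagnoses are typically
triggered by a recent screen; an independently drawn `d` would leave
almost no case with a screen near diagnosis, contradicting the structure
of real surveillance cohorts where roughly 80% of cases have a screen in
their final six months. ALT/PLT are generated independently of AFP; the
association observed in real cirrhosis patients is not modelled, so the
synthetic cohort cannot demonstrate the specificity gain the lab model
derives from explaining benign AFP elevations — a genuine limitation of
what passing tests show about real data. The generator also makes no
attempt at death/censoring processes, assay changes, or informative visit
timing in controls.

Every cohort carries a truth sidecar (θᵢ, onset time) sufficient to build
oracle labels, and the generator is byte-reproducible from its seed.

## Numerical and procedural choices

* Normal quantiles and the Φ score are computed in double precision
  (`qnorm`/`pnorm`); `√(1 − B₁B_j)` is always positive since B₁ < 1 and
  B_j ≤ 1, and this is asserted.
* Threshold positivity is strict (`score > c`) everywhere, matching the
  displayed decision rules; the AFP ≥ 400 cut-off is inclusive.
* Stratified split-sample halves assign the odd patient to training.
  Out-of-bag bootstrap training draws re-identify duplicated patients so
  a patient sampled twice contributes two independent resampling units;
  replicates whose out-of-bag set has no evaluable case are skipped and
  counted. Split-sample and bootstrap validation share one evaluation
  code path.
* All randomness flows from a single root seed through named substreams
  (simulation, split, per-iteration visit draws, bootstrap replicates),
  with every derived seed kept below 2³¹.

## Problem sizes used in the checks

The package's own verification uses desk-scale simulations chosen to make
Monte-Carlo error small relative to the assertion bands: false positive
rate control of both rules on 2,000 null control patients × 6 screens
(pooled rate within ±0.6 percentage points; each screen index within
3 Monte-Carlo standard deviations at n = 2,000); variance-component
recovery within 5% on 5,000 control patients; the directional comparison
(PEB vs fixed threshold at matched 10% FPR) on 2,000 controls and 200
cases. Exact identities — oracle equivalence of the measures, rule
equivalence at j = 1, knot continuity, curve/table consistency — are
checked on enumerable cohorts where brute force is feasible.

## Known limitations

Beyond the generator caveats above: the PEB extension with covariates is
out of scope; the risk model's knots are treated as fixed constants
(no knot or variable selection); PPV/NPV conventions for excluded-region
screens are configurable precisely because the definitions underdetermine
them — both modes are first-class and tested; and absolute performance
numbers produced on synthetic cohorts characterize the implementation
under its assumed model, not clinical performance in any real population.
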