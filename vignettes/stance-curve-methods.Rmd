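---
title: "Methods: stance-phase curve extraction and anthropometric regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stance-phase curve extraction and anthropometric regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stancecurve)
```

## The measurement and the model

A pressure insole reports the total vertical ground reaction force under
one foot, here at 100 Hz in Newton. While walking, each ground contact
(stance phase) produces an M-shaped force curve: weight acceptance up to
a first maximum Fz2, mid-stance unloading to a local minimum Fz3, active
push-off to a second maximum Fz4, then unloading to toe-off. The package
reduces each stance to nine parameters — four section means, the three
extrema, and the loading/unloading slopes — and models each parameter's
per-subject mean as a linear function of age, body height, body weight
(or BMI) and handgrip strength by forced-entry ordinary least squares.

The statistical model, per parameter \(y\) and subject \(i\):

\[
y_i = \beta_0 + \beta_1\,\mathrm{age}_i + \beta_2\,\mathrm{height}_i +
\beta_3\,\mathrm{weight}_i + \beta_4\,\mathrm{grip}_i + \varepsilon_i,
\]

with a second model replacing height and weight by BMI. Forced entry
means every predictor stays in the model regardless of significance —
appropriate when the predictor set is small and each has a plausible
mechanism. Height, weight and BMI are never entered together (BMI is a
function of the other two; the design would be ill-conditioned, and
`fit_model()` refuses rank-deficient designs outright). No
multiple-testing correction is applied: each of the 9 × 2 fits uses
α = 0.05 per test, which keeps the published analysis convention; users
comparing many parameters should interpret borderline p-values
accordingly.

## Pipeline stages and their tunables

### Step detection (`detect_stance_events`)

A stance candidate is a maximal run of force readings strictly above
`force_threshold` (default 30 N). Two decisions deserve note:

* **Gap tolerance applies to missing samples only.** Insole links drop
  samples; a run may bridge at most `max_gap = 3` consecutive missing
  samples. A *measured* sub-threshold value always terminates the run —
  the tolerance models device faults, not swing-phase contact.
* **Duration is measured first-to-last sample** (closed interval, n − 1
  sample periods) and gated inclusively to `[300, 2000]` ms. Durations
  are computed from timestamps, so missing samples inside an event do
  not distort them.

### Dual-axis normalization (`normalize_stance`)

Force is divided by the subject's static weight force (mass × g,
g = 9.81 m/s² by default, configurable) and expressed in percent body
weight. Ground reaction force is dynamic, so peaks above 100 %BW are
normal and no ceiling is applied.

Time is normalized by fitting a **natural cubic spline** (second
derivative zero at both boundary knots) to the non-missing
(timestamp, force) pairs and evaluating it at 100 equidistant points
spanning the event inclusively: index *i* ∈ {0, …, 99} sits at *i*/99 of
stance duration, so one index step is 1 % of stance duration — the unit
the slope parameters are expressed in. The inclusive-endpoint
convention keeps initial and final contact representable; "one sample
per percent of stance" is ambiguous between 1/99 and 1/100 spacing, and
we fix the former. Missing samples are simply absent from the knot set
(the spline bridges them, consistent with the segmentation gap
tolerance); events with fewer than 4 knots cannot support a cubic
spline and are rejected with a reason code. Spline undershoot below
zero (possible near sharp transients) is clipped to 0 %BW: negative
vertical ground reaction force is unphysical. Interpolation is over
timestamps, not sample indices, so irregular gaps do not warp the time
axis.

### Extremum location (`locate_extrema`)

Sensor jitter makes raw local extrema ambiguous. The curve is smoothed
with a truncated Gaussian kernel (σ = 3 index units, 7 taps, weights
normalized to sum 1; mirror reflection at the edges, which preserves
constants exactly). The filter is applied to the 100-point normalized
curve — one canonical domain for all index arithmetic. Crucially the
filtered curve is used **only to pick indices**; the reported forces are
read from the unfiltered curve at those indices, so smoothing never
attenuates the parameter values.

Candidates are strict interior local extrema; a plateau contributes its
center index (rounded down). If the candidate set is not already
exactly two maxima enclosing one minimum, four strategies run in order,
each only while ambiguity remains:

(a) *time plausibility*: drop candidates at index < 10 or ≥ 90 (the
    half-open upper bound is a convention);
(b) *pool filtering*: same-polarity candidates linked by pairwise
    distance ≤ 5 indices (transitive closure) form a pool; the pool's
    highest maximum / lowest minimum survives, ties to the earlier
    index;
(c) *monotony check*: a surviving maximum (minimum) must have the
    filtered curve strictly decreasing (increasing) for 5 indices on
    both sides;
(d) *monotony grace*: if (c) leaves fewer than two maxima or no
    minimum, its rejects return in descending order of the monotone run
    length achieved on their weaker side (capped at 5; ties broken by
    distance from the curve mean) until two maxima and one minimum are
    reached.

Any other final state — wrong counts, or the minimum not strictly
between the maxima — marks a **non-step event** (turning artifacts,
shuffles, partial contacts) and the event is excluded with the failing
rule logged. The tie-break rules in (b) and (d) and the definition of
"monotony distance" are explicit package conventions; the procedure's
published description leaves them open.

One subtlety, verified by the test suite: a truncated Gaussian filter
shifts the argmax of a peak with asymmetric curvature by roughly an
index. The cascade is therefore exact on locally symmetric peaks and
may sit one index off on strongly skewed ones — the force value is
still read from the unfiltered curve, where the cost of one index near
a stationary point is second-order.

### Parameters (`compute_parameters`)

All section means use inclusive index ranges (boundary samples shared
by adjacent sections — symmetric, and verified by a reconstruction
identity in the tests). The loading slope is the secant from index 0 to
the first sample at or above 80 % of Fz2; the unloading slope is the
secant from the first sample after Fz4 below 80 % of Fz4 to index 99.
Start of loading = index 0 and end of unloading = index 99 are fixed
conventions. Events where the 80 % crossing collapses a denominator
(crossing at index 0 or 99, or absent) are flagged degenerate and
excluded from aggregation rather than contributing infinite slopes.

### Aggregation and regression

A subject's curve is the index-wise arithmetic mean of all accepted
steps, both feet pooled (left/right pooling is a package choice; the
event-level table keeps the side column for per-foot audits). Parameter
means are taken over the same accepted, non-degenerate events. Group
comparison curves carry pointwise t-based 95 % confidence bands,
undefined (and flagged) for singleton groups.

OLS is delegated to `stats::lm`; the package adds standardized Betas
(sample SDs, n − 1), the adjusted R², the overall F-test, and an
explicit collinearity guard. The tests verify the whole fit against
hand-coded normal equations. Raw coefficients are in dependent-units
per predictor-unit (e.g. %BW per kg).

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` exists so the full pipeline can be validated against
known ground truth without any recorded data:

* **Cohort**: truncated-normal age/height/weight/grip with the published
  healthy-cohort means, SDs and ranges (age 43.65 ± 17.59 in 18–87,
  height 173.70 ± 11.22 cm, weight 79.81 ± 27.85 kg, grip
  35.41 ± 12.46 kg); BMI derived. Predictors are sampled independently —
  real anthropometrics co-vary (taller people are heavier), so the
  synthetic design is *easier* for regression than a field sample.
* **Planted effects**: the three extremum targets are linear in the
  centered predictors with the published raw coefficients for Fz2, Fz3,
  Fz4 (zeros where no effect was reported), around baselines
  110 / 75 / 105 %BW. Subject-level residual SDs are derived in closed
  form, `sqrt(signalVar · (1 − R²)/R²)`, to land the population R² at
  the published adjusted R² of those parameters (0.376 / 0.199 / 0.282).
  Section means and slopes are *induced* by the same curve rather than
  independently planted: a shape generator whose degrees of freedom are
  the three extrema cannot also set four overlapping section means and
  two crossing-based slopes to arbitrary values. Their regressions are
  exercised, but coefficient-recovery claims are made for the extrema.
* **Gait**: alternating stance (truncated normal, 650 ± 40 ms within
  450–900) and swing (400 ± 30 ms), right foot shifted half a cycle;
  1 minute at 100 Hz per foot. Each stance renders a closed-form
  template of four raised-cosine ease segments joined with zero slope at
  the three extrema — C¹-smooth, exactly hitting the extremum targets at
  28 / 50 / 72 % of stance, strictly monotone in between, zero force at
  both edges. (An additive two-bumps-minus-a-dip template cannot hit
  prescribed extremum values while returning to zero at the edges; the
  ease-segment construction can, which is why it was chosen.)
* **Sensor model**: additive Gaussian noise (3 N SD, a realistic
  total-force jitter for consumer insoles) floored at 0 N, and Bernoulli
  sample dropout (p = 0.004) producing the short missing runs the gap
  tolerance is designed for.

Not emulated: anthropometric correlations, left/right asymmetry,
cadence drift and fatigue, pathological double-peak loss, per-sensor
(16-channel) spatial information, walking-speed variation. Passing
end-to-end tests therefore demonstrates that the pipeline recovers what
it is designed to measure under its stated assumptions — not that those
assumptions hold in any particular clinical population.

## Numerical choices

* Threshold "above 30 N" is strict (`>`); the duration gate is
  inclusive.
* All index arithmetic uses the 0–99 convention of the normalized
  curve; slopes are %BW per index = %BW per % stance duration.
* Plateau candidates take `floor((start + end)/2)`.
* The determinism contract is byte-level: identical configuration and
  seed reproduce identical parameter CSVs and manifest checksums
  (verified in the tests); all generator randomness flows from one seed
  through a single RNG stream.
* Problem sizes in the validation suite: segmentation is checked against
  a brute-force window enumerator on 1000 random sequences; the extremum
  cascade against an independently coded exhaustive reference on 1000
  smooth curves; end-to-end coefficient recovery on 50 replicates of a
  200-subject cohort (a size at which the 95 % CIs are narrow enough to
  make coverage informative), with zero-planted cells tested against
  binomial 99 % bounds at the nominal 5 % false-positive rate.

## Known limitations

* The extremum cascade targets regular M-shaped walking curves; running,
  stair climbing and many pathological gaits violate its 2-maxima
  assumption by design and are rejected as non-step events rather than
  characterized.
* With ~100 steps per subject the event-level noise contributes little
  to subject means; for short recordings (few steps) the per-subject
  parameter estimates, and hence the regressions, degrade.
* The 80 %-crossing slope definitions are sensitive to the curve value
  at single indices; degenerate flags catch the pathological cases but
  borderline events still contribute slope variance.
* Regression assumes complete predictor data; no imputation is offered.
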