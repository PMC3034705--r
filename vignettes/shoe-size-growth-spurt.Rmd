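---
title: "Detecting the pubertal foot growth spurt from shoe-size records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the pubertal foot growth spurt from shoe-size records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footspurt)
library(dplyr)
```

## The measurement model

The raw material is a table of shop visits: a client identifier, sex, birth
date, visit date, and the measured EU shoe size of each foot. Three
properties of such data drive every design choice in this package:

* **Quantization.** Each foot is measured to the nearest half-size; the
  analysed value is the *unrounded* average of both feet, so it lives on a
  0.25-size grid. One EU size is one Paris point, 20/3 ≈ 6.7 mm of last
  length, so the measurement grid is coarse relative to growth: a foot can
  grow several millimetres without the recorded size moving.
* **Irregular sampling.** Children visit a shoe shop when they need shoes —
  roughly every 0.6–0.7 years during the analysed age range, but with wide
  variation, and records start in infancy and stop whenever the family
  stops coming (censoring).
* **No latent model at analysis time.** The analysis statistics are defined
  directly on the recorded step function, without smoothing or curve
  fitting. Fitting a growth model to data this coarse and short would mostly
  return the prior; the window statistic below needs no such commitment.

Ages are computed as exact day counts divided by 365.25 — deterministic and
leap-year-safe; no rounding.

## The peak-increase statistic

For one client's eligible visits (ages strictly above 8 years), consider
every ordered pair $(i, j)$ with $s_j - s_i \ge 2$ EU sizes. The *peak
increase* is the pair minimizing $t_j - t_i$; the estimated spurt age is the
window midpoint and the velocity is the observed increase over the observed
duration. Rationale and conventions:

* **Threshold 2.0, inclusive.** On the half-size grid an increase of
  exactly 2.0 is attainable and common; treating it as "not two whole
  sizes" would be arbitrary. The threshold is a `min_increase` argument.
* **Velocity from the observed increase.** The window often overshoots the
  threshold (e.g. a 2.5-size rise); velocity uses the actual rise, which is
  why cohort mean velocities exceed 2 sizes/year.
* **Ages strictly above 8.** Windows never straddle the age-8 boundary:
  both endpoints must exceed `min_age`. The floor exists to exclude
  pre-pubertal growth and precocious puberty from masquerading as the
  spurt; strict inequality keeps the rule identical to the selection
  criteria's reading of "above".
* **Tie-breaking.** Several windows can share the minimal duration
  (uniform growth guarantees it). Ties go to the earliest start age, then
  to the largest increase. Any fixed rule would do; this one is
  deterministic, favours the earliest evidence of the spurt, and is
  documented so results are reproducible across implementations.
* **Degenerate inputs.** Fewer than two eligible visits, or no qualifying
  pair, yield `found = FALSE` with a machine-readable reason rather than an
  error — cohorts legitimately contain such clients and the selection
  report needs to count them.

`detect_peak()` is deliberately the naive $O(n^2)$ exhaustive search —
series have tens of visits, and the exhaustive form *is* the definition,
which the test suite cross-checks against an independently written oracle
on 1,000 random quantized series.

## The plateau rule

Cessation of foot growth is read from the earliest post-peak run of visits
in which no size exceeds the run's first value (plus a tolerance) that
lasts at least 1 year. Conventions:

* The run must start strictly after the detected peak age, which excludes
  pre-spurt flat stretches; runs shorter than a year are ignored as
  temporary plateaus (new shoes bought for width or wear, not length).
* `tol = 0` by default: "did not increase any further" is read literally on
  the recorded grid. With averaged feet a 0.25-size wobble is pure
  measurement noise, so `tol = 0.25` is a reasonable alternative and is a
  plain argument.
* Growth resuming after a qualifying run (a late second rise, seen in some
  boys) sets `resumed_growth = TRUE` but keeps the plateau. Whether such
  clients belong in plateau summaries is genuinely ambiguous; the package
  surfaces the flag instead of deciding silently.
* A single-step *decrease* of more than 1 size within a series is flagged
  as a suspect record (mis-measurement or data entry). Suspect series are
  excluded from plateau analysis by default — a spurious high point would
  otherwise anchor a false run — but kept for peak analysis, where a
  spurious point can only shorten a window it actually contains. Both
  behaviours are toggleable.

## Selection and summaries

A client is analysed when three criteria hold, checked in a fixed order so
each exclusion carries one reproducible first-failing reason: at least 5
visits above age 8 ("more than 4"), a span of those visits strictly greater
than 2 years, and a last visit strictly above 12 y (girls) / 13 y (boys).
Follow-up is measured over the visits above age 8, matching how follow-up
time is tabulated in the summary; a `followup_over = "all"` toggle exists
because records legitimately start in infancy and the alternative reading
is defensible.

Summaries report per-sex means and SDs (n − 1 denominator) with a pooled
total row computed from the pooled individual values — which makes every
total mean exactly the sample-size-weighted combination of the sex means,
an identity the tests assert. The mean inter-visit interval is the ratio of
the follow-up mean to the measurement-count mean; this is the convention
under which the interval, follow-up and count columns of a summary table
are mutually consistent. Reported precision (1 decimal for ages, sizes and
velocities; 2 for intervals; integer percent for attrition) is applied only
at the reporting layer, with half-up rounding; all computation is full
precision.

Lead times subtract the cohort's mean peak-increase age from reference
sitting-height peak-growth-velocity ages (defaults 11.7 y girls, 14.0 y
boys, SDs 0.8/0.9 — Dutch reference values contemporaneous with typical
shoe-shop records; `reference_growth()` accepts overrides). The
`sensitivity_analysis()` verb re-runs selection and detection at stricter
last-age cutoffs: the selected n must fall monotonically, and a stable mean
peak age indicates the estimate is not driven by the inclusion boundary.

## The synthetic cohort generator

The generator exists so the pipeline can be validated against known ground
truth. Each client's latent foot size follows a double logistic,

$$s(t) = C + \frac{A_1}{1 + e^{-k_1 (t - m_1)}} + \frac{A_2}{1 + e^{-k_2 (t - m_2)}},$$

a childhood component plus a pubertal component. This form was chosen over
Preece–Baines because its velocity is closed-form, each component is
controlled independently, and the calibration requirement is only
distributional: the pubertal midpoint $m_2$ is drawn per sex from
N(10.4, 1.1²) (girls) and N(11.5, 1.5²) (boys) years, and the adult size
$C + A_1 + A_2$ from N(38.9, 1.5²) / N(41.4, 1.8²) EU. The childhood
component's centre values ($C = 16$, $A_1 = 14$, $k_1 = 0.45$/y,
$m_1 = 3.5$ y, with small per-client jitter) put size at age 8 around
28–31 EU; the pubertal rate $k_2$ is uniform on 1.1–1.6/y. Ground truth per
client: the argmax of the analytic velocity on a 0.001-year grid over
[6, 18] (the true spurt age), the adult size, and the first age within 0.25
sizes of it (the true cessation age).

Observation mimics the shop protocol: first visit uniform at 1–3 y,
inter-visit gaps gamma with shape 4 (mean 0.61 y girls / 0.69 y boys —
shape 4 keeps gaps away from zero, with a hard 0.05-y floor), censoring age
uniform on 10–17 y so that the selection criteria genuinely bite, a
per-client left/right asymmetry (SD 0.15 sizes), per-foot noise
(SD 0.25 sizes), and rounding of each foot to the nearest half-size before
averaging. All randomness flows from one integer seed; each client uses a
substream derived from the seed and client index, so cohorts are
reproducible byte-for-byte and a cohort prefix does not change when later
clients are added.

What the generator deliberately does **not** model: secular trends, seasonal
shoe buying, brand-to-brand sizing differences, recall bias in reported
sizes, or any correlation between spurt timing and visit behaviour. Passing
parameter-recovery tests therefore shows that the statistics recover a
known spurt from quantized, irregular, noisy series — not that retail data
are free of those additional artifacts.

## Validation choices and problem sizes

The test suite validates each layer at sizes chosen to keep the full run
around a minute while leaving sampling error well below the tolerances
asserted: the peak detector against an independent exhaustive oracle on
1,000 random series; the generator's calibration on 500 girls (mean true
spurt age within 0.15 y of 10.4, i.e. ~3 standard errors); end-to-end
recovery on a 242-girl + 104-boy cohort (mean detected peak age within
0.5 y of the selected clients' mean true spurt age and 0.4 y of the
configured means); plateau-size recovery on a noise-free cohort of the same
size (mean detected-minus-true adult size within 0.5 EU); and the dense
noise-free regime (gap mean 0.3 y, no noise) where at least 90 % of clients
whose records span the spurt are recovered within 0.7 y. Fixed seeds make
every stochastic assertion reproducible.

## Known limitations

* Shoe size is a proxy: different brands map size to length differently,
  and the recorded size reflects when shoes were *bought*, not when the
  foot grew. Nothing in the package calibrates brand-specific lasts.
* The plateau statistic is conservative on censored records — a child last
  seen growing has no plateau, and late second spurts make boys' plateau
  summaries depend on who is still visiting the shop at 15–16. The
  `resumed_growth` flag and per-reason counts exist to keep that visible.
* The window midpoint estimates the spurt age only up to the sampling
  pattern: with visits 0.6 y apart the midpoint cannot be more accurate
  than roughly a quarter of a window. Cohort means are far more stable than
  individual estimates, which is why reporting is cohort-first.
* Lead times compare a cohort mean against an external reference mean; they
  are not individual predictions of a patient's sitting-height spurt.
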