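# footspurt

Timing of the pubertal foot growth spurt from longitudinal shoe sizes.

## The problem

In the management of adolescent idiopathic scoliosis it matters greatly
*when* a child's spine will have its pubertal growth spurt, usually tracked
through sitting height. Growth follows a distal-to-proximal gradient: the
feet spurt one to two years before the trunk. Shoe size is a practical proxy
for foot length — families remember when they bought new shoes and what size
they were — so the longitudinal course of shoe size is an early, cheap
indicator of the coming sitting-height spurt.

`footspurt` is an R package for clinicians and growth researchers working
with longitudinal shoe-size records (one row per shop visit or recalled
purchase). It implements:

* **Cohort selection** — a client enters the analysis with more than 4
  measurements above age 8, more than 2 years of follow-up among those
  visits, and a last measurement above 12 y (girls) / 13 y (boys);
  exclusions are reported with their first failing criterion and attrition
  percentages.
* **Peak-increase detection** — the core statistic. For visit ages
  \(t_i\) and recorded sizes \(s_i\) (EU half-sizes, averaged over both
  feet), the *peak increase* is the shortest window with a two-whole-size
  rise:

  \[(i^\*, j^\*) \;=\; \arg\min_{i<j,\; s_j - s_i \ge 2}\;(t_j - t_i),\]

  with the estimated spurt age \(\hat a = (t_{i^\*}+t_{j^\*})/2\) and
  velocity \((s_{j^\*}-s_{i^\*})/(t_{j^\*}-t_{i^\*})\) in sizes/year.
* **Plateau detection** — cessation of foot growth: the earliest post-peak
  run of visits in which the size never exceeds the run's first value,
  lasting at least 1 year; growth resuming after the run is flagged.
* **Cohort summaries and lead times** — per-sex means/SDs with pooled
  totals, mean inter-visit interval, and the lead of the shoe-size spurt
  over reference sitting-height peak-growth-velocity ages (defaults
  11.7 y girls / 14.0 y boys), plus a cutoff-age sensitivity analysis.
* **A synthetic cohort generator** — seeded double-logistic growth curves
  observed on irregular visit schedules with half-size quantization, foot
  asymmetry and measurement noise, returning per-client ground truth
  (true peak-velocity age, adult size, cessation age) so the whole pipeline
  can be validated without access to retail data.

Everything is tibble-first: readers return tidy visit tables, each stage is
a verb, fitted analyses have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(footspurt)

sim <- simulate_cohort(generator_config(seed = 1))   # 242 girls + 104 boys
ana <- analyze_cohort(sim$cohort)
ana
#> Shoe-size growth-spurt analysis
#>   F: 161 of 242 clients selected (attrition 33%)
#>   M: 61 of 104 clients selected (attrition 41%)
#> ...
#> Lead time vs reference sitting-height PHV:
#>   F: peak shoe age 10.4, reference 11.7 -> lead 1.3 years
#>   M: peak shoe age 11.7, reference 14.0 -> lead 2.3 years
```

The girls' detected peak-increase age (10.4 y) reproduces the generator's
calibrated spurt timing, and its lead over the sitting-height reference
(1.3 y) is the clinically useful quantity: on average the shoe-size spurt
precedes the trunk spurt by that much. `glance(ana)` returns those numbers
as a one-row tibble; `tidy(ana)` gives the per-client windows and plateaus.

Robustness to the inclusion boundary, as a table:

```r
sensitivity_analysis(sim$cohort, "M", c(13, 14, 15))
#> # A tibble: 3 × 3
#>   cutoff n_selected mean_peak_age
#>    <dbl>      <int>         <dbl>
#> 1     13         61          11.7
#> 2     14         43          11.8
#> 3     15         26          11.6
```

Raising the boys' last-measurement cutoff shrinks the cohort but barely
moves the estimated spurt age — the estimate is not an artifact of who
clears the inclusion bar.

File-based use mirrors the in-memory verbs: `read_cohort()` /
`write_cohort()` for delimited visit tables (with a validation-issue log),
`run_pipeline()` for an end-to-end run that writes per-client results,
selection report, summary, sensitivity table and a seed-stamped
`run_info.json`. `convert_eu()` translates EU sizes to UK/US, and
`sizes_to_mm()` applies the Paris-point rule (one size = 20/3 mm).

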