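# accelcut

Intensity thresholds on raw tri-axial accelerometer data: compute the
**ENMO** and **MAD** metrics over 5-second epochs and derive
internally-validated cut-points that separate **sedentary behaviours**
(lying/sitting) from common **light-intensity physical activities**
(standing still, washing pots, dusting, sweeping, walking), per device
brand and wear site (hip/wrist).

The package is written for physical-activity and sedentary-behaviour
researchers who work with raw (non-count) accelerometry. It is
tidyverse-native: every user-facing function takes a data frame and
returns a tibble, fitted objects have `tidy()`/`glance()` methods, and
result types have `autoplot()` methods.

## The metrics and the analysis

With per-sample vector magnitude
$r_i = \sqrt{x_i^2 + y_i^2 + z_i^2}$ (mg, 1 g = 1000 mg), over an epoch
of $n = f_s \times 5$ samples:

* $\mathrm{ENMO} = \frac1n \sum_i \max(r_i - 1000,\ 0)$ — gravity is
  removed by subtracting a fixed 1 g, so the metric is sensitive to
  calibration error; recordings are auto-calibrated first by fitting
  per-axis gain/offset so that stationary-window magnitudes sit on the
  1000-mg gravity sphere.
* $\mathrm{MAD} = \frac1n \sum_i |r_i - \bar r|$ — the static component
  cancels in the deviation, so no calibration or filtering is needed.

Epochs are joined to an activity log; the first and last 30 s of each
activity are discarded (central 4 minutes kept). For each
discrimination "pooled sedentary (activities 1–11) vs one upright
activity", a univariate logistic regression is fitted, the
Youden-optimal threshold is read off the ROC curve, and performance is
summarised by the AUROC (DeLong 95% CI) plus a pooled
leave-one-out cross-validated AUROC. Brand differences are tested with
unpaired t-tests on per-participant means.

A synthetic-signal module generates 100 Hz cohorts with the structure
the analysis assumes (static gravity orientation per activity,
sinusoidal movement, brand-specific offset/noise), so the whole
pipeline is testable without laboratory data.

## Worked example

Simulate a 12-participant hip-worn cohort (both brands), summarise the
MAD metric by activity group, and derive thresholds:

```r
library(accelcut)
library(dplyr)

labeled <- simulate_labeled_cohort(n_participants = 12, seed = 2016,
                                   placements = "hip")
summarize_by_activity(filter(labeled, brand == "AG"), metric = "mad")
#> # A tibble: 6 × 4
#>   group                mean_mg   se_mg n_participants
#>   <chr>                  <dbl>   <dbl>          <int>
#> 1 sedentary behaviours    1.31  0.0123             12
#> 2 standing still          1.34  0.0372             12
#> 3 washing pots            8.23  0.622              12
#> 4 dusting                27.1   1.85               12
#> 5 sweeping floor         41.7   3.44               12
#> 6 self-paced walk       129.   12.0                12
```

Sedentary postures sit near the sensor noise floor (~1.3 mg MAD) while
the motion activities rise through washing pots to walking — the mean
(between-participant SE) layout of the classic descriptive tables.

```r
battery <- run_threshold_battery(labeled)
battery |>
  filter(metric == "mad", brand == "AG") |>
  select(discrimination, threshold_mg, sensitivity, specificity,
         auroc, loocv_auroc)
#> # A tibble: 5 × 6
#>   discrimination threshold_mg sensitivity specificity auroc loocv_auroc
#>   <chr>                 <dbl>       <dbl>       <dbl> <dbl>       <dbl>
#> 1 standing               1.29        0.75       0.530 0.580       0.402
#> 2 washing_pots           5.69        1          1     1           1
#> 3 dusting               19.7         1          1     1           1
#> 4 sweeping              22.2         1          1     1           1
#> 5 walk                  67.5         1          1     1           1
```

Each row is one threshold report: the mg cut-point, its
sensitivity/specificity on the data, the apparent AUROC and the
leave-one-out cross-validated AUROC. Motion activities separate
perfectly from the sedentary pool at participant-mean granularity,
while standing is indistinguishable (AUROC near 0.5, and the
cross-validated value degrades further) — magnitude metrics carry no
posture information, which is exactly the caveat this analysis
quantifies. `autoplot(battery)` draws the AUROC panel.

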