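---
title: "Deriving sedentary/light-activity cut-points from raw accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving sedentary/light-activity cut-points from raw accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcut)
```

## The problem

Modern tri-axial accelerometers record raw acceleration at up to 100 Hz
instead of proprietary "counts". Two simple metrics summarize the
movement intensity of such a signal over short epochs without any
filtering, because both remove the static 1-g gravity component
arithmetically:

* **ENMO** (Euclidean Norm Minus One): per sample,
  $e_i = r_i - 1000\ \mathrm{mg}$ with
  $r_i = \sqrt{x_i^2 + y_i^2 + z_i^2}$; negative values are rounded up
  to zero and the epoch value is the mean of the $e_i$.
* **MAD** (Mean Amplitude Deviation):
  $\tfrac1n \sum_i |r_i - \bar r|$, the mean absolute deviation of the
  vector magnitudes about their epoch mean.

Both are expressed in milligravity (mg; axes recorded in g are
multiplied by 1000 on read) and computed over 5-second epochs, i.e.
$n = f_s \times 5 = 500$ samples at 100 Hz.

Given a laboratory protocol in which participants wear four devices
(two brands x hip/wrist) through 11 sedentary postures and 5 upright
light-intensity activities, the package derives and internally
validates intensity thresholds that separate the pooled sedentary class
from each upright activity, and quantifies where such magnitude-based
separation must fail (standing still).

## Pipeline

1. **Ingest** (`read_raw_csv()`, `read_activity_log()`): two plain-text
   CSV dialects (timestamped `t,x,y,z`, or `x,y,z` rows under a
   `# fs_hz=` header). Proprietary binary device files are out of
   scope; they are exported to CSV upstream.
2. **Auto-calibration** (`calibrate_recording()`): ENMO subtracts a
   fixed 1000 mg, so a per-axis offset or gain error propagates
   directly into the metric. Windows of `window_s = 10` s whose
   per-axis SD is below `sd_threshold_mg = 13` mg are treated as
   stationary; per-axis gain and offset are then estimated so that the
   calibrated stationary means lie on the 1000-mg gravity sphere, by
   damped Gauss-Newton on
   $\sum_w (\lVert g \circ m_w + b\rVert - 1000)^2$ (convergence when
   the parameter change falls below 1e-9, at most 100 iterations).
   With fewer than `min_windows = 10` stationary windows, or when all
   window means lie within 30 degrees of one direction (the sphere is
   then unidentifiable along an axis), the identity calibration is
   returned with a flag rather than an extrapolated fit, and a fit is
   never accepted if it would worsen the residual. This is a
   deliberately simplified sphere calibration: it captures the
   functional role of the published auto-calibration stage (stationary
   magnitude of 1 g) without temperature covariates or claims of
   equivalence to any specific implementation.
3. **Metrics** (`compute_epoch_metrics()`): non-overlapping epochs
   anchored at the recording start; a trailing partial epoch is dropped
   (padding would bias MAD downward). No band-pass or other filtering
   is applied anywhere — avoiding filters is precisely the appeal of
   these metrics.
4. **Labeling** (`trim_and_label()`): the first and last `trim_s = 30`
   s of every logged activity are discarded as transitional movement,
   so a 5-minute activity contributes its central 4 minutes = 48
   epochs. An epoch is labeled only if it lies wholly inside the
   trimmed window.
5. **Inference** (`run_threshold_battery()`): per metric x brand x
   wear-site stratum and per discrimination (sedentary vs standing /
   washing pots / dusting / sweeping / walking): univariate logistic
   regression, ROC analysis on the raw metric values, the
   Youden-optimal threshold, AUROC with a DeLong 95% interval, and a
   pooled leave-one-out cross-validated AUROC. Brand contrasts of
   per-participant means use unpaired t-tests
   (`compare_brands()`, pooled-variance Student form by default,
   two-sided, alpha 0.05, no multiplicity correction).

## Decisions where the method was underdetermined

* **Observation granularity.** Nothing in the source analysis pins down
  whether the logistic/ROC observations are epochs or participant-level
  aggregates. The default is one observation per participant x
  activity (the mean over that activity's labeled epochs): 11 sedentary
  observations and 1 positive observation per participant per
  discrimination, consistent with descriptive tables whose standard
  errors are between-participant. `granularity = "epoch"` is available
  throughout; neither is asserted to be the original choice. This is
  the single most consequential ambiguity in reproducing the analysis.
* **ENMO truncation order.** "Negative values rounded up to zero"
  leaves open whether clamping precedes epoch averaging. Default:
  per-sample clamping then averaging (the convention of the common raw
  toolchain); `truncate_per_sample = FALSE` clamps the epoch mean
  instead. Both are exact in `compute_enmo()` and both are tested.
* **Calibration scope.** The published pipeline auto-calibrates before
  ENMO; whether MAD inputs were calibrated is unstated. Default: both
  (MAD is offset-free to first order, so this is harmless);
  `calibrate = FALSE` or computing MAD from the uncalibrated recording
  restricts it.
* **Epoch anchoring.** Epochs are anchored at the recording start.
  Under the protocol (5-min activities, 30-s breaks) every activity
  boundary is a multiple of 5 s, so labeled epochs never straddle an
  activity and anchoring at the trimmed activity start would give the
  identical 48 epochs. For logs that are not 5-s aligned, the
  wholly-inside rule simply drops the straddling boundary epochs.
* **"Optimal" threshold.** Youden's $J = $ sensitivity + specificity
  $- 1$, with ties broken by higher sensitivity and then by lower
  threshold; the classification rule is score >= threshold. If no
  threshold achieves $J > 0$ the scores are anti-discriminating and a
  warning is raised. No claim is made that the original study used
  Youden.
* **AUROC interval.** The Mann-Whitney pair-counting estimator (ties
  credited 0.5) with the DeLong variance and a normal interval clamped
  to [0, 1]. The original interval method is unstated; DeLong is the
  standard nonparametric choice.
* **LOOCV.** Leave-one-observation-out refits (n folds of n-1
  observations) cannot yield a per-fold AUROC from a single held-out
  point, so out-of-fold predicted probabilities are pooled and one
  AUROC is computed on the pooled set — the only reading under which a
  LOOCV AUROC exists. A training fold reduced to one class predicts its
  prevalence. `unit = "participant"` gives the subject-independent
  variant. One behaviour of this pooling is worth knowing: leaving a
  *positive* out lowers the training prevalence, so with a near-zero
  slope every held-out positive's predicted probability sits slightly
  below every held-out negative's. Ranks are scale-free, so under the
  null the pooled LOOCV AUROC is strongly *downward*-biased (it can
  collapse to 0 on a permuted-label draw) and near-null apparent
  AUROCs degrade sharply under LOOCV — the same depression visible in
  the published cross-validated values for the standing contrast. The
  optimism bound (cross-validated not exceeding apparent by more than
  a few points) is therefore a property of datasets with genuine
  signal, where the fitted slope's sign is stable; it is asserted in
  the tests for separations of at least 0.8 SD.
* **Separation.** With one predictor, complete separation is detected
  directly from the class ranges (and as a backstop from a diverging
  slope beyond 1e4 per mg or failure to reach gradient norm < 1e-8 in
  100 IRLS iterations); the fit then falls back to a ridge-stabilized
  refit (penalty 1e-6 on the standardized slope) and is flagged
  `converged = FALSE`. The fallback preserves ranking, which is all
  that the downstream ROC consumes.

## The synthetic cohort

Laboratory recordings cannot ship with the package, so `synth`
generates raw 100 Hz signals with the statistical structure the
analysis assumes. Per activity: a static device orientation carrying
the 1000-mg gravity vector; 2-4 sinusoids (0.8-3 Hz) whose directions
are the columns of one random orthonormal frame per activity instance,
scaled to a movement amplitude in mg; isotropic Gaussian sensor noise.
Device brands differ by additive offsets and extra noise only
(AG ~1.5 mg effective noise at the hip; GA adds ~10 mg, which
reproduces the higher low-intensity readings reported for that brand);
the two brands at a site observe the same latent movement. Log-normal
per-participant x activity random effects (sd 0.3 on the log scale)
spread the amplitudes between subjects.

Choices worth knowing about:

* The orthonormal movement frame makes the movement energy projected on
  gravity independent of the direction draw, so participant-level means
  are governed by the amplitude and the between-subject random effect —
  with the random effect disabled they become nearly equal, as a
  controlled generator should behave.
* All 11 sedentary postures and standing still share one near-zero
  movement amplitude. Vector-magnitude metrics carry no posture
  information, so an exchangeable standing model makes the standing
  discrimination an exact null — mirroring the laboratory finding that
  standing cannot be isolated from sitting/lying by intensity alone.
  Giving the typing/phone postures slightly larger amplitudes would be
  cosmetically realistic but would silently bias the standing null.
* The lying postures roll the device to both signs of the x/z axes
  (lying on the left vs right side). Orientation diversity is what
  makes the affine calibration identifiable; a protocol observing only
  one sign of an axis leaves a gain/offset trade-off along it.
* Motion-activity amplitudes (hip 19.5/86/109/350 mg, wrist
  292/250/518/448 mg for washing pots/dusting/sweeping/walk) were
  calibrated once against the published cohort mean MAD values per wear
  site, via the same one-dimensional search exposed as
  `fit_generator_to_targets()` (match within 15%). The wrist/hip
  amplitude ratio is therefore activity-specific (~2x for sweeping,
  ~15x for washing pots), as the published hip/wrist contrast implies.
  Base noise: hip 1.5 mg, wrist 8 mg. Device extra noise is an
  independent Gaussian component (not a sum of SDs): the cohort shares
  one latent true signal per site and each device adds its own sensor
  noise on top.
* What the generator does **not** emulate: biomechanical gait
  structure, posture transitions, autocorrelated or non-Gaussian sensor
  noise, temperature drift, frequency-response differences between
  brands, and idle-sleep artifacts. Passing the pipeline's validation
  studies on this cohort therefore demonstrates correctness of the
  computations and the qualitative signal/null contrast, not
  field-readiness of any specific threshold value.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:
the MAD/ENMO worked examples and 100-epoch brute-force comparisons
(1e-12 relative); 200-dataset brute-force AUROC comparisons and the
all-tied case; calibration parameter recovery over 50 seeded
simulations (median gain/offset error vs 0.005 and 2 mg); logistic
recovery at n = 2000 (within 3 SE) and the separation fallback; a full
33-participant synthetic cohort (16 activities, 100 Hz, four devices,
40 threshold reports) for the walk-vs-standing contrast; a 50-seed
standing null study at reduced size (8 participants, hip site,
3-minute activities — the null does not depend on cohort size, and
this keeps the study inside a few minutes of compute); and LOOCV
optimism/permutation checks. Type-I coverage and power of the DeLong
interval are checked over 200 replicates at the cohort's n = 33.

## Limitations

Thresholds derived from any laboratory protocol are sample- and
protocol-specific; the synthetic cohort inherits that caveat twice
over. The standing discrimination is unlearnable for magnitude metrics
by construction — posture separation needs orientation features, which
are out of scope here. The laboratory per-epoch workbook that would
allow recomputing the published tables directly is not redistributable
with the package; `read_epoch_table()` ingests any epoch-level table in
the documented schema once obtained.
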