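---
title: "Estimating dynamic effective connectivity from resting-state BOLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic effective connectivity from resting-state BOLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(dynconn)
library(dplyr)
```

## The model

`dynconn` estimates *dynamic effective connectivity* (DEC): time-resolved,
directed influences between brain regions, operationalized as the
coefficients of a vector autoregression whose coefficient matrices are
allowed to drift over time (a dynamic multivariate autoregressive model,
dMVAR). For standardized region signals $y_t \in \mathbb{R}^d$,

$$y_t = \sum_{k=1}^{p} A_k(t)\, y_{t-k} + e_t,
  \qquad e_t \sim N(0, R),$$

and the DEC of the directed connection from region $j$ to region $i$ at time
$t$ is $\sum_k A_k(t)[i, j]$. This is a filter-based, time-varying form of
Granger causality: past activity of a source region improves prediction of a
target region beyond the target's own past. A negative coefficient is read as
a putatively inhibitory directed influence, a positive one as excitatory.

Estimation casts the stacked, vectorized coefficient matrices as the latent
state $\theta_t$ of a linear-Gaussian state-space model with random-walk
dynamics, $\theta_t = \theta_{t-1} + w_t$ with $\mathrm{cov}(w) = c\,I$, and
runs the standard Kalman predict/update recursion; the observation matrix at
time $t$ is built from the $p$ most recent lagged observations. Only the
forward filter is run — no backward smoothing — so estimates at time $t$ use
data up to $t$ only, matching the filter-based tracking literature. A
smoother would reduce variance but is deliberately not the default.

Each subject's DEC trajectory is reduced to two dependent variables per
connection: the time **mean** (direction and magnitude of the influence) and
the time **SD** (its variability), computed with `summarize_dec()`.

## The pipeline

A full analysis (`run_pipeline()`) chains:

1. **Input**: synthetic cohort generation, a 4D NIfTI volume plus spherical
   seeds in MNI space, or per-subject region-by-time TSV matrices.
2. **Blind hemodynamic deconvolution** (`deconvolve_bold()`): the BOLD signal
   is the latent neural signal convolved with a hemodynamic response function
   (HRF), which varies across people and regions; deconvolving first removes
   that nuisance filter from the connectivity estimates.
3. **dMVAR estimation** (`fit_dmvar_kalman()`).
4. **Summaries and QC** (`summarize_dec()`, `compute_dvars()`,
   `flag_high_motion()`).
5. **Inference** (`mancova_pillai()`, `posthoc_group_regressions()`,
   `symptom_regression()`, `medication_interaction()`, plus the
   summary-statistics helpers).

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `order` ($p$) | `dmvar_config()` | 1 | VAR lag order; one coefficient per directed pair per time point. For $p>1$ DEC is the sum over lags. |
| `adaptation` ($c$) | `dmvar_config()` | 1e-3 | State-noise scale on standardized data. $c \to 0$ approaches the static least-squares VAR fit; larger $c$ tracks faster drift at the price of noisier trajectories. |
| `initial_state_variance` | `dmvar_config()` | 10 | Diffuse prior on each coefficient. |
| `burn_in` | `dmvar_config()` | max(50, 5%) | Samples dropped while the filter forgets its prior. |
| `innovation_memory` | `dmvar_config()` | 0.05 | Exponential-window weight of the recursive observation-noise estimate; avoids a second free noise parameter. |
| `threshold_k` | `deconvolve_bold()` | 1 SD | Pseudo-event threshold on the standardized signal. |
| `window` | `estimate_hrf()` | 0–24 s | Lag window of the fitted response. |
| `lambda` | `wiener_deconvolve()` | data-driven | Wiener regularizer; the default scales the high-frequency power of the observed series by the peak of $|H|^2$. |
| `radius` | `roi_set()` | 5 mm | Seed sphere radius. |

The lag order, adaptation constant and event threshold used in any given
published analysis are rarely reported; all are surfaced in configuration
objects and echoed into every result so a run is fully reproducible from its
artifacts.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture. It emulates a
two-group (patient/control) resting-state study with a known ground truth:

* every subject has a true coefficient on one **target directed connection**,
  drawn around a group mean; patients' mean differs from controls' by
  `group_dec_offset`;
* a YBOCS-like symptom score (0–40, clipped, clipping counted) is a linear
  function of the subject's true coefficient plus noise — so symptom-
  association analyses have a recoverable truth;
* covariates use plausible clinical marginals: age Normal(30, 10) truncated
  at 18 years, gender Bernoulli(0.5), motion (DVARS) LogNormal, medication
  Bernoulli within patients — all overridable;
* defaults mirror the study design the package targets: 43 patients vs 24
  controls, TR 2.0 s (a second regime at 0.72 s is exercised in tests).

Coefficient trajectories for the generator come in the three shapes a
tracking filter must handle — constant, sinusoidal, step — via
`coef_constant()`, `coef_sinusoid()` and `coef_step()`; every specification
is checked for stationarity (companion-matrix spectral radius < 1 at every
time index) before simulation.

What the generator does **not** emulate: full-brain physiology, structured
physiological noise (cardiac/respiratory), scanner drift and artifacts,
spatial autocorrelation beyond the embedded seed blobs, or non-Gaussian
innovations. Passing tests therefore demonstrate that the estimation and
inference chain is correct and calibrated under its own model assumptions —
not that those assumptions hold in any particular real dataset.

## Worked example

```{r example}
design <- cohort_design(n_patients = 12, n_controls = 10,
                        n_timepoints = 200, group_dec_offset = -0.25,
                        symptom_slope = 25, symptom_noise_sd = 3, seed = 7)
result <- run_pipeline(design = design)
result
result$stats$posthoc
```

The target connection's group coefficient is negative (patients lower than
controls, as configured) and the symptom regression recovers a positive
slope:

```{r example-symptom}
result$stats$symptom
```

```{r example-plot}
autoplot(result)
```

## Numerical choices

* **Standardization.** Region series are standardized (zero mean, unit
  variance) before filtering, so coefficients are dimensionless and
  invariant to the original units; `fit_dmvar_kalman()` enforces this with a
  warning.
* **Wiener edge handling.** The observed series is zero-padded to the full
  linear-convolution length before the FFT. Reflection padding was rejected:
  it makes the padded signal inconsistent with the convolution model, and the
  near-inverse filter amplifies that inconsistency where $|H(f)|$ is small —
  measurably so at TR 0.72 s, where the HRF attenuates high frequencies by
  orders of magnitude. The first and last HRF-length samples are still the
  least reliable and are trimmed in all round-trip comparisons.
* **Event detection** uses strict local maxima of the standardized series
  above `threshold_k`; a constant series yields no events rather than an
  error. Detection is invariant to affine rescaling by construction.
* **HRF estimation fallback.** Regions with fewer than 3 detected events
  fall back to the canonical double-gamma response; the fallback is recorded
  per region in the result.
* **Resampling** uses a zero-phase (forward–backward) Butterworth low-pass
  at 80% of the target Nyquist before spline interpolation on the new time
  grid, so downsampled series have no phase shift relative to the original.
* **Motion QC** flags subjects with DVARS strictly above the cohort mean
  plus two cohort SDs, computed once over the pooled dataset (no iterative
  re-thresholding). Note a quirk of this rule: a single extreme outlier
  inflates the SD enough that, in very small cohorts, it can escape its own
  threshold; the tests pin this behaviour explicitly.
* **MANCOVA** enters covariates before the group factor, so the group test
  is covariate-adjusted; Pillai's trace is converted to an exact F for a
  two-level factor (error df $n - \mathrm{rank}(X) - q + 1$, e.g. F(3, 60)
  at $n = 67$ with three covariates and three outcomes). The implementation
  is cross-checked against `stats::manova()` to 1e-10.
* **Pooled-variance t** (not Welch) is used for demographic comparisons and
  the gender test uses the Yates continuity correction — the combination
  that reproduces published clinical-table statistics with df $n_1+n_2-2$.
* **Effect-size interval.** The Cohen's d interval uses the normal
  approximation $d \pm 1.96\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$,
  which reproduces printed two-decimal intervals; correlation intervals use
  the Fisher $z$ transform.

## Design choices where the design was open

* **Connection list.** Eleven seed regions admit 110 ordered pairs; analyses
  in this literature report only a subset, and the published membership of
  intermediate-size sets is typically not enumerated. No fixed set is
  hard-coded: `dmvar_config(connections = ...)` takes any list,
  `analyzed_connections()` provides the seven named arbitration / habitual /
  goal-directed connections, and the default reports all ordered pairs.
* **Voxel inclusion** in a sphere is by voxel-center distance (inclusive),
  not partial-volume weighting — the simplest convention consistent with a
  stated radius; on a 2 mm grid a 5 mm sphere centered on a voxel center
  contains exactly 81 voxels.
* **Motion threshold reading.** "Two standard deviations of the mean" is
  read as mean + 2·SD of the cohort distribution (common practice), not
  2 standard errors.
* **Required sample size.** `required_n()` computes power exactly from the
  noncentral t distribution. At d = 0.74, one-sided α = 0.05 and 85% power
  with equal allocation it returns a total n of 54. Published power
  statements in this area sometimes print smaller values (e.g. 48) that are
  not reproducible under standard equal-allocation assumptions without
  knowing the software, allocation ratio and effect size actually used; the
  function documents its assumptions instead of matching any particular
  printed value.
* **Monte-Carlo problem sizes.** Calibration checks run 200 null cohorts at
  the summary level of the generator (observed connection means = subject
  truth + measurement noise) — the statistics layer is what those checks
  exercise, and this keeps a full calibration run in seconds. The complete
  series-level chain (generate → convolve → deconvolve → filter → summarize
  → test) is exercised end-to-end at the study's own sample sizes with a
  shorter series (T = 300 at TR 2 s, a 10-minute scan), and the static-limit
  oracle uses T = 5000.

## Known limitations

* The forward filter estimates lag coefficients at the sampling interval;
  comparing DEC across very different TRs compares slightly different
  quantities, mitigated but not removed by the anti-aliased resampling
  check.
* Blind deconvolution recovers the latent signal up to a small timing
  indeterminacy (the pseudo-event convention anchors the HRF peak, not its
  onset); a common shift across regions does not affect the VAR
  relationships, but region-specific shifts add noise.
* The recursive innovation-based estimate of the observation noise slightly
  overestimates $R$ (it includes coefficient-uncertainty variance); this
  biases the filter toward smoother trajectories and is absorbed in practice
  by the choice of the adaptation constant.
* With 110 possible connections and short resting-state series, per-subject
  DEC summaries are noisy; group-level inference is where the signal lives.
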