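---
title: "Diffusion-MRI tumor metrics and progression models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-MRI tumor metrics and progression models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In locally advanced head and neck squamous cell carcinoma (HNSCC), the
apparent diffusion coefficient (ADC) from diffusion-weighted MRI is a
candidate biomarker for stratifying progression risk during radiotherapy:
densely cellular tumor restricts water diffusion and depresses ADC, while
stroma, edema and necrosis raise it. `adcboost` implements a complete
analysis chain for two-b-value diffusion MRI of such tumors:

1. voxelwise ADC mapping from b = 50 and b = 800 s/mm² volumes;
2. histogram metrics in the gross tumor volume (GTV), including a
   two-Gaussian decomposition of the ADC distribution;
3. construction of a mid-treatment adaptive boost target from persisting
   low-perfusion and low-ADC subvolumes;
4. time-to-event modelling of progression with Cox interaction models,
   Kaplan–Meier splits and false-discovery-rate control.

Because patient imaging of this kind is not publicly distributable, the
package ships a synthetic-data module that generates phantoms and cohorts
with the statistical structure the analysis assumes, so every stage is
exercised end to end by the test suite without any download.

# ADC mapping

With exactly two diffusion weightings and monoexponential decay
$S(b) = S_0 e^{-b\,\mathrm{ADC}}$, the estimator is the closed form

$$\mathrm{ADC} = \frac{\ln(S_{50}/S_{800})}{800 - 50}\ \mathrm{mm^2/s},$$

converted once to µm²/ms (× 1000) inside `compute_adc()`; all downstream
thresholds are in µm²/ms. Using b = 50 rather than b = 0 as the lower
weighting suppresses the perfusion (pseudo-diffusion) contribution without
requiring an intravoxel-incoherent-motion model.

Degenerate voxels — non-positive signal at either b-value, or
$S_{800} > S_{50}$ (a negative ADC estimate, which happens under noise) —
are *marked invalid*, not clipped to zero. Clipping would pile spurious
mass into the low-ADC histogram tail that the downstream metrics analyze;
an explicit validity indicator keeps the estimator unbiased on the voxels
it does report.

`resample_to_grid()` reformats an ADC map onto the anatomical grid the
GTVs were contoured on, using trilinear interpolation through the two
affines; a target voxel is valid only when all contributing source voxels
are valid. Masks move by nearest neighbour. Deformable registration is out
of scope: inputs are assumed co-registered (patients are scanned in
immobilization devices), and the grid check (`check_same_grid`, tolerance
1 µm on affine entries by default) guards against silent geometry
mismatches.

# Histogram metrics

All metrics are computed after necrosis exclusion: voxels with
ADC ≥ 2.7 µm²/ms — 10% below free-water diffusivity (3.0 µm²/ms at body
temperature) — are removed from the analysis mask, since gross necrosis
and cysts carry no information about viable tumor. The comparison is
strictly below the ceiling, as is every threshold comparison in the
package.

Per tumor and timepoint, `tumor_metrics()` reports:

* **GTV volume** (cm³) of the contoured mask;
* **mean ADC** over the analysis mask;
* **TV_LADC** (cm³): the subvolume with ADC < 1.2 µm²/ms, read as the
  densely cellular burden;
* the **two-Gaussian decomposition** of the binned ADC histogram.

The histogram uses a fixed support [0, 2.7) with 27 bins of width
0.1 µm²/ms, left-closed right-open, so the bin scheme is identical across
tumors and group averaging (`group_average_histogram()`, each histogram
normalized to unit area before bin-wise averaging) is well defined.

## The bimodal decomposition

ADC distributions in these tumors are often bimodal — a low component L
(cellularity-dominated tissue) and a high component H (stroma/edema). The
model is a sum of two Gaussians in *counts*,

$$\hat n_b = A_L\, e^{-(c_b-\mu_L)^2/2\sigma_L^2}
           + A_H\, e^{-(c_b-\mu_H)^2/2\sigma_H^2},$$

fitted to the bin counts $n_b$ at bin centers $c_b$ by least squares with
a multi-start Nelder–Mead simplex (`stats::optim`). Starting points place
the means at the 25th/75th percentile of the in-mask distribution with
interquartile-derived widths; further restarts (default 8) jitter these
deterministically from the `seed` argument, and one restart duplicates the
best single-Gaussian solution so the two-component residual can never be
worse than the nested one-component fit. Components are relabelled after
fitting so $\mu_L \le \mu_H$; amplitude parameters are in counts because
the fit targets raw counts, which leaves $\mu$ and $\sigma$ unchanged
relative to a density-scaled fit. The fit is fully deterministic given
`(hist, restarts, seed)` and requires at least 50 voxels by default.

## When is a histogram "single-Gaussian-like"?

If a tumor's distribution is really unimodal, the convention is to refit a
single Gaussian and report it as both components with the amplitude split
50/50. "Single-Gaussian-like" needs an operational rule; the package
declares the decomposition unimodal when **any** of:

* **(a) separation**: $|\mu_H - \mu_L| < \max(\sigma_L, \sigma_H)$ — the
  peaks are not resolvable;
* **(b) amplitude**: $\min(A)/\max(A) < 0.05$ — the minor component is
  negligible;
* **(c) parsimony**: the single-Gaussian fit already explains the counts
  to within sampling noise, measured by its Pearson statistic
  $\sum_b (n_b - \hat n_b)^2 / \max(\hat n_b, 1) \le 3 \times \#\text{bins}$.

Rule (c) exists because least-squares decomposition is greedy: on $10^4$
draws from one Gaussian, the two-component fit reliably absorbs sampling
skew into a second component whose separation exceeds $\max\sigma$ and
whose amplitude ratio is far above 0.05, so (a) and (b) alone misclassify
clean unimodal data as bimodal. The Pearson statistic is the right scale
for this decision: for Poisson bin counts an adequate model scores on the
order of the number of bins, while a genuinely two-component histogram
scores orders of magnitude higher (measured at $n = 12{,}000$ voxels:
unimodal samples max ≈ 34, bimodal mixtures with peak separation ≥ 0.3
min ≈ 270, against a threshold of 81). All three constants are exposed in
`adc_defaults()`.

# The adaptive boost target

The trial logic implemented by `build_boost_target()`: a voxel is a boost
candidate when it is *persistently* abnormal from pre-treatment to the
20 Gy (week-2) scan — blood volume < 7.64 ml/100g at both timepoints, or
ADC < 1.2 µm²/ms at both timepoints. Persistence is the voxelwise
intersection on the co-registered grid; the boost target is the union of
the BV and ADC persisting subvolumes. If the union is smaller than
1.0 cm³ the patient is not boosted (observation arm). No morphological
cleanup is applied by default — the rule is pure set algebra, and the
implementation is tested against brute-force set operations. Which ROI
the union is taken over is the caller's choice; the pipeline defaults to
the union of all GTVs and records that choice in its report.

# Survival stage

`derive_endpoint()` turns a cohort table into cause-specific time-to-event
data for four endpoints: freedom from local (FFLP), locoregional (FFLRP),
distant (FFDP), and locoregional-or-distant (FFLRDP) progression. Time
runs from the start of radiotherapy; the event is the earliest targeted
progression; the record is censored at the earliest non-targeted
progression, death, or last follow-up. A targeted progression on the same
day as a censoring cause counts as an event — real cohorts contain
simultaneous failures (e.g. local and distant on one scan date), and
dropping them would discard exactly the high-risk patients the models are
about. Competing risks are handled by censoring, not by a Fine–Gray
model, matching the endpoint definitions above.

For the locally-targeted endpoints, `apply_boost_exclusion()` removes
boosted patients with no evidence of disease: their favorable outcome may
be a treatment effect rather than a marker effect, and retaining them
would confound the metric's predictive value. Boosted patients *with*
events stay; for FFDP everyone stays (no boost effect on distant control
is expected).

Metrics enter the Cox model dichotomized at the cohort median
(`dichotomize_at_median`, strict `>`, ties to the low group, median
computed after exclusions). The model uses group-specific metric slopes,

$$h(t) = h_0(t)\exp\big(\beta_1\,\mathrm{p16}
 + \beta_2\, m\,\mathbb{1}[\mathrm{LAHNSCC}]
 + \beta_3\, m\,\mathbb{1}[\mathrm{p16^{+}OPSCC}]\big),$$

so the reported contrasts are direct transforms: within-group hazard
ratios $e^{\beta_2}$ and $e^{\beta_3}$, the difference-in-effects
(interaction) $e^{\beta_3-\beta_2}$, and the p16 effect $e^{\beta_1}$,
each with Wald 95% CIs. Monotone likelihood (zero events in a stratum)
flags the result rather than silently reporting a diverged coefficient.
`fdr_adjust()` applies Benjamini–Hochberg within declared families — the
package's convention is one family per contrast type across endpoints, and
the grouping argument lets callers declare any other family structure.
Smoking status is deliberately not a covariate.

# The synthetic-data generator

`generate_dwi_pair()` emulates the acquisition the pipeline targets:
~1.2 × 1.2 × 4.8 mm voxels, b = 50/800 s/mm², ellipsoidal tumors whose
voxels draw true ADC from a two-Gaussian mixture (defaults
$\mu_L = 1.08$, $\mu_H = 1.67$ µm²/ms, $\sigma$ = 0.15/0.2, weight 0.5 —
typical pre-treatment values for locally advanced HNSCC), a necrosis
fraction at Uniform(2.7, 3.0), and background tissue at 0.8–1.1. Signals
follow $S = S_0 e^{-b\,\mathrm{ADC}}$ with optional additive Gaussian
noise. Noise is Gaussian rather than Rician: at the signal-to-noise
regimes used for testing the distinction is immaterial to the properties
under test, and a zero-noise setting keeps the two-point inversion exact,
which is what makes the closed-form recovery check meaningful. The
mixture is truncated (by rejection) to [0.2, 2.6] so tumor draws never
collide with the necrosis ceiling. `generate_longitudinal()` adds the
week-2 response — a systematic ADC increase (default +0.15 µm²/ms) plus
voxel jitter — and `generate_bv_pair()` supplies a deliberately simple
synthetic blood-volume field for exercising the boost rule; it is
plumbing, not a perfusion model.

`generate_cohort()` draws cohorts that satisfy proportional hazards *by
construction*: exponential baseline hazard times
$\exp(\beta_1 \mathrm{p16} + \beta_2 m \mathbb{1}[\mathrm{LAHNSCC}] +
\beta_3 m \mathbb{1}[\mathrm{OPSCC}])$ on the median-split indicator,
raced against exponential dropout and an administrative horizon. Default
group sizes (28/51) mirror the cohort composition this pipeline targets;
default effects ($\beta_2 = \ln 4$ within LAHNSCC, null within OPSCC,
p16 hazard ratio 0.3) are of the magnitude reported for low-ADC metrics
in such cohorts. Event types (local/regional/distant, with a 10% chance
of a same-day second type) make the output consumable by the full
endpoint-derivation path. Every generator is reproducible from its seed,
and truth tables carry the latent per-voxel ADC and per-patient event
times so downstream results are checkable without re-derivation.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: within-tumor spatial correlation (voxels are
i.i.d. given component membership), MRI artifacts (distortion, ghosting,
bias fields), Rician noise floors at low SNR, registration error between
timepoints, and non-proportional hazards. The tests validate the
estimators and rules under their stated assumptions; they are not a
clinical validation.

# Numerical choices and problem sizes

* Optimizer: Nelder–Mead, `reltol` 1e-12, up to 4000 iterations per
  restart; parameter-domain violations (σ ≤ 0, A < 0, µ outside
  [−0.5, 3.2]) are handled by graded penalties so the simplex recovers.
* Histogram fits are rated for ≥ 50 voxels (hard error below); the
  parameter-recovery checks run at ~10⁴ voxels per tumor, where the mean
  absolute error of recovered peak positions is ≈ 0.005–0.01 µm²/ms.
* Verification sizes, chosen to give stable Monte-Carlo estimates at
  interactive runtimes: 100 simulated tumors for mixture recovery, 200
  cohorts of n = 300 for Cox bias/coverage, a 3⁴ event-calendar grid for
  the censoring rule, all p-vectors of length ≤ 8 over a 3-point lattice
  for Benjamini–Hochberg.
* Ties: component relabelling orders by µ; median splits send ties to the
  low group; simultaneous failures count as events.
* Determinism: every stochastic routine takes a seed and uses a private
  RNG stream, so identical configurations produce byte-identical CSV
  outputs (`run_pipeline` is tested for this).

# Known limitations

* Only the two-b-value closed form is provided — no multi-b, IVIM or
  kurtosis fitting.
* The unimodality rule is an operationalization; clinical descriptions of
  "single Gaussian-like" histograms are qualitative, and the rule's
  constants, while config-exposed and well separated on synthetic data,
  have not been calibrated against expert reads.
* Blood-volume maps are consumed, never computed; the synthetic BV field
  is spatially unstructured.
* The Cox stage fits one metric at a time with p16 and its interaction,
  as the analysis design intends; it is not a general model-selection
  framework.
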