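# adcboost

Quantitative diffusion-MRI analysis for head and neck radiotherapy:
apparent diffusion coefficient (ADC) mapping from two b-value
diffusion-weighted volumes, gross-tumor-volume (GTV) histogram metrics
with a two-Gaussian decomposition, adaptive-radiotherapy boost-target
construction, and progression prediction with Cox interaction models.

## Who it is for

Imaging scientists and radiation oncology researchers analyzing
two-b-value diffusion MRI of locally advanced head and neck squamous cell
carcinoma (HNSCC) — in particular trials that adapt the radiation dose
mid-treatment based on persisting low-perfusion / low-ADC subvolumes, and
studies relating ADC histogram structure to progression risk in p16+
oropharyngeal vs other locally advanced tumors.

## What it computes

**ADC mapping.** With monoexponential decay S(b) = S₀·exp(−b·ADC), two
weightings give the closed form

    ADC = ln(S₅₀ / S₈₀₀) / (800 − 50)   [mm²/s → µm²/ms]

The b = 50 floor suppresses perfusion effects. Degenerate voxels are
flagged invalid, never clipped.

**Histogram metrics.** After excluding gross necrosis (ADC ≥ 2.7 µm²/ms,
10% below free water), each GTV yields its volume, mean ADC, the low-ADC
subvolume TV_LADC (ADC < 1.2 µm²/ms, in cm³), and a two-Gaussian fit of
the 0.1 µm²/ms-binned histogram,

    n(c) ≈ A_L·exp(−(c−µ_L)²/2σ_L²) + A_H·exp(−(c−µ_H)²/2σ_H²),

by multi-start Nelder–Mead least squares, with a 50/50 single-peak
convention when the histogram is single-Gaussian-like. Nodal tumors can
be pooled into a total-nodal metric set; histograms can be group-averaged.

**Boost target.** The union of subvolumes persisting from pre-RT to the
20 Gy scan — blood volume < 7.64 ml/100g at both timepoints or
ADC < 1.2 µm²/ms at both — with a 1 cm³ eligibility floor (smaller
targets route to observation).

**Survival stage.** Cause-specific endpoints (FFLP / FFLRP / FFDP /
FFLRDP) derived from an event calendar with censoring at non-targeted
progressions, death, or last follow-up; median-dichotomized metrics in a
Cox model h₀(t)·exp(β₁·p16 + β₂·m·1[LAHNSCC] + β₃·m·1[OPSCC]) reporting
within-group hazard ratios, the difference-in-effects e^(β₃−β₂), and the
p16 effect with Wald CIs; Benjamini–Hochberg FDR within declared
families; Kaplan–Meier median splits with log-rank tests; Kruskal–Wallis
subgroup comparisons.

**Synthetic data.** Reproducible phantoms (two-Gaussian tumor ADC
mixtures, necrosis component, signal decay, longitudinal ADC increase)
and cohorts with proportional hazards by construction, each with truth
tables, so the whole chain is testable without patient data.

## Worked example

```r
library(adcboost)

ph  <- generate_dwi_pair(phantom_spec(seed = 42))       # b=50/800 phantom
adc <- compute_adc(ph$dwi_low, ph$dwi_high)
adc
#> adc_map (preRT): 64x64x16, 65536/65536 valid voxels, range 0.616-2.999 um^2/ms

tumor_metrics(adc, ph$masks$primary, seed = 1)
#> tumor_metrics phantom/primary (preRT): GTV 17.16 cm^3, mean ADC 1.374, TV_LADC 6.48 cm^3
#> bimodal_fit: mu_L=1.089 (s=0.160, A=304.7), mu_H=1.679 (s=0.206, A=220.5), SSE=1314.7
```

The phantom planted µ_L = 1.08 and µ_H = 1.67 µm²/ms; the decomposition
recovers 1.089 and 1.679. TV_LADC is the cm³ of tumor below 1.2 µm²/ms —
the putative high-cellularity burden.

```r
wk2  <- generate_longitudinal(ph, wk2_shift = 0.15, seed = 2)
adc2 <- compute_adc(wk2$dwi_low, wk2$dwi_high)
gtv  <- ph$masks$primary
pers <- persisting_low_subvolume(adc, adc2, gtv, 1.2)
bv   <- generate_bv_pair(ph$grid, seed = 3)
bvp  <- persisting_low_subvolume(bv$bv_pre, bv$bv_wk2, gtv, 7.64)
build_boost_target(bvp, pers)
#> boost_target: 4.617 cm^3 -> eligible for 80 Gy boost (components: bv+adc)
```

4.617 cm³ of tumor stayed low-BV or low-ADC through 20 Gy — above the
1 cm³ floor, so this synthetic patient would receive the boost.

```r
coh <- generate_cohort(cohort_spec(seed = 7))           # 28 + 51 patients
d   <- derive_endpoint(apply_boost_exclusion(coh$cohort, "FFLRDP"), "FFLRDP")
d$split <- dichotomize_at_median(d$metric)
fit_cox_interaction(d, metric = "split")
#>               contrast               hr          p
#>                    p16 0.28 (0.09-0.87) 0.02807082
#>         metric_LAHNSCC 2.11 (0.86-5.17) 0.10201677
#>       metric_p16+OPSCC 0.36 (0.07-1.96) 0.23772749
#>  difference_in_effects 0.17 (0.02-1.16) 0.07100775
```

At this trial-sized cohort (n = 79) the planted within-LAHNSCC hazard
ratio of 4 is estimated at 2.11 with a CI crossing 1 — a realistic
picture of the power available at that size; the recovery properties are
verified on larger simulated cohorts (see below). `run_pipeline(out_dir)`
executes the whole chain and writes `metrics.csv`, `boost.json`,
`models.csv`, `km.csv` and a run log, byte-identically for identical
seeds.

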