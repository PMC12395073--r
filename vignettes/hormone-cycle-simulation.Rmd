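---
title: "Simulating multi-hormone menstrual-cycle dynamics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-hormone menstrual-cycle dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclesim)
```

## The model

`cyclesim` generates daily observations of seven reproductive hormones —
estradiol (E2, pg/mL), estrone (E1, pg/mL), LH and FSH (mIU/mL), AMH
(ng/mL), testosterone (ng/mL) and GnRH daily area (arbitrary units, AU) —
for virtual subjects of two phenotypes: eumenorrheic (normal ovulatory
cycles) and PCOS-like (anovulatory, hyperandrogenic, with
hypothalamic-pituitary-ovarian dysregulation).

The approach is semi-mechanistic: rather than integrating a differential
HPO-axis model, each hormone's noise-free trajectory is a parametric
Gaussian-bump curve whose parameters are sampled per subject (and partly per
cycle), with the key physiological couplings imposed as hard constraints on
the event timings:

* **Eumenorrheic E2** is biphasic:
  $E2(t) = E2_0 + A_1 e^{-(t-\mu_1)^2/2\sigma_1^2} + A_2 e^{-(t-\mu_2)^2/2\sigma_2^2}$,
  a narrow pre-ovulatory surge ($\sigma_1 \in [0.9, 1.3]$ d) and a broader
  luteal rise ($\sigma_2 \in [1.5, 2.5]$ d), with amplitudes defined relative
  to baseline ($A_1 = E2^{peak1} - E2_0$, $A_2 = E2^{peak2} - E2_0$).
* **LH** is a single sharp Gaussian surge (width 0.6–0.9 d). The E2→LH
  positive-feedback lag is encoded as $\mu_1 = t_{surge} - \Delta$ with
  $\Delta \sim U[1.5, 2.0]$ d (36–48 h), and the luteal E2 center as
  $\mu_2 = \mu_1 + \delta$, $\delta \sim U[5.5, 7.5]$ d.
* **FSH** is biphasic (an early-follicular bump at day 2 and a
  peri-ovulatory bump one day before the surge) with negative feedback:
  $-\beta_{E2}\max(E2_{true}(t) - \theta_{E2}, 0)$, $\theta_{E2} = 100$
  pg/mL. Feedback acts on the *noise-free* E2, so physiology drives
  physiology and the pipeline stays deterministic given the parameter draws.
* **GnRH daily area** is ~1 AU with a 22% peri-ovulatory bump centered one
  day before the surge. A minute-resolution Gaussian pulse-train variant
  (60–90 min interpulse intervals, numerically integrated per day) is
  implemented as a developer-facing alternative but is off by default; the
  daily-area bump is the model that feeds the dataset.
* **AMH** is a constant per-subject trait (ovarian reserve); **testosterone**
  is a low-amplitude sinusoid around its baseline.
* **PCOS-like** cycles are flat in E1, E2, LH, FSH and GnRH (chronic
  anovulation: elevated E1 80–150 pg/mL, low surge-free E2 10–60, LH 12–25
  constrained below the 30 mIU/mL surge threshold, suppressed FSH 4–8,
  GnRH tone > 1.3 AU), keep the testosterone sinusoid at a hyperandrogenic
  baseline (0.8–2.0 ng/mL), and carry a high AMH trait 4–8 ng/mL with a
  negative BMI slope: $AMH_i = \alpha_i + \beta_{BMI}(BMI_i - 25)$.

Observation runs on a fixed 28-point grid affinely rescaled to each cycle's
length ($t = 1 + \frac{d-1}{27}(L-1)$), so a 35-day cycle is still observed
28 times. Observations are truth plus Gaussian noise,
$Y(t) = Y_{true}(t) + \varepsilon(t)$, with time-dependent variance for E2
and LH only:
$\sigma^2(t) = \sigma_{base}^2\left(1 + \kappa e^{-(t-c)^2/(2\cdot 1.2^2)}\right)$,
centered on $\mu_1$ (E2) and the surge day (LH) — variability is highest
around ovulation. All other hormones use constant subject-level noise; AMH
carries none (trait-like).

## Two levels of truncation, two mechanisms

*Parameter-level* truncation (subject and cycle parameters) uses rejection
resampling: clipping would pile probability mass at the bounds and bias the
cohort summary statistics the simulation is calibrated to.
*Observation-level* truncation uses clipping to generous physiological caps
(e.g. E2 at 600 pg/mL, LH at 100 mIU/mL, everything floored at 0): clipping
preserves the record count and the noise law's center, and at default
parameters alters well under 1% of observations (the run manifest logs the
measured rate).

## Default study conditions

The default configuration reproduces the reference design: 500 eumenorrheic
and 50 PCOS-like subjects (~9% PCOS, the upper end of prevalence), 3
consecutive cycles each, 28 observation days per cycle — 550 subjects, 1,650
cycles, 46,200 daily records. Cycle lengths are truncated normal: EUM
28 ± 2 d on [24, 35]; PCOS 35 ± 6 d on [28, 60]. Age is uniform on [20, 45];
BMI is normal (EUM 24 ± 2.5, PCOS 28 ± 3.2 kg/m²).

Where the literature anchor gives only a range, widths and timing
parameters are uniform over that range. Level parameters with published
mean ± SD summaries are truncated normal, with centers/SDs chosen so the
*simulated observable* matches the published value; two of them deserve
comment:

* `e2_peak1` (pre-ovulatory E2 peak): published only as "≥ 200 pg/mL" with a
  simulated mean peak of 259 ± 28. Because the discrete grid rarely samples
  the continuous peak exactly (the observed per-cycle maximum understates
  the curve's peak — a property the test suite checks directly), the draw
  distribution is N(268, 28): the *observed* per-cycle maxima then average
  ≈ 260 with ≈ 98% of cycles reaching 200.
* `beta_bmi` defaults to −0.055 ng/mL per BMI unit. With BMI sd 3.2 and AMH
  intercept sd 0.58, the closed form
  $r = \beta\sigma_{BMI}/\sqrt{\beta^2\sigma_{BMI}^2 + \sigma_\alpha^2}$
  gives the intended AMH–BMI correlation ≈ −0.29. A slope of −0.5 (the other
  end of a range sometimes quoted) would push most PCOS AMH values out of
  the 4–8 ng/mL range and is not usable with these variances.

Choices that were genuinely open and fixed once: the mid-cycle surge center
is $L/2$ with 0.5 d Gaussian jitter per cycle; the peri-ovulatory phase is
±1 d around the surge (the surge *flag* additionally requires observed
LH ≥ 30 mIU/mL within ±0.5 d); the GnRH bump width is U[0.8, 1.2] d;
eumenorrheic estrone — not part of the physiological model, but needed so
the E1/E2 ratio feature is defined for all subjects — tracks noise-free E2
at a 0.7 ratio, giving a sharp phenotype contrast (≈ 0.7 vs ≫ 1 in PCOS).
EUM estrone observation noise is 4 pg/mL (not the PCOS 10) so clipping at 0
stays rare at the low EUM estrone level.

## Randomness and reproducibility

All randomness flows from one integer `master_seed`. Every subject gets two
derived substreams (parameters; observation noise) keyed by its cohort
index, so any subject's data are bit-reproducible independent of cohort
composition: enlarging the PCOS arm does not change subject 1's cycles.
Re-running with the same configuration yields byte-identical CSVs.

## Feature extraction and discrimination

Per subject, across all cycles: mean, sample SD and maximum of each hormone;
LH/FSH and E1/E2 ratios (ratios **of means**, stabler than means of daily
ratios); phase-day proportions; cycle-length mean and SD (a single cycle
reports SD 0 with a warning, keeping the matrix complete). Two presets
exist: `"pca6"` — the six per-subject mean levels (E2, FSH, LH, AMH,
testosterone, GnRH) — feeds PCA, k-means and the classifier by default;
`"full"` exports everything (constant columns such as the AMH daily SD are
dropped before standardization there).

The analysis pipeline standardizes features (transform fitted on the
training split only — the no-leakage property is tested), runs PCA (sign
convention: each component's largest-magnitude loading is positive, making
scores platform-stable), seeded k-means with 10 restarts (k = 2; the label
agreement is reported, never used for fitting), and a stratified 70/30
logistic evaluation with PCOS as the positive class. The logistic model is
ridge-regularized at a small fixed penalty ($\lambda = 10^{-3}$): the
synthetic classes are perfectly separable, where the unregularized MLE
diverges; the reported metrics, not the coefficients, are the contract.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(master_seed = 101)   # 500 EUM + 50 PCOS, 3 cycles
ds  <- simulate_cohort(cfg)
ds
#> Simulated hormone dataset: 46200 daily records (550 subjects x 3 cycles x 28 days)
#>   clip rate: 0.112%  |  EUM cycles with surge flag: 97.5%

an <- analyze_features(feature_table(ds), preset = "pca6", seed = 1)
an
#> Phenotype discrimination (preset 'pca6', seed 1)
#>   PCA: PC1+PC2 explain 83.6% of variance
#>   k-means (k = 2): label agreement 1.000
#> Stratified train/test logistic-regression evaluation
#>   train n = 385, test n = 165 (positive class: PCOS)
#>   accuracy = 1.000  sensitivity = 1.000  specificity = 1.000  AUC = 1.000
plot(an)   # PC1/PC2 scatter, phenotypes in color
```

## What the generator does and does not show

The test suite and the acceptance script measure the simulation against its
own design targets at the default study size (550 × 3 × 28; the AMH–BMI
correlation uses a 2,000-subject PCOS arm to tame sampling error in r).
Passing them shows internal consistency — the equations, sampling scheme and
pipeline do what they claim — not clinical validity. Real hormone series
carry features this generator deliberately omits: assay error structure and
missingness, progesterone and inhibin dynamics, coupled feedback (here the
couplings are timing constraints, not state dynamics), PCOS sub-phenotypes,
cycle-to-cycle autocorrelation beyond independent jitter, and temporal-shape
features (peak timing, rates of change) that the mean-level feature set
ignores. The perfect discrimination metrics are expected for strongly
separated synthetic classes and should be read as a pipeline check, not a
claim about clinical classification difficulty.

## Numerical notes

Truncated-normal rejection caps at 1,000 iterations and then errors
(misconfigured bounds), as does event placement inside short cycles
(`1 < mu1 < mu2 < L`). The pulse-train integrator uses a 1-minute trapezoid
rule over 24 h, calibrated so the default train integrates to ≈ 1 AU/day.
CSV round-trips preserve 6 significant digits. `standardize()` refuses
constant columns by name; `pca_project()` refuses more components than
features or subjects; k-means requires `2 ≤ k ≤ n`.
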