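---
title: "Terahertz spectroscopy of coagulating blood: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terahertz spectroscopy of coagulating blood: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzcoag)
library(dplyr)
```

## The measurement this package emulates and analyses

Transmission terahertz time-domain spectroscopy (THz-TDS) measures the
electric field of a sub-picosecond THz pulse as a function of optical delay.
Because the field — not just the intensity — is recorded, a Fourier
transform yields amplitude *and* phase, and a pair of measurements through
an empty and a liquid-filled cell determines the liquid's complex refractive
index $\bar n(\omega) = n(\omega) + i\kappa(\omega)$ and hence its power
absorption constant $\alpha = 2\omega\kappa/c$ (reported in cm$^{-1}$).

The application is blood coagulation. Blood is ~95 % water by plasma volume,
and sub-THz absorption of liquid water is governed by picosecond hydrogen-bond
and reorientation dynamics. When platelet activation starts the thrombotic
cascade, protein generation perturbs the solvation dynamics of the
surrounding water: absorption *decreases* below a characteristic frequency
(a "THz defect") and *increases* above it (a "THz excess"). The crossing
point — the **transparency frequency** $f_t$, where
$\Delta\alpha = \alpha_{\text{state}} - \alpha_{\text{blood}} = 0$ — shifts
red with increasing platelet count. The package provides three layers:

1. a **synthetic cohort generator** producing paired reference/sample time
   traces through a 100 µm polyethylene-windowed fluidic chamber, plus a
   hematology metadata table,
2. the **spectral inversion** recovering $n$, $\kappa$, $\alpha$ per subject,
3. the **cohort statistics**: pooled t-tests, Pearson correlations against
   hematology covariates, normalized change spectra
   $\Delta\alpha/\alpha_{\text{blood}}$, and platelet-stratified
   transparency-frequency estimation.

No clinical data ships with the package; the generator defines the study
conditions and every quantitative claim the tests make is about this
simulated pipeline, not about patients.

## Forward model

### Chamber transfer

For a channel of thickness $d$ between polyethylene (PE) windows of index
$n_{PE} = 1.5$, with Fresnel field transmissions
$T_{a\to b} = 2\bar n_a/(\bar n_a + \bar n_b)$ at normal incidence, the
transmitted fields are

$$E_{ref}(\omega) = E_s(\omega)\,T_{PE\to air}\,T_{air\to PE}\,
  e^{i\omega d/c}, \qquad
  E_{sam}(\omega) = E_s(\omega)\,T_{PE\to b}\,T_{b\to PE}\,
  e^{i\omega d n/c}\,e^{-\omega d \kappa/c}.$$

PE propagation and absorption are common to both arms and cancel in the
ratio. We use the ordered interface product $T_{PE\to air}T_{air\to PE}$ in
the reference arm; this is the only convention under which an air-"filled"
chamber is exactly indistinguishable from the empty chamber, which the
inversion relies on as its degenerate anchor case. The transfer is
single-pass; a first-order Fabry–Pérot echo term
$(1 + r^2 e^{2i\omega d\bar n/c})$ is available behind the `echo` flag to
emulate the residual etalon ripple of a thin cell (about a 600 GHz free
spectral range for model water; the echo is strongly damped by the blood's
absorption, of order $e^{-2}$ to $e^{-4}$, and is off by default).

### Water baseline

Blood enters the model as water with multiplicative perturbations of
$\kappa$. The water permittivity is a two-relaxation (double-Debye) model,

$$\varepsilon(\omega) = \varepsilon_\infty
 + \frac{\varepsilon_s - \varepsilon_1}{1 - i\omega\tau_s}
 + \frac{\varepsilon_1 - \varepsilon_\infty}{1 - i\omega\tau_f},$$

with literature room-temperature defaults $\varepsilon_s = 78.36$,
$\varepsilon_1 = 4.93$, $\varepsilon_\infty = 3.48$, $\tau_s = 8.24$ ps,
$\tau_f = 0.18$ ps, all overridable through `debye_water()`. The sign
convention is $\mathrm{Im}\,\varepsilon > 0$ for loss, consistent with the
propagation factor $e^{i\omega d\bar n/c}$ and $\kappa \ge 0$; note that a
Debye term written with $1 + i\omega\tau$ in the denominator belongs to the
opposite time convention and would make loss negative here.

```{r water}
complex_index(c(0.27, 0.35, 0.82))
```

### Coagulation effect model

The normalized absorption change is modelled as a line in frequency with a
platelet-dependent zero crossing:

$$\frac{\Delta\alpha}{\alpha_{\text{blood}}}(f)
  = s_\Delta\,\bigl(f - f_t(\mathrm{PLT})\bigr), \qquad
  f_t(\mathrm{PLT}) = f_{t,ref} + s_{PLT}\,
  \frac{\mathrm{PLT} - \mathrm{PLT}_{ref}}{50}.$$

Defaults: $f_{t,ref} = 0.9$ THz at $\mathrm{PLT}_{ref} = 175$ K/µL and
$s_{PLT} = -0.5\cdot 50/49$ THz per 50 K/µL, so that the crossing sits at
exactly 0.9 THz and 0.4 THz at the two platelet bin means (175 and
224 K/µL) used in the stratified analysis, and at ≈ 0.68 THz at the
cohort-mean platelet count. The thrombus state adds a small blue shift
(+0.05 THz) of $f_t$, producing a mild further reduction of low-frequency
absorption; $\Delta\alpha/\alpha$ slope $s_\Delta = 0.10$ per THz puts the
270 GHz thrombus-vs-uncoagulated group difference at ≈ 5.8 cm$^{-1}$
(within the 5–7 cm$^{-1}$ calibration window), given the water baseline
$\alpha(0.27\ \mathrm{THz}) \approx 126$ cm$^{-1}$.

Uncoagulated blood instead carries a red-blood-cell effect,
$\kappa = \kappa_w\,(1 + c_{RBC}(\mathrm{RBC} - 4.5))$, with
$c_{RBC} = 0.02$ per M/µL, and *no* platelet dependence; coagulated states
drop the RBC dependence, reflecting the empirical loss of RBC correlation
once the cascade starts. A per-subject log-normal scale on $\kappa$
(sdlog = 0.02) carries between-subject absorption variability;
$c_{RBC}$ and the sdlog were chosen jointly by the closed form so that the
RBC–$\alpha_{270}$ Pearson correlation is ≈ 0.4 at $n = 28$ uncoagulated
subjects. These two numbers are free calibrations: the effect directions
and crossing frequencies are anchored, the correlation strength is not.

Because the platelet slope is anchored at two points 0.5 THz apart, the
linear $f_t(\mathrm{PLT})$ extrapolates below the measured band for counts
above ≈ 263 K/µL. That is inherent to the calibration, not a failure of a
particular draw; the generator informs (not errors) when it happens and
rejects only parameterizations that would drive $\kappa \le 0$.

### Covariates and instrument

Hematology covariates are truncated normals: RBC ~ N(4.5, 0.45²) on
[3, 6] M/µL, WBC ~ N(7, 1.8²) K/µL, MCH ~ N(29.5, 2²) pg,
MCHC ~ N(33.5, 1²) g/dL, and PLT ~ N(196.6, 31²) on [100, 400] K/µL. The
platelet mean and spread are the one genuinely constrained pair: they make
the conditional means of the [100, 200) and [200, 300] K/µL bins ≈ 175 and
≈ 224 K/µL and put the cohort-mean transparency at ≈ 0.68 THz
simultaneously. Clotting times are uniform on [8, 21] min and are metadata
only (the measurement state is the group label). The default cohort carries
28 uncoagulated, 29 early-coagulated and 29 thrombus records as independent
subjects; in a real longitudinal study the early and thrombus spectra would
come from the same 29 people, a correlation structure this generator does
not reproduce.

The instrument records 512 delay samples at 0.05 ps (25.6 ps span,
Nyquist 10 THz), 120 traces per one-minute average. The source pulse is
specified spectrally as two smooth lobes $(\omega\tau/2)^2 e^{2-\omega\tau}$
— a main lobe peaking at 0.3 THz and a weak fast shoulder (relative
amplitude 0.4, peaking at 1.5 THz) that keeps usable signal out to the
3 THz band edge. Two modelling points deserve emphasis:

* The $\omega^2$ prefactor keeps the two-sided spectrum smooth through DC,
  so the pulse decays like $t^{-3}$ and genuinely fits the window; clean
  traces are rendered on an 8× oversampled grid and truncated, so the
  emitted 512 samples are samples of the continuous-time signal rather than
  one period of a circular one. Skipping either choice leaves
  discretization leakage of order $10^{-2}$ in the recovered constants —
  well above the inversion's own accuracy.
* Noise is white Gaussian in the delay domain, per trace, with RMS set by
  the peak dynamic range. The default is 54 dB: the instrument class is
  specified as "greater than 48 dB", and 48 dB exactly is too noisy at the
  band edges to reproduce the sub-percent water-fill repeatability the same
  instrument demonstrates over 0.1–1.2 THz, so the default adopts the
  smallest round value consistent with both facts. Repeatability
  (STD/AVG of $\alpha$ over repeated fills < 1 %) is the noise model's
  calibration check, not a fitted quantity.

One master seed drives the covariate draws; per-subject substream seeds
(drawn once from the master stream) drive trace noise, so any subject subset
regenerates reproducibly.

## Spectral inversion

Averaged traces are transformed with the convention
$E(\omega) = \sum_j E(t_j) e^{+i\omega t_j}$ (a pure delay gives phase
$+\omega\Delta t$, matching $e^{i\omega d n/c}$), rectangular window and 4×
zero-padding by default; traces are pulse-like and decay within the span,
so apodization is unnecessary (a Hann option exists). The analysis band
defaults to 0.13–1.02 THz.

From the ratio $R = E_{sam}/E_{ref}$ the closed-form first estimate is

$$\kappa_0 = -\frac{c}{2\omega d}\,\ln|R|^2, \qquad
  n_0 = \frac{c}{\omega d}\,\Delta\varphi + 1,$$

with the sign of $\kappa_0$ fixed so that attenuation gives
$\kappa \ge 0$ (the estimate is sometimes printed with the opposite sign,
which contradicts the $e^{-\omega d\kappa/c}$ attenuation convention).
$\Delta\varphi$ is unwrapped along frequency from the low band edge; the
$2\pi k$ branch is anchored at `phase_anchor` (default 0.13 THz) by
requiring a physically plausible index there. Branch spacing at 0.13 THz is
≈ 23 index units, so air ($n = 1$) and water-like liquids ($n \approx 2.5$)
unambiguously share the $k = 0$ branch.

The interface transmissions are then eliminated by per-frequency fixed
point: with $C_k = T_{PE\to b}T_{b\to PE}/(T_{PE\to air}T_{air\to PE})$
evaluated at $\bar n_k$,

$$\kappa_{k+1} = -\frac{c}{\omega d}\bigl(\ln|R| - \ln|C_k|\bigr), \qquad
  n_{k+1} = \frac{c}{\omega d}\bigl(\Delta\varphi - \arg C_k\bigr) + 1,$$

iterated until both $|n_{k+1}-n_k| < 10^{-3}$ and
$|\kappa_{k+1}-\kappa_k| < 10^{-3}$ (both-parameter, per-frequency reading
of the convergence rule), with a 100-iteration cap. $C$ depends only weakly
on $\bar n$, so the map is strongly contracting — water converges in ~10
iterations, and a tolerance of $10^{-6}$ still converges well within the
cap. Frequencies that exhaust the cap are reported as-is with
`converged = FALSE`, and oscillation is distinguished from slow convergence
in the warning. Degenerate inputs behave exactly: an identity ratio gives
$n = 1, \kappa = 0$ in ≤ 2 iterations, and a vanishing reference amplitude
flags the bin instead of propagating NaNs. A residual check,
`resynthesize_ratio()`, pushes the extracted constants back through the
forward model and compares with the measured ratio per frequency.

Reference and sample acquisitions are treated as drift-free pairs
(the reference is taken a minute before filling); instrument drift is out
of scope.

## Cohort statistics

* **Group comparisons** (`unpaired_ttest()`, `compare_groups()`): two-tailed
  two-sample t-test with the pooled equal-variance statistic — matching the
  default semantics of the classic `ttest2`-style function — plus the 95 %
  CI of the mean difference; a Welch option exists. Zero pooled variance
  follows the conventions p = 1 (equal means) / p = 0 flagged degenerate.
  Significance stars use the printed open bins (\*\*\* p < 0.001,
  \*\* 0.001 < p < 0.01, \* 0.01 < p < 0.05); a p-value exactly on a
  boundary takes the less significant label. No multiple-testing correction
  is applied across frequencies — comparisons are reported per frequency,
  and readers should treat the per-frequency p-values accordingly.
* **Correlations** (`pearson_correlation()`): Pearson r with the two-sided
  p from the t transform; a correlation is "declared" only below p = 0.05;
  zero-variance inputs are flagged undefined rather than returning NaN.
* **Filters** (`filter_subjects()`): RBC strictly above the lower bound and
  at or below the upper (the half-open "4 < RBC ≤ 5" convention as
  printed), platelets in the closed [100, 300] K/µL range.
* **Delta spectra** (`delta_spectrum()`): $\Delta\alpha/\alpha_{blood}$ per
  frequency, an unweighted least-squares line over the band, and
  $f_t = -\text{intercept}/\text{slope}$. The *fitted* crossing, not the
  nearest raw sign change, defines $f_t$: the raw curve carries etalon
  ripple and noise, and the linear trend is the model. Fits flatter than
  `min_slope` (default 0.005 per THz) leave $f_t$ undefined with a flag.
  Frequencies above/below the crossing are labelled excess/defect.
* **Stratification** (`plt_stratified_shift()`): platelet bins are
  left-closed right-open except the last (a boundary count belongs to the
  higher bin), each bin's mean spectrum is compared against the common
  uncoagulated mean, and the shift is $f_t(\text{high}) - f_t(\text{low})$
  (negative = red shift).

## Problem sizes and reproducibility

The test-suite and acceptance runs use sizes chosen to estimate each
quantity stably: single noiseless subjects for round-trip accuracy; three
simulated fills for repeatability; 10–20 replicate cohorts of the default
sizes (28 + 29, and 9 + 9 per platelet bin after filtering a 44-subject
early-coagulated draw) for the stochastic effect-recovery checks, with
across-replicate SDs defining the comparison tolerances; $10^4$ null
replicates for the t-test's type-I error. A full default cohort simulates
and inverts in a few seconds on one CPU. `run_pipeline()` stamps every
output with the config hash and seed, and identical configs produce
byte-identical outputs.

## What passing tests do and do not show

The generator reproduces the *statistical structure* the analysis assumes:
a water-dominated baseline, linear-in-frequency normalized change with a
platelet-dependent crossing, RBC dependence only before coagulation,
white instrument noise at a fixed dynamic range. Real blood measurements
additionally contain etalon ripple correlated across subjects, slow
instrument drift between reference and fill, cell scattering,
temperature dependence, non-Gaussian subject variability, and the
within-subject correlation of early and thrombus spectra. Passing the
recovery tests therefore demonstrates that the estimators faithfully
propagate the modelled effects at study-scale sample sizes — not that the
effects themselves hold clinically. Absolute absorption levels are anchored
only to the water model; treat them as model values, not ground truth.

Other known limitations: the inversion is single-pass (no transfer-matrix
treatment of higher-order echoes, so `echo = TRUE` data are inverted
slightly biased); uncertainty is carried only through repeat-measurement
spread, not propagated analytically; Debye-model fitting to extracted
spectra is deliberately out of scope.
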