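# thzcoag

Terahertz time-domain spectroscopy (THz-TDS) analysis of blood coagulation:
a simulation and analysis pipeline for transmission measurements of blood in
a thin (100 µm) polyethylene-windowed fluidic chamber.

Coherent THz-TDS records the transmitted electric field versus optical
delay; Fourier-transforming paired empty-chamber (reference) and
blood-filled (sample) traces yields the complex spectral ratio, from which
the blood's complex refractive index n̄(ω) = n(ω) + iκ(ω) and absorption
constant α = 2ωκ/c (cm⁻¹) follow. Because blood plasma is mostly water,
sub-THz absorption tracks picosecond water dynamics — and the
platelet-activated coagulation cascade perturbs them: absorption drops
below a **transparency frequency** f_t (where Δα = α_state − α_blood = 0,
"THz defect") and rises above it ("THz excess"), with f_t red-shifting as
platelet count increases. The package is written for spectroscopists and
biomedical statisticians who want to study that analysis chain end to end
on fully synthetic, seeded data.

It provides three layers, all tibble-in/tibble-out and pipe-friendly:

- **Synthetic cohort generator** (`cohort_config()`, `simulate_cohort()`):
  double-Debye water baseline, RBC-dependent absorption in uncoagulated
  blood, platelet-dependent linear Δα/α effect with a transparency crossing
  for early-coagulated and thrombus states, hematology covariates, a
  single-cycle source pulse, and white instrument noise at a configurable
  peak dynamic range; 120 traces per one-minute average.
- **Spectral inversion** (`to_spectrum()`, `initial_estimate()`,
  `refine_index()`, `extract_cohort()`): FFT with the +ωΔt delay
  convention, closed-form estimates
  κ₀ = −(c/2ωd)·ln|E_sam/E_ref|² and n₀ = Δφ·c/(ωd) + 1, then per-frequency
  fixed-point elimination of the Fresnel interface transmissions
  T_{a→b} = 2n̄_a/(n̄_a+n̄_b) until both n and κ change by less than 0.001.
- **Cohort statistics** (`compare_groups()`, `pearson_correlation()`,
  `filter_subjects()`, `delta_spectrum()`, `plt_stratified_shift()`):
  pooled two-sample t-tests with 95 % CIs and significance stars, Pearson
  correlations against hematology covariates, normalized change spectra
  with fitted transparency frequencies, and platelet-binned red-shift
  estimation. Results come with broom-style `tidy()`/`glance()` methods and
  `autoplot()` figures.

## Worked example

```r
library(thzcoag)
library(dplyr)

report <- run_pipeline(pipeline_config(seed = 42))
print(report)
#> <thz_report> n = 86 subjects ( early_coagulated=29, thrombus=29, uncoagulated=28 )
#>   transparency (early_coagulated): 0.627 THz
#>   transparency (thrombus): 0.827 THz
#>   PLT-bin transparency shift: -0.422 THz
```

The default cohort (28 uncoagulated controls; 29 early-coagulated and 29
thrombus measurement states) is simulated, inverted per subject, and
analysed. Thrombus absorption at low THz frequencies drops by 6–8 cm⁻¹
relative to uncoagulated blood:

```r
report$comparisons |>
  filter(group_a == "thrombus", freq_THz < 0.35) |>
  select(freq_THz, mean_a, mean_b, t_statistic, p_value, stars)
#> # A tibble: 3 × 6
#>   freq_THz mean_a mean_b t_statistic  p_value stars
#>      <dbl>  <dbl>  <dbl>       <dbl>    <dbl> <chr>
#> 1    0.195   105.   113.       -8.19 4.29e-11 ***
#> 2    0.273   120.   127.       -7.10 2.61e- 9 ***
#> 3    0.342   130.   137.       -6.31 5.06e- 8 ***
```

(`mean_a` is the thrombus group, `mean_b` uncoagulated, both in cm⁻¹; the
270 GHz difference here is 7.0 cm⁻¹ with p ≈ 3·10⁻⁹.) The early-coagulated
normalized change spectrum is linear in frequency and crosses zero near
0.65 THz for this seed:

```r
glance(report$deltas$early_coagulated)
#> # A tibble: 1 × 6
#>   transparency_freq fit_slope fit_intercept r_squared n_freqs flat
#>               <dbl>     <dbl>         <dbl>     <dbl>   <int> <lgl>
#> 1             0.627    0.0995       -0.0624     1.000      91 FALSE
```

and the covariate correlations reproduce the coagulation phenomenology —
RBC count correlates with 270 GHz absorption only *before* coagulation,
platelet count only *after*:

```r
report$correlations |> filter(group != "early_coagulated")
#> # A tibble: 4 × 10
#>   group        filtered freq_THz covariate       r  p_value     n stars significant
#> 1 uncoagulated FALSE       0.273 rbc        0.451  1.61e-2    28 *     TRUE
#> 2 uncoagulated TRUE        0.273 plt        0.275  3.21e-1    15 ns    FALSE
#> 3 thrombus     FALSE       0.273 rbc       -0.0724 7.09e-1    29 ns    FALSE
#> 4 thrombus     TRUE        0.273 plt        0.841  2.67e-7    24 ***   TRUE
```

`run_pipeline(config, out_dir = "out")` additionally writes the metadata
CSV, per-subject spectra CSVs, comparison/correlation/delta tables and a
`summary.json`, all stamped with the config hash; identical config and seed
give byte-identical outputs. A thin command-line wrapper with
`simulate` / `extract` / `analyze` / `report` subcommands lives in
`inst/scripts/thz-pipeline.R`.

## Method details

See the methods vignette (`vignettes/thzcoag-methods.Rmd`) for the forward
model and its assumptions, the calibration of every generator default, the
inversion's numerical choices (phase unwrapping and anchoring, convergence
rules, degenerate cases), the statistical conventions, and what the
synthetic study does and does not demonstrate about real blood.
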