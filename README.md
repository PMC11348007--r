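# aperiodic

Estimation and inference for the aperiodic (1/f) component of EEG power
spectra, built for within-subject pharmaco-EEG designs.

Event-related EEG spectra mix broadband "aperiodic" activity with narrowband
oscillations. The aperiodic exponent — the negative slope of the spectrum in
log–log space — is a compact index of cortical noise: steeper spectra
(higher exponent) indicate less noisy, more persistent cortical dynamics.
This package provides the full analysis chain needed to ask whether
experimental conditions (e.g. a stimulant vs placebo session, pre- vs
within-trial analysis windows, conflict-task congruency) shift that
exponent:

- **Welch PSD estimation** (`welch_psd()`, `condition_psd()`): 0.25-s
  Hamming segments, 50% overlap, correct-trials-only pooling per
  participant × electrode × condition × period.
- **Spectral parameterization** (`fit_spectrum()`, `fit_spectra()`): a
  from-scratch implementation of the iterative aperiodic + Gaussian-peaks
  decomposition,

  log10 PSD(f) = b − x·log10(f) + Σₙ aₙ·exp(−(f−μₙ)²/(2σₙ²)),

  fit over 3–35 Hz in fixed mode with peak width limits [2, 8] Hz, at most
  8 peaks, and minimum peak height 0.05 — returning offset `b`, exponent
  `x`, peak parameters, R² and error per spectrum.
- **Inference** (`rm_anova()`, `follow_up_anovas()`,
  `cluster_permutation_test()`, `electrodewise_condition_tests()`): fully
  within-subject 2×2×2×2 ANOVA on brain-wide exponents, and
  electrode-space cluster-based permutation tests (sample threshold
  α = .005 for F, 1000 sign-flip permutations, max-cluster-mass
  family-wise error control at .05) on a configurable montage adjacency.
- **Synthetic ground truth** (`generate_design()`, `synth_spectrum()`,
  `synth_epochs()`, `synth_spectra()`): a generator emulating a 25-subject,
  two-session, 384-trial prime–flanker experiment with injected exponent
  effects, so every stage is testable end to end without raw recordings.
- **Orchestration** (`run_config()`, `run_pipeline()`): seeded, resumable,
  bit-reproducible runs with TSV/JSON/YAML provenance and a markdown
  report.

Results are tibbles or small S3 objects with broom-style `tidy()` /
`glance()` methods and `autoplot()` figures.

## Worked example

Fit one synthetic spectrum with known truth (offset 1, exponent 2, one
alpha peak at 10 Hz) and realistic noise:

```r
library(aperiodic)

sp <- synth_spectrum(1:45, aperiodic = c(1, 2),
                     peaks = list(c(10, 0.5, 2)), noise_sd = 0.05, seed = 3)
fit <- fit_spectrum(sp)
fit
#> <spectral_fit> offset 0.986, exponent 1.990, 1 peak(s), R^2 0.9961, MAE 0.0342
#> # A tibble: 1 × 3
#>   center amplitude bandwidth
#>    <dbl>     <dbl>     <dbl>
#> 1   9.89     0.502      1.92
```

The estimated exponent (1.990) and offset (0.986) recover the generating
values to ~0.01 despite the noise, and the alpha peak is found at 9.9 Hz
with its injected height; R² = 0.996 says the two-component model accounts
for essentially all structure in the log spectrum.

Run the pipeline end to end on a small synthetic study (8 participants,
4 electrodes, spectrum-level generation) and inspect the brain-wide ANOVA:

```r
cfg <- run_config(seed = 1, design = task_design(n_participants = 8),
                  n_electrodes = 4, freqs = 3:35,
                  stats = list(run_cluster = FALSE))
rep <- run_pipeline(cfg)
dplyr::filter(tidy(rep$anova), effect %in% c("drug", "period", "prime", "flanker"))
#> # A tibble: 4 × 7
#>   effect  estimate       F   df1   df2        p partial_eta_sq
#>   <chr>      <dbl>   <dbl> <dbl> <dbl>    <dbl>          <dbl>
#> 1 period   0.146   1791.       1     7 1.07e- 9          0.996
#> 2 drug     0.129   2419.       1     7 3.76e-10          0.997
#> 3 prime    0.00902    9.93     1     7 1.61e- 2          0.587
#> 4 flanker  0.00652    2.46     1     7 1.61e- 1          0.260
```

The injected drug effect (+0.129: higher exponent under MPH) is recovered
exactly in the marginal contrast (`estimate`), and both the drug and period
main effects are highly significant. The period estimate (0.146) exceeds
the injected +0.124 because the within-trial-only congruency effects fold
into the within-trial marginal mean — exactly as they would in the real
design. `rep$truth_comparison` tabulates injected vs recovered effects, and
`rep$condition_means` holds the 16 condition means ± SEM.

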