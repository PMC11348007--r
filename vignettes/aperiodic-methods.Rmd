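---
title: "Methods: aperiodic spectral parameterization and electrode-cluster inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aperiodic spectral parameterization and electrode-cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aperiodic)
```

## The model

The package treats a power spectral density in log space as the sum of an
aperiodic component and a small number of oscillatory peaks:

$$\log_{10} \mathrm{PSD}(f) \;=\; \underbrace{b - x \,\log_{10} f}_{L(f)}
\;+\; \sum_{n} a_n \exp\!\left(-\frac{(f - \mu_n)^2}{2\sigma_n^2}\right)$$

Here $b$ is the aperiodic *offset* (broadband shift, log10-power units) and
$x$ the aperiodic *exponent* — the negative slope of the spectrum in
log–log space. In the cortical-noise framework, a steeper spectrum (higher
$x$) indexes less "neural noise", i.e. a more persistent processing regime;
a flatter spectrum indexes a noisier, more flexible regime. Each peak is a
Gaussian in *linear* frequency with amplitude $a_n$ (log10-power above the
aperiodic component), center $\mu_n$ (Hz) and SD bandwidth $\sigma_n$ (Hz).
All logarithms in the package are base 10, which is what makes the "slope in
log–log space" reading of $x$ exact.

The scientific question the pipeline answers is whether experimental
conditions — in the emulated study, a drug session (methylphenidate, MPH, vs
placebo), an analysis period (pre-trial −1200..−200 ms vs within-trial
0..1000 ms relative to target onset), and prime/flanker congruency — shift
the exponent, brain-wide and locally over electrodes.

## Fitting algorithm

`fit_spectrum()` re-implements the standard iterative decomposition:

1. trim the spectrum to the fit range (default 3–35 Hz) and take log10;
2. **robust aperiodic fit**: an OLS line in log–log space, then a refit
   restricted to bins whose positive residual does not exceed the
   `ap_percentile` (0.025th) quantile of positive-clipped residuals — in
   practice, the bins at or below the initial line. This removes the upward
   bias oscillatory bumps would otherwise impose on the slope. Because the
   fixed (knee-free) aperiodic model is linear in $(b, x)$, both fits are
   closed-form least squares; no iterative optimizer or starting point is
   involved;
3. **peak extraction** on the flattened spectrum: repeatedly take the
   maximum residual; stop when it falls below `peak_threshold` (2.0) SDs of
   the current residual or below `min_peak_height` (0.05); seed a Gaussian
   with a half-height width heuristic clipped to the width limits
   (default [2, 8] Hz, i.e. SD limits [1, 4] Hz); subtract and repeat up to
   `max_n_peaks` (8) times. Candidates whose center lies within one SD of a
   range edge are dropped, as is the smaller of two candidates whose
   0.75-bandwidth neighborhoods overlap. Survivors are refined jointly by
   bounded least squares (L-BFGS-B with an analytic gradient; amplitude
   ≥ 0, SD within limits, center within ±3 seeded SDs clipped to the range);
4. subtract the peak model from the original log spectrum and refit the
   aperiodic line by plain OLS on the peak-removed spectrum (this final
   simple refit, rather than a second robust pass, mirrors the reference
   implementation of the algorithm);
5. report $R^2$ (squared Pearson correlation between observed and modeled
   log10 power on the fit grid) and the mean absolute error. Ties in step 3
   resolve to the lowest frequency (`which.max`), so fits are deterministic.

Degenerate spectra with ≤ 3 in-range bins refuse the peak stage and return a
flagged aperiodic-only fit — an 8-peak model on 3 points is meaningless.

**A caveat on spurious small peaks.** With `min_peak_height = 0.05` and
bin noise of the same magnitude, the relative 2-SD detection rule admits the
maximum of ~33 noise residuals in most spectra, so small spurious peaks are
common on noisy peak-free input. This is inherent to the algorithm at these
settings, not an implementation artifact; it leaves the exponent essentially
unbiased (median absolute exponent error ≈ 0.03 over the recovery grid, see
the test suite), which is why exponent-focused analyses tolerate it. Peak
*counts* at realistic noise should therefore not be over-interpreted.

## Welch spectra

`welch_psd()` averages modified periodograms of 0.25-s Hamming-tapered
segments with 50% overlap (7 segments per 1000-ms epoch at 256 Hz), scaled
as a one-sided density so white noise of variance $\sigma^2$ integrates to
$\sigma^2$. Two choices the convention leaves open are exposed in
`welch_settings()`:

- **`n_fft`**: a 64-sample segment natively yields 4-Hz resolution — only
  ~8 bins across 3–35 Hz, which under-determines an 8-peak model. The
  default policy zero-pads to `max(256, segment samples)`, giving the 1-Hz
  grid (33 bins in range) that common Welch implementations produce by
  default.
- **`detrend`**: per-segment mean removal (default `"constant"`), preventing
  DC leakage into the lowest fit bins; `"none"` reproduces implementations
  that skip detrending.

`condition_psd()` pools segments across all *correct* trials of each
electrode × condition × period cell before averaging — identical in
expectation to averaging per-trial spectra, exactly equal when every trial
contributes the same number of segments (tested), and with simpler variance
bookkeeping. Cells with no correct trials are reported as explicitly
missing, never as silent NaNs, and missingness propagates (missing cells are
excluded from brain-wide means with counts reported, and abort the ANOVA,
which requires complete cells).

## The synthetic study

The generator emulates a two-session pharmaco-EEG experiment: 25
participants × 2 drug sessions × 384 trials in 4 blocks, the four
prime × flanker congruency conditions equally frequent and randomized
within block, 60 electrodes at 256 Hz, analyzed in pre-trial and
within-trial windows.

Ground truth (`ground_truth()`): every cell's exponent is
`base (3.40) + subject effect (SD 0.20) + condition effects`. Default
condition effects derive from the printed brain-wide condition means of the
motivating study — drug +0.129 (3.528 − 3.399), period +0.124
(3.525 − 3.401) — plus small within-trial-only congruency effects (+0.026
prime, +0.02 flanker) taken from its within-trial contrasts. They are
configuration, not constants. The default `base_offset = 2.0` log10(µV²/Hz)
and a single alpha peak (10 Hz, 0.6, SD 1.5 Hz) give band powers in the
range typical of cleaned scalp EEG. Note that the *marginal* period
contrast in a default run is ≈ 0.147, not 0.124: the within-trial-only
congruency effects fold into the within-trial marginal mean, exactly as
they would in the real design.

Two generation modes:

- **Fast (spectrum-level)**, `synth_spectra()`: evaluates the model per cell
  and adds i.i.d. log10-power noise (`noise_sd`, default 0.05), emulating
  the averaged PSD of a cell's correct trials. This is the mode used for
  large simulation studies.
- **Time-domain**, `synth_epochs()`: white Gaussian noise shaped in the
  frequency domain (amplitude ∝ $f^{-x/2}$, randomized phases, zero DC), so
  the expected PSD follows the target power law *exactly* on the epoch's
  native 1-Hz grid. Oscillations are added as amplitude-modulated sinusoids
  whose center frequency jitters across trials by the peak bandwidth,
  yielding Gaussian-like bumps in the averaged PSD without disturbing the
  controlled aperiodic slope.

**Estimator bias at steep slopes.** The spectral-fidelity checks regress
log10 PSD on log10 frequency using full-window (1-s) segments, where
generated epochs recover requested exponents {0, 1, 2, 3.5} within ±0.1.
With 0.25-s segments the 64-sample Hamming mainlobe spans ±8 Hz, and for
steep spectra ($x \gtrsim 3$) power below 3 Hz smears into the lowest fit
bins, inflating the measured slope by up to ~+0.3 at $x = 3.5$. This is a
property of the short-segment estimator applied to *any* steep spectrum,
not of the generator; condition *differences* (the inferential quantity)
are only mildly amplified and their signs preserved.

What the generator does **not** emulate: ERP waveforms and evoked
transients, volume conduction / spatial correlation between electrodes,
artifacts, non-stationarity within a session, or knee-shaped spectra.
Passing tests therefore validate the estimator and inference chain, not the
physiological realism of any particular dataset.

## Inference

**ANOVA.** With all factors at two within-subject levels, every effect of
the 2×2×2×2 design has one numerator df and reduces to a paired t test on
per-subject contrast scores; `rm_anova()` computes $F = (\bar L / SE)^2$
with df (1, n−1), $p$ from the F distribution and partial
$\eta^2 = F/(F + df_2)$. Agreement with `aov()` error strata is verified to
1e-9 in the tests. Because every effect has 1 numerator df, the
Greenhouse–Geisser correction is an identity and is intentionally not
implemented for >2-level factors (out of scope). `follow_up_anovas()`
splits by a factor (typically period) and Bonferroni-corrects by the number
of levels.

**Cluster-based permutation test.** `cluster_permutation_test()` thresholds
electrode-level statistics (F with sample α = .005, or two-sided paired t
with α = .05), groups suprathreshold electrodes into connected clusters on
the montage adjacency (by sign for t), scores each cluster by the sum of
its statistics, and compares observed masses against the permutation
distribution of the *maximum* cluster mass obtained by flipping the sign of
whole subjects' difference vectors — the exact exchangeability operation
under the paired null, and the standard max-statistic construction for
family-wise error control. $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(1 + n_{perm})$, so the observed labeling is always included, $p$ is never
zero, and ties count conservatively. Under a simulated global null the
family-wise false-positive rate is ≈ 0.034–0.037 (2000 replicates), i.e.
at or conservatively below the nominal .05 — the discreteness of the
threshold-then-cluster construction makes the test slightly conservative
rather than anti-conservative.

**Adjacency.** The montage is a synthetic equidistant cap: a sunflower
(Fermat spiral) arrangement on the unit disk, with electrodes declared
neighbors within 1.5× the median nearest-neighbor distance — the standard
distance-threshold construction for sensor neighborhoods. The default
60-channel graph is connected with typical degree 4–6. An explicit edge
list can be supplied instead; disconnected graphs are flagged with their
components, since clusters cannot span components.

## Numerical and design choices

- Seeds: every stochastic routine takes an explicit seed; stage seeds are
  derived deterministically from the run seed with a string-keyed hash, so
  stages never share a stream and runs are bit-reproducible (tested via
  file-level identity of rerun outputs).
- The robust-refit quantile is applied to positive-clipped residuals with
  type-7 quantiles; at the default 0.025th percentile this keeps exactly
  the bins at or below the initial line whenever ≥ 0.025% of bins lie
  below it (always, in practice).
- Peak refinement failure (singular curvature) falls back to the seeded
  Gaussian parameters rather than erroring; peaks are reported sorted by
  center frequency.
- `fit_spectrum()` errors on nonpositive in-range power, naming the
  offending frequencies, rather than producing NaNs downstream.
- Exponent tables, fits, ANOVA and cluster summaries serialize to TSV with
  17 significant digits and round-trip bit-identically; epochs serialize as
  little-endian doubles plus a JSON sidecar and TSV trial table.

## Validation study sizes

The package's validation studies (test suite and `scripts/acceptance.R`)
use: 1000 spectra for the fit-quality ensemble (mean $R^2$ ≈ 0.97,
threshold 0.94); 2000 replicates × 1000 permutations for the cluster-test
FWER study; 20 seeded end-to-end runs (fast mode, 25 participants,
4 electrodes, 3–35 Hz grid) for effect recovery, where both the drug and
period main effects must be significant with the correct sign — with the
default effect sizes and noise this succeeds in 20/20 runs, since
within-subject contrasts cancel the large between-subject variance. The
4-electrode montage in the recovery runs is a deliberate reduction: the
brain-wide ANOVA averages across however many electrodes are simulated, and
its operating characteristics do not depend on the montage size.

## Limitations

- Only the fixed (knee-free) aperiodic mode is supported; spectra with a
  visible knee will bias the exponent.
- Clusters are over electrodes only (no time–frequency clustering), and the
  adjacency is synthetic unless a real montage's positions or edges are
  supplied.
- The offset and peak parameters are estimated but not analyzed
  inferentially; the pipeline's statistics target the exponent.
- Fast-mode spectra have independent noise across cells; real cell PSDs
  share trials across periods and electrodes and are spatially correlated.
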