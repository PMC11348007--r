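#' Ground-truth parameters for synthetic spectra and epochs
#'
#' Defines the generative model for the synthetic study: every cell of the
#' design has a true aperiodic exponent
#' `base_exponent + subject effect + condition effects`, where condition
#' effects are an MPH shift (`effect_drug`), a within-trial shift
#' (`effect_period`), and prime/flanker-incongruency shifts that apply to the
#' within-trial period only. Subject effects are drawn once per participant
#' from `N(0, subject_sd_exponent)`. Narrowband oscillatory activity is
#' described by Gaussian peaks on the log10-power spectrum.
#'
#' Default effect sizes are taken from the brain-wide condition means of the
#' motivating pharmaco-EEG study (MPH 3.528 vs placebo 3.399; within-trial
#' 3.525 vs pre-trial 3.401); they are configuration, not constants.
#'
#' @param base_offset Aperiodic offset `b`, log10(uV^2/Hz) at 1 Hz.
#' @param base_exponent Baseline aperiodic exponent (default 3.40).
#' @param subject_sd_exponent SD of the participant random effect on the
#'   exponent (default 0.20).
#' @param effect_drug Exponent shift under MPH (default +0.129).
#' @param effect_period Exponent shift in the within-trial period (default +0.124).
#' @param effect_prime Within-trial-only shift for prime-incongruent trials
#'   (default +0.026).
#' @param effect_flanker Within-trial-only shift for flanker-incongruent
#'   trials (default +0.02).
#' @param peaks Oscillatory peaks: a list of `c(center, amplitude, bandwidth)`
#'   triplets (Hz, log10-power, Hz Gaussian SD). Default: one alpha peak at
#'   10 Hz, height 0.6, SD 1.5.
#' @param noise_sd SD of i.i.d. log10-power measurement noise added to each
#'   frequency bin of a generated spectrum (default 0.05).
#' @param spatial_effect_map Optional per-electrode multiplier (numeric
#'   vector) applied to all condition effects, used to emulate spatially
#'   localized effects; `NULL` means 1 everywhere.
#'
#' @return An object of class `ground_truth` (a named list).
#' @export
ground_truth <- function(base_offset = 2.0,
                         base_exponent = 3.40,
                         subject_sd_exponent = 0.20,
                         effect_drug = 0.129,
                         effect_period = 0.124,
                         effect_prime = 0.026,
                         effect_flanker = 0.02,
                         peaks = list(c(center = 10, amplitude = 0.6, bandwidth = 1.5)),
                         noise_sd = 0.05,
                         spatial_effect_map = NULL) {
  if (base_exponent < 0) {
    abort("`base_exponent` must be nonnegative.", class = "aperiodic_config_error")
  }
  for (pk in peaks) {
    if (length(pk) != 3 || pk[[3]] <= 0 || pk[[1]] <= 0) {
      abort("each peak must be c(center > 0, amplitude, bandwidth > 0).",
            class = "aperiodic_config_error")
    }
  }
  structure(
    list(
      base_offset = base_offset,
      base_exponent = base_exponent,
      subject_sd_exponent = subject_sd_exponent,
      effect_drug = effect_drug,
      effect_period = effect_period,
      effect_prime = effect_prime,
      effect_flanker = effect_flanker,
      peaks = peaks,
      noise_sd = noise_sd,
      spatial_effect_map = spatial_effect_map
    ),
    class = "ground_truth"
  )
}

#' Participant random effects on the exponent
#'
#' @param truth A [ground_truth()] object.
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @return Numeric vector of per-participant exponent offsets.
#' @export
subject_effects <- function(truth, n_participants, seed = 1L) {
  with_seed(derive_seed(seed, "subjects"),
            rnorm(n_participants, 0, truth$subject_sd_exponent))
}

#' True exponent for one design cell
#'
#' Applies the ground-truth effect structure: drug and period shifts always,
#' prime/flanker-incongruency shifts in the within-trial period only, all
#' condition effects scaled by the electrode's spatial multiplier.
#'
#' @param truth A [ground_truth()] object.
#' @param drug `"placebo"` or `"MPH"`.
#' @param period `"pre_trial"` or `"within_trial"`.
#' @param prime,flanker `"congruent"` or `"incongruent"`.
#' @param subject_effect Participant offset (see [subject_effects()]).
#' @param electrode_mult Spatial multiplier for this electrode (default 1).
#' @return The cell's true aperiodic exponent (scalar).
#' @export
cell_exponent <- function(truth, drug, period, prime, flanker,
                          subject_effect = 0, electrode_mult = 1) {
  within <- period == "within_trial"
  eff <- (drug == "MPH") * truth$effect_drug +
    within * truth$effect_period +
    (within & prime == "incongruent") * truth$effect_prime +
    (within & flanker == "incongruent") * truth$effect_flanker
  truth$base_exponent + subject_effect + electrode_mult * eff
}

#' Evaluate the spectral model on a frequency grid
#'
#' The model is `log10 PSD(f) = b - x * log10(f) + sum_n a_n exp(-(f - mu_n)^2
#' / (2 sigma_n^2))`: a linear aperiodic component in log-log space plus
#' Gaussian peaks in linear frequency.
#'
#' @param freqs Frequencies in Hz, all > 0.
#' @param offset,exponent Aperiodic parameters `b` and `x`.
#' @param peaks List of `c(center, amplitude, bandwidth)` triplets (possibly
#'   empty).
#' @return log10-power values on `freqs`.
#' @export
spectral_model <- function(freqs, offset, exponent, peaks = list()) {
  lp <- offset - exponent * log10(freqs)
  for (pk in peaks) {
    lp <- lp + pk[[2]] * exp(-(freqs - pk[[1]])^2 / (2 * pk[[3]]^2))
  }
  lp
}

#' Generate one synthetic power spectrum
#'
#' Evaluates the aperiodic-plus-peaks model on `freqs`, adds i.i.d. Gaussian
#' noise on the log10-power scale, and returns linear power.
#'
#' @param freqs Strictly increasing frequencies in Hz, all > 0.
#' @param aperiodic `c(offset, exponent)`.
#' @param peaks List of `c(center, amplitude, bandwidth)` triplets.
#' @param noise_sd SD of log10-power noise (>= 0).
#' @param seed Optional integer seed.
#' @return A tibble with columns `freq` (Hz) and `power` (linear units).
#' @export
#' @examples
#' synth_spectrum(1:40, aperiodic = c(1, 2),
#'                peaks = list(c(10, 0.5, 2)), noise_sd = 0)
synth_spectrum <- function(freqs, aperiodic, peaks = list(), noise_sd = 0,
                           seed = NULL) {
  if (any(freqs <= 0)) {
    abort("all frequencies must be positive.", class = "aperiodic_domain_error")
  }
  if (is.unsorted(freqs, strictly = TRUE)) {
    abort("`freqs` must be strictly increasing.", class = "aperiodic_domain_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "aperiodic_domain_error")
  }
  lp <- spectral_model(freqs, aperiodic[[1]], aperiodic[[2]], peaks)
  if (noise_sd > 0) {
    lp <- lp + with_seed(seed, rnorm(length(freqs), 0, noise_sd))
  }
  tibble(freq = as.numeric(freqs), power = 10^lp)
}

#' Generate cell-level spectra for the whole study (fast mode)
#'
#' Bypasses time-domain simulation: for every participant x drug x condition
#' x period x electrode cell it evaluates the ground-truth spectral model at
#' the cell's true exponent and adds log10-power measurement noise, emulating
#' the averaged PSD of that cell's correct trials.
#'
#' @param truth A [ground_truth()] object.
#' @param n_participants Number of participants.
#' @param n_electrodes Number of electrodes (default 60).
#' @param freqs Frequency grid in Hz (default 1-Hz grid 1..45).
#' @param seed Integer seed.
#' @return A long tibble: `participant`, `drug`, `prime`, `flanker`,
#'   `period`, `electrode`, `freq`, `power`.
#' @export
synth_spectra <- function(truth = ground_truth(), n_participants = 25,
                          n_electrodes = 60, freqs = 1:45, seed = 1L) {
  subj <- subject_effects(truth, n_participants, seed)
  emap <- truth$spatial_effect_map %||% rep(1, n_electrodes)
  if (length(emap) != n_electrodes) {
    abort("`spatial_effect_map` length must equal `n_electrodes`.",
          class = "aperiodic_config_error")
  }
  elec <- sprintf("E%02d", seq_len(n_electrodes))
  cells <- tidyr::expand_grid(
    participant = seq_len(n_participants),
    drug = c("placebo", "MPH"),
    prime = c("congruent", "incongruent"),
    flanker = c("congruent", "incongruent"),
    period = c("pre_trial", "within_trial"),
    electrode = elec
  )
  ei <- match(cells$electrode, elec)
  x_true <- cell_exponent(truth, cells$drug, cells$period, cells$prime,
                          cells$flanker, subj[cells$participant], emap[ei])
  nf <- length(freqs)
  base_lp <- -outer(x_true, log10(freqs)) + truth$base_offset
  pk_lp <- spectral_model(freqs, 0, 0, truth$peaks)
  lp <- sweep(base_lp, 2, pk_lp, "+")
  if (truth$noise_sd > 0) {
    lp <- lp + with_seed(derive_seed(seed, "specnoise"),
                         matrix(rnorm(length(lp), 0, truth$noise_sd), nrow(lp), nf))
  }
  out <- cells[rep(seq_len(nrow(cells)), each = nf), ]
  out$freq <- rep(as.numeric(freqs), nrow(cells))
  out$power <- as.vector(t(10^lp))
  as_tibble(out)
}
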