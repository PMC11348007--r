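# Shared fixture builders; everything is generated in code under fixed seeds.

# A noisy realistic spectrum with known ground truth.
make_noisy_spectrum <- function(offset, exponent, peaks = list(), noise_sd = 0.05,
                                seed = 1, freqs = 1:45) {
  synth_spectrum(freqs, c(offset, exponent), peaks, noise_sd, seed = seed)
}

# Long exponent table with exact cell structure and optional injected drug
# effect; residual noise is subject-by-cell measurement error.
make_exponent_table <- function(n_subjects = 25, n_electrodes = 1,
                                effect_drug = 0, effect_period = 0,
                                noise_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    tbl <- tidyr::expand_grid(
      participant = seq_len(n_subjects),
      drug = c("placebo", "MPH"),
      prime = c("congruent", "incongruent"),
      flanker = c("congruent", "incongruent"),
      period = c("pre_trial", "within_trial"),
      electrode = sprintf("E%02d", seq_len(n_electrodes))
    )
    subj <- rnorm(n_subjects, 0, 0.2)
    tbl$exponent <- 3.4 + subj[tbl$participant] +
      effect_drug * (tbl$drug == "MPH") +
      effect_period * (tbl$period == "within_trial") +
      rnorm(nrow(tbl), 0, noise_sd)
    tbl$r_squared <- 0.99
    tbl
  })
}

# Paired-difference data for the cluster test: subjects x electrodes noise
# with an optional localized effect.
make_cluster_data <- function(n_subjects = 25, montage, effect = 0,
                              effect_electrodes = character(), sd = 1,
                              seed = 1) {
  withr::with_seed(seed, {
    ne <- length(montage$names)
    D <- matrix(rnorm(n_subjects * ne, 0, sd), n_subjects, ne)
    idx <- match(effect_electrodes, montage$names)
    D[, idx] <- D[, idx] + effect
    tibble::tibble(
      subject = rep(seq_len(n_subjects), ne),
      electrode = rep(montage$names, each = n_subjects),
      diff = as.vector(D)
    )
  })
}
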