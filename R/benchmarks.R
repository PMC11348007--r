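#' Fit-quality benchmark on an ensemble of synthetic spectra
#'
#' Generates `n_spectra` spectra from the aperiodic-plus-peaks model on the
#' 1-Hz 3--35 Hz grid — offset uniform in \[-1, 2\], exponent uniform in
#' \[0.5, 3.5\], 1--3 Gaussian peaks with centers inside the band, amplitudes
#' uniform in \[0.1, 0.8\] log10 units and SD-bandwidths uniform in \[1, 4\]
#' Hz, plus log10-power noise of SD `noise_sd` — fits each with the default
#' settings, and summarizes goodness of fit.
#'
#' @param n_spectra Ensemble size (default 1000).
#' @param noise_sd Log10-power noise SD (default 0.05).
#' @param settings [fit_settings()] used for every fit.
#' @param seed Integer seed.
#' @return A list: `mean_r_squared`, `median_r_squared`, `mean_exponent_error`
#'   (against the generating truth), and `n`.
#' @export
benchmark_fit_quality <- function(n_spectra = 1000, noise_sd = 0.05,
                                  settings = fit_settings(), seed = 1L) {
  freqs <- seq(settings$freq_range[1], settings$freq_range[2])
  with_seed(derive_seed(seed, "fitquality"), {
    rsq <- exp_err <- numeric(n_spectra)
    for (i in seq_len(n_spectra)) {
      b <- runif(1, -1, 2)
      x <- runif(1, 0.5, 3.5)
      n_pk <- sample(1:3, 1)
      pks <- lapply(seq_len(n_pk), function(j) {
        c(runif(1, freqs[1], freqs[length(freqs)]), runif(1, 0.1, 0.8),
          runif(1, 1, 4))
      })
      lp <- spectral_model(freqs, b, x, pks) + rnorm(length(freqs), 0, noise_sd)
      fit <- fit_spectrum(10^lp, settings, freqs = freqs)
      rsq[i] <- fit$r_squared
      exp_err[i] <- abs(fit$aperiodic[["exponent"]] - x)
    }
    list(mean_r_squared = mean(rsq), median_r_squared = median(rsq),
         mean_exponent_error = mean(exp_err), n = n_spectra)
  })
}

#' Family-wise error benchmark for the cluster permutation test
#'
#' Simulates the global null: `n_replicates` data sets of i.i.d. standard
#' normal paired differences for `n_subjects` subjects at every electrode of
#' the default montage, each analyzed with the F-statistic cluster test
#' (sample threshold `sample_alpha`, `n_perm` sign-flip permutations,
#' cluster alpha `cluster_alpha`). Reports the fraction of replicates with at
#' least one significant cluster.
#'
#' @param n_replicates Number of null replicates (default 2000).
#' @param n_subjects Subjects per replicate (default 25).
#' @param n_electrodes Electrodes (default 60).
#' @param n_perm Permutations per test (default 1000).
#' @param sample_alpha Electrode-level threshold (default .005).
#' @param cluster_alpha Cluster significance level (default .05).
#' @param seed Integer seed.
#' @return A list: `fwer`, `mc_se` (binomial Monte-Carlo standard error at
#'   the nominal level), `n` (replicates).
#' @export
benchmark_cluster_fwer <- function(n_replicates = 2000, n_subjects = 25,
                                   n_electrodes = 60, n_perm = 1000,
                                   sample_alpha = 0.005, cluster_alpha = 0.05,
                                   seed = 1L) {
  montage <- montage_adjacency(n_electrodes)
  hits <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    D <- with_seed(derive_seed(seed, "fwerdata", r),
                   matrix(rnorm(n_subjects * n_electrodes), n_subjects))
    dat <- tibble(
      subject = rep(seq_len(n_subjects), n_electrodes),
      electrode = rep(montage$names, each = n_subjects),
      diff = as.vector(D)
    )
    ct <- cluster_permutation_test(dat, montage, stat = "F",
                                   sample_alpha = sample_alpha,
                                   n_perm = n_perm,
                                   cluster_alpha = cluster_alpha,
                                   seed = derive_seed(seed, "fwerperm", r))
    hits[r] <- any(ct$clusters$significant)
  }
  list(fwer = mean(hits),
       mc_se = sqrt(cluster_alpha * (1 - cluster_alpha) / n_replicates),
       n = n_replicates)
}

#' End-to-end effect-recovery benchmark
#'
#' Runs the fast-mode pipeline `n_runs` times with the default injected
#' effects (drug +0.129, period +0.124) and counts the runs in which the
#' brain-wide ANOVA finds both main effects significant with the correct
#' sign (exponent higher under MPH and within-trial).
#'
#' @param n_runs Number of seeded runs (default 20).
#' @param n_participants Participants per run (default 25).
#' @param n_electrodes Electrodes per run (default 4; the brain-wide ANOVA
#'   averages across however many electrodes are simulated).
#' @param alpha Significance level per effect (default .05).
#' @param seed Integer seed.
#' @return A list: `recovery_rate`, `n` (runs).
#' @export
benchmark_effect_recovery <- function(n_runs = 20, n_participants = 25,
                                      n_electrodes = 4, alpha = 0.05,
                                      seed = 1L) {
  ok <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- run_config(
      seed = derive_seed(seed, "recovery", r),
      design = task_design(n_participants = n_participants),
      truth = ground_truth(),
      n_electrodes = n_electrodes,
      freqs = 3:35,
      stats = list(run_cluster = FALSE)
    )
    td <- tidy(run_pipeline(cfg)$anova)
    drug <- td[td$effect == "drug", ]
    period <- td[td$effect == "period", ]
    ok[r] <- drug$p < alpha && drug$estimate > 0 &&
      period$p < alpha && period$estimate > 0
  }
  list(recovery_rate = mean(ok), n = n_runs)
}
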