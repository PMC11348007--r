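test_that("synth_spectrum evaluates the aperiodic-plus-peaks model exactly", {
  # b=0, x=1 at 10 Hz: log10 power = -1 -> linear 0.1
  sp <- synth_spectrum(c(5, 10, 20), c(0, 1))
  expect_equal(sp$power[sp$freq == 10], 0.1, tolerance = 1e-12)

  # flat spectrum b=2, x=0
  sp <- synth_spectrum(1:30, c(2, 0))
  expect_true(all(abs(sp$power - 100) < 1e-9))

  # b=1, x=2, peak (a=0.5, mu=10, sigma=2) at f=10: log10 = 1 - 2 + 0.5 = -0.5
  sp <- synth_spectrum(c(2, 10, 30), c(1, 2), peaks = list(c(10, 0.5, 2)))
  expect_equal(log10(sp$power[sp$freq == 10]), -0.5, tolerance = 1e-12)
})

test_that("nonpositive or unsorted frequencies are domain errors", {
  expect_error(synth_spectrum(c(0, 1, 2), c(0, 1)), class = "aperiodic_domain_error")
  expect_error(synth_spectrum(c(-1, 5), c(0, 1)), class = "aperiodic_domain_error")
  expect_error(synth_spectrum(c(5, 3, 8), c(0, 1)), class = "aperiodic_domain_error")
  expect_error(synth_spectrum(1:10, c(0, 1), noise_sd = -1),
               class = "aperiodic_domain_error")
})

test_that("spectrum noise is reproducible under a seed", {
  a <- synth_spectrum(1:40, c(1, 2), noise_sd = 0.1, seed = 3)
  b <- synth_spectrum(1:40, c(1, 2), noise_sd = 0.1, seed = 3)
  c <- synth_spectrum(1:40, c(1, 2), noise_sd = 0.1, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("ground truth injects the drug contrast into cell exponents", {
  gt <- ground_truth()
  base <- cell_exponent(gt, "placebo", "pre_trial", "congruent", "congruent")
  expect_equal(cell_exponent(gt, "MPH", "pre_trial", "congruent", "congruent") - base,
               0.129, tolerance = 1e-12)
  expect_equal(cell_exponent(gt, "placebo", "within_trial", "congruent", "congruent") - base,
               0.124, tolerance = 1e-12)
  # prime/flanker effects are within-trial only
  expect_equal(cell_exponent(gt, "placebo", "pre_trial", "incongruent", "incongruent"),
               base, tolerance = 1e-12)
  wt <- cell_exponent(gt, "placebo", "within_trial", "incongruent", "incongruent")
  expect_equal(wt - base, 0.124 + 0.026 + 0.02, tolerance = 1e-12)
})

test_that("fast-mode study spectra carry the injected drug effect through fitting", {
  gt <- ground_truth(noise_sd = 0.03, peaks = list(c(10, 0.5, 1.5)))
  sp <- synth_spectra(gt, n_participants = 5, n_electrodes = 2,
                      freqs = 3:35, seed = 21)
  fits <- fit_spectra(sp)
  exps <- brainwide_exponents(exponent_table(fits))
  d <- mean(exps$exponent[exps$drug == "MPH"]) -
    mean(exps$exponent[exps$drug == "placebo"])
  expect_lt(abs(d - gt$effect_drug), 0.03)
})

test_that("spatial effect map localizes the condition effects", {
  emap <- c(0, 0, 1, 1)
  gt <- ground_truth(noise_sd = 0, peaks = list(), spatial_effect_map = emap,
                     subject_sd_exponent = 0)
  sp <- synth_spectra(gt, n_participants = 1, n_electrodes = 4,
                      freqs = 3:35, seed = 1)
  fits <- fit_spectra(sp)
  ex <- exponent_table(fits)
  mph <- ex[ex$drug == "MPH" & ex$period == "pre_trial" &
            ex$prime == "congruent" & ex$flanker == "congruent", ]
  pla <- ex[ex$drug == "placebo" & ex$period == "pre_trial" &
            ex$prime == "congruent" & ex$flanker == "congruent", ]
  diff <- mph$exponent[match(pla$electrode, mph$electrode)] - pla$exponent
  expect_equal(diff, c(0, 0, 0.129, 0.129), tolerance = 1e-6,
               ignore_attr = TRUE)
})
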