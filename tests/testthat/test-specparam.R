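test_that("initial aperiodic fit recovers an exact line and a flat spectrum", {
  lf <- log10(3:35)
  ap <- fit_aperiodic_initial(lf, 2 - 1.5 * lf)
  expect_equal(ap[["offset"]], 2, tolerance = 1e-6)
  expect_equal(ap[["exponent"]], 1.5, tolerance = 1e-6)

  ap0 <- fit_aperiodic_initial(lf, rep(0.7, length(lf)))
  expect_equal(ap0[["offset"]], 0.7, tolerance = 1e-9)
  expect_equal(ap0[["exponent"]], 0, tolerance = 1e-9)

  expect_error(fit_aperiodic_initial(lf[1:2], c(1, 2)),
               class = "aperiodic_fit_error")
})

test_that("robust refit equals the initial fit on pure aperiodic input", {
  lf <- log10(3:35)
  lp <- 1.2 - 2.3 * lf
  init <- fit_aperiodic_initial(lf, lp)
  rob <- fit_aperiodic_robust(lf, lp, init)
  expect_equal(rob, init, tolerance = 1e-6)
})

test_that("robust refit removes the peak-induced exponent bias", {
  f <- 3:35
  lf <- log10(f)
  truth <- c(offset = 1, exponent = 2)
  lp <- 1 - 2 * lf + 0.8 * exp(-(f - 10)^2 / (2 * 1.5^2))
  init <- fit_aperiodic_initial(lf, lp)
  expect_gt(abs(init[["exponent"]] - 2), 0.05)  # biased by the bump
  rob <- fit_aperiodic_robust(lf, lp, init)
  expect_lt(abs(rob[["exponent"]] - 2), 0.05)
})

test_that("a contaminated bin is excluded from the robust refit", {
  f <- 3:35
  lf <- log10(f)
  lp <- 0.5 - 1.8 * lf
  lp[f == 20] <- lp[f == 20] + 1
  rob <- fit_aperiodic_robust(lf, lp)
  # residual-ranking oracle: refit on all bins except the contaminated one
  keep <- f != 20
  oracle <- fit_aperiodic_initial(lf[keep], lp[keep])
  expect_equal(rob, oracle, tolerance = 1e-9)
})

test_that("peak extraction returns nothing for a flat residual", {
  expect_equal(nrow(extract_peaks(3:35, rep(0, 33))), 0)
})

test_that("a single Gaussian is recovered and sub-threshold bumps ignored", {
  f <- 3:35
  withr::with_seed(2, {
    flat <- 0.8 * exp(-(f - 10)^2 / (2 * 1.5^2)) + rnorm(length(f), 0, 0.01)
  })
  pk <- extract_peaks(f, flat)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$center - 10), 0.5)
  expect_lt(abs(pk$amplitude - 0.8), 0.1)

  two <- 0.5 * exp(-(f - 10)^2 / (2 * 1.5^2)) +
    0.5 * exp(-(f - 20)^2 / (2 * 1.5^2)) +
    0.03 * exp(-(f - 28)^2 / (2 * 1.5^2))
  pk2 <- extract_peaks(f, two)
  expect_equal(nrow(pk2), 2)
  expect_equal(sort(round(pk2$center)), c(10, 20))
})

test_that("full fit recovers noise-free parameters within 0.02", {
  sp <- synth_spectrum(1:45, c(1, 2), peaks = list(c(10, 0.5, 2)))
  fit <- fit_spectrum(sp)
  expect_lt(abs(fit$aperiodic[["exponent"]] - 2), 0.02)
  expect_lt(abs(fit$aperiodic[["offset"]] - 1), 0.03)
  expect_equal(nrow(fit$peaks), 1)
})

test_that("a pure aperiodic spectrum fits with R^2 >= 0.999 and no peaks", {
  for (par in list(c(0, 1), c(2, 3.5), c(-1, 0.5))) {
    fit <- fit_spectrum(synth_spectrum(1:45, par))
    expect_gte(fit$r_squared, 0.999)
    expect_equal(nrow(fit$peaks), 0)
  }
})

test_that("model spectrum satisfies the reconstruction identity to 1e-10", {
  sp <- make_noisy_spectrum(1, 2.5, list(c(9, 0.6, 2), c(20, 0.3, 2.5)),
                            noise_sd = 0.05, seed = 12)
  fit <- fit_spectrum(sp)
  manual <- (fit$aperiodic[["offset"]] - fit$aperiodic[["exponent"]] * log10(fit$freqs))
  for (i in seq_len(nrow(fit$peaks))) {
    manual <- manual + fit$peaks$amplitude[i] *
      exp(-(fit$freqs - fit$peaks$center[i])^2 / (2 * fit$peaks$bandwidth[i]^2))
  }
  expect_lt(max(abs(manual - fit$model)), 1e-10)
  # r_squared is the squared Pearson correlation of observed and model
  expect_equal(fit$r_squared, cor(fit$log_power, fit$model)^2, tolerance = 1e-12)
})

test_that("allowing peaks never lowers R^2 relative to an aperiodic-only fit", {
  for (seed in 1:5) {
    sp <- make_noisy_spectrum(0.5, 1.8, list(c(11, 0.5, 2)), 0.05, seed = seed)
    with_peaks <- fit_spectrum(sp)
    without <- fit_spectrum(sp, fit_settings(max_n_peaks = 0))
    expect_gte(with_peaks$r_squared, without$r_squared - 1e-12)
  }
})

test_that("scaling linear power by 10^c shifts only the offset", {
  sp <- make_noisy_spectrum(0.5, 2.2, list(c(10, 0.5, 1.8)), 0.05, seed = 31)
  f1 <- fit_spectrum(sp)
  sp2 <- dplyr::mutate(sp, power = power * 10^3)
  f2 <- fit_spectrum(sp2)
  expect_equal(f2$aperiodic[["offset"]] - f1$aperiodic[["offset"]], 3,
               tolerance = 1e-6)
  expect_equal(f2$aperiodic[["exponent"]], f1$aperiodic[["exponent"]],
               tolerance = 1e-6)
  expect_equal(as.data.frame(f2$peaks), as.data.frame(f1$peaks),
               tolerance = 1e-4)
})

test_that("exponent recovery over the parameter grid meets the error budget", {
  errs <- c()
  for (x in c(0.5, 1, 2, 3.5)) {
    for (b in c(-1, 0, 2)) {
      for (rep in 1:5) {
        seed <- 1000 + 100 * x + 10 * (b + 1) + rep
        sp <- make_noisy_spectrum(b, x, list(), 0.05, seed = seed, freqs = 3:35)
        fit <- fit_spectrum(sp)
        errs <- c(errs, abs(fit$aperiodic[["exponent"]] - x))
      }
    }
  }
  expect_lte(median(errs), 0.05)
})

test_that("no peak is fabricated on noiseless peak-free spectra", {
  for (x in c(0.5, 1, 2, 3.5)) {
    for (b in c(-1, 0, 2)) {
      fit <- fit_spectrum(synth_spectrum(3:35, c(b, x)))
      expect_equal(nrow(fit$peaks), 0)
    }
  }
})

test_that("nonpositive power in range is an input error naming frequencies", {
  sp <- synth_spectrum(1:45, c(1, 2))
  sp$power[sp$freq == 10] <- 0
  expect_error(fit_spectrum(sp), "10", class = "aperiodic_input_error")
})

test_that("spectra with <= 3 in-range bins return a flagged aperiodic-only fit", {
  sp <- synth_spectrum(c(5, 15, 25), c(1, 2))
  expect_warning(fit <- fit_spectrum(sp), "aperiodic-only")
  expect_true(fit$degenerate)
  expect_equal(nrow(fit$peaks), 0)
  expect_error(suppressWarnings(fit_spectrum(synth_spectrum(c(5, 15), c(1, 2)))),
               class = "aperiodic_input_error")
})

test_that("tidy/glance/fit_components expose the fit consistently", {
  sp <- synth_spectrum(1:45, c(1, 2), peaks = list(c(10, 0.5, 2)))
  fit <- fit_spectrum(sp)
  g <- glance(fit)
  expect_equal(g$exponent, fit$aperiodic[["exponent"]])
  expect_equal(g$n_peaks, nrow(tidy(fit)))
  comp <- fit_components(fit)
  expect_equal(comp$observed - comp$aperiodic, comp$flattened)
})
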