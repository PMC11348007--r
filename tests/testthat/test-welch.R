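test_that("a bin-aligned tone produces its spectral peak at that bin", {
  srate <- 256
  t <- seq(0, 4 - 1 / srate, by = 1 / srate)
  x <- sin(2 * pi * 12 * t)
  ps <- welch_psd(x, welch_settings(srate = srate))
  expect_equal(ps$freq[which.max(ps$power)], 12)
})

test_that("white-noise spectrum integrates to the signal variance (Parseval)", {
  withr::with_seed(42, {
    x <- rnorm(256 * 60)
    ps <- welch_psd(x, welch_settings(detrend = "none"))
    df <- ps$freq[2] - ps$freq[1]
    expect_lt(abs(sum(ps$power) * df - 1), 0.1)
  })
})

test_that("a constant-zero signal yields an all-zero spectrum", {
  ps <- welch_psd(rep(0, 512), welch_settings())
  expect_true(all(ps$power == 0))
})

test_that("default settings give 7 segments per 1000-ms trial and a 1-Hz grid", {
  ps <- welch_psd(rnorm(256), welch_settings())
  expect_equal(attr(ps, "n_segments"), 7)
  expect_equal(ps$freq[2] - ps$freq[1], 1)
  expect_equal(sum(ps$freq >= 3 & ps$freq <= 35), 33)
})

test_that("signals shorter than one segment are input errors", {
  expect_error(welch_psd(rnorm(32), welch_settings()),
               class = "aperiodic_input_error")
  expect_error(welch_settings(overlap_fraction = 1),
               class = "aperiodic_config_error")
  expect_error(welch_settings(n_fft = 16), class = "aperiodic_config_error")
})

test_that("condition PSD pools segments and equals per-trial averaging", {
  ep <- synth_epochs(exponent = 1.5, n_trials = 8, n_electrodes = 1, seed = 2)
  ep$metadata <- tibble::tibble(
    prime = rep(c("congruent", "incongruent"), each = 4),
    flanker = "congruent",
    correct = TRUE
  )
  st <- welch_settings()
  ps <- condition_psd(ep, st)
  # every trial contributes the same number of segments, so the pooled
  # spectrum equals the mean of per-trial spectra
  idx <- which(ep$metadata$prime == "congruent")
  per_trial <- sapply(idx, function(tr) welch_psd(ep$data[tr, 1, ], st)$power)
  pooled <- ps$power[ps$prime == "congruent" & ps$electrode == "E01"]
  expect_equal(pooled, rowMeans(per_trial), tolerance = 1e-12)
})

test_that("two conditions with identical trials give identical per-cell spectra", {
  ep <- synth_epochs(exponent = 1, n_trials = 2, n_electrodes = 1, seed = 8)
  ep$data[2, , ] <- ep$data[1, , ]
  ep$metadata <- tibble::tibble(prime = c("congruent", "incongruent"),
                                flanker = "congruent", correct = TRUE)
  ps <- condition_psd(ep, welch_settings())
  expect_equal(ps$power[ps$prime == "congruent"],
               ps$power[ps$prime == "incongruent"], tolerance = 1e-14)
})

test_that("incorrect trials are excluded and empty cells flagged missing", {
  ep <- synth_epochs(exponent = 1, n_trials = 8, n_electrodes = 1, seed = 6)
  ep$metadata <- tibble::tibble(
    prime = rep(c("congruent", "incongruent"), each = 4),
    flanker = rep(c("congruent", "incongruent"), times = 4),
    correct = rep(c(TRUE, FALSE), each = 4)
  )
  expect_warning(ps <- condition_psd(ep, welch_settings()),
                 "no correct trials")
  miss <- attr(ps, "missing_cells")
  expect_true(all(miss$prime == "incongruent"))
  expect_false("incongruent" %in% ps$prime)

  ep$metadata$correct <- FALSE
  expect_warning(ps2 <- condition_psd(ep, welch_settings()))
  expect_equal(nrow(ps2), 0)
  expect_equal(nrow(attr(ps2, "missing_cells")), 4)
})
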