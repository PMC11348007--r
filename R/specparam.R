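#' Spectral parameterization settings
#'
#' Controls the decomposition of a power spectrum into an aperiodic component
#' and Gaussian peaks. Defaults are the standard settings for event-related
#' EEG exponent analyses: fit range 3--35 Hz, fixed (knee-free) aperiodic
#' mode, peak widths bounded to \[2, 8\] Hz, at most 8 peaks, and a minimum
#' peak height of 0.05 log10-power units.
#'
#' The remaining knobs are the algorithm's conventional defaults: peaks must
#' also exceed `peak_threshold` (2.0) standard deviations of the flattened
#' spectrum; the robust aperiodic refit drops frequency bins whose positive
#' residual exceeds the `ap_percentile` quantile (0.025%) of the
#' positive-clipped residuals; overlapping peaks closer than
#' `proximity_guard` (0.75) bandwidths are pruned, keeping the taller peak;
#' and peaks whose center sits within one bandwidth of a range edge are
#' dropped.
#'
#' @param freq_range Fit range in Hz (default `c(3, 35)`).
#' @param aperiodic_mode Only `"fixed"` is supported.
#' @param peak_width_limits Bounds on peak FWHM-scale width in Hz
#'   (default `c(2, 8)`); Gaussian SD bounds are half these values.
#' @param max_n_peaks Maximum number of peaks (default 8).
#' @param min_peak_height Minimum peak height in log10-power units (default 0.05).
#' @param peak_threshold Detection threshold in residual-SD multiples (default 2).
#' @param proximity_guard Minimum center separation in bandwidth multiples
#'   (default 0.75).
#' @param ap_percentile Percentile (0--100) of positive-clipped residuals
#'   used by the robust aperiodic refit (default 0.025).
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(freq_range = c(3, 35), aperiodic_mode = "fixed",
                         peak_width_limits = c(2, 8), max_n_peaks = 8,
                         min_peak_height = 0.05, peak_threshold = 2.0,
                         proximity_guard = 0.75, ap_percentile = 0.025) {
  if (!identical(aperiodic_mode, "fixed")) {
    abort("only the 'fixed' aperiodic mode is supported.",
          class = "aperiodic_config_error")
  }
  if (length(freq_range) != 2 || diff(freq_range) <= 0 || freq_range[1] <= 0) {
    abort("`freq_range` must be a positive, increasing interval.",
          class = "aperiodic_config_error")
  }
  if (any(peak_width_limits <= 0) || diff(peak_width_limits) < 0) {
    abort("`peak_width_limits` must be positive and ordered.",
          class = "aperiodic_config_error")
  }
  structure(
    list(freq_range = freq_range, aperiodic_mode = aperiodic_mode,
         peak_width_limits = peak_width_limits,
         gauss_std_limits = peak_width_limits / 2,
         max_n_peaks = as.integer(max_n_peaks),
         min_peak_height = min_peak_height, peak_threshold = peak_threshold,
         proximity_guard = proximity_guard, ap_percentile = ap_percentile),
    class = "fit_settings"
  )
}

#' Initial aperiodic fit
#'
#' Ordinary least squares for `log_power = b - x * log_freqs`; because the
#' fixed aperiodic model is linear in its parameters the least-squares
#' solution is exact and needs no iterative seeding.
#'
#' @param log_freqs log10 frequencies.
#' @param log_power log10 power.
#' @return Named numeric `c(offset, exponent)`.
#' @export
fit_aperiodic_initial <- function(log_freqs, log_power) {
  if (length(log_freqs) < 3) {
    abort("need at least 3 frequency points for an aperiodic fit.",
          class = "aperiodic_fit_error")
  }
  cf <- stats::.lm.fit(cbind(1, log_freqs), log_power)$coefficients
  c(offset = cf[1], exponent = -cf[2])
}

#' Robust aperiodic refit
#'
#' Flattens the spectrum against an initial aperiodic fit, clips negative
#' residuals to zero, and refits using only the bins whose positive residual
#' does not exceed the `percentile_thresh` quantile of the clipped residuals.
#' Bins under oscillatory peaks (large positive residuals) are thereby
#' excluded, removing the upward exponent bias peaks would otherwise cause.
#'
#' @param log_freqs,log_power log10 frequency and power vectors.
#' @param initial Initial `c(offset, exponent)` (see [fit_aperiodic_initial()]).
#' @param percentile_thresh Percentile (0--100) of the clipped residuals.
#' @return Named numeric `c(offset, exponent)`.
#' @export
fit_aperiodic_robust <- function(log_freqs, log_power, initial = NULL,
                                 percentile_thresh = 0.025) {
  initial <- initial %||% fit_aperiodic_initial(log_freqs, log_power)
  resid <- log_power - (initial[["offset"]] - initial[["exponent"]] * log_freqs)
  flat <- pmax(resid, 0)
  thresh <- quantile(flat, percentile_thresh / 100, names = FALSE, type = 7)
  keep <- flat <= thresh
  if (sum(keep) < 2) {
    abort("robust refit excluded all frequency points.",
          class = "aperiodic_fit_error")
  }
  cf <- stats::.lm.fit(cbind(1, log_freqs[keep]), log_power[keep])$coefficients
  c(offset = cf[1], exponent = -cf[2])
}

# Sum of Gaussians; `peaks` is a matrix with columns center, amplitude, sd.
gaussian_model <- function(freqs, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) return(rep(0, length(freqs)))
  out <- rep(0, length(freqs))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks[i, 2] * exp(-(freqs - peaks[i, 1])^2 / (2 * peaks[i, 3]^2))
  }
  out
}

#' Extract Gaussian peaks from a flattened spectrum
#'
#' Iteratively locates the maximum of the peak-flattened log10 spectrum,
#' stops when it falls below `max(min_peak_height, peak_threshold * SD)` of
#' the current residual, seeds a Gaussian there with a half-height width
#' heuristic (clipped to the width limits), subtracts it, and repeats up to
#' `max_n_peaks` times. Candidates hugging a range edge or overlapping a
#' taller candidate are dropped, and the survivors are refined jointly by
#' bounded least squares.
#'
#' @param freqs Frequencies (Hz) of the fit grid.
#' @param flattened Observed log10 power minus the robust aperiodic fit.
#' @param settings A [fit_settings()] object.
#' @return A tibble with columns `center`, `amplitude`, `bandwidth`
#'   (Gaussian SD, Hz); zero rows when no peak qualifies.
#' @export
extract_peaks <- function(freqs, flattened, settings = fit_settings()) {
  std_lim <- settings$gauss_std_limits
  freq_res <- if (length(freqs) > 1) freqs[2] - freqs[1] else 1
  flat_iter <- flattened
  guess <- NULL

  for (i in seq_len(settings$max_n_peaks)) {
    max_ind <- which.max(flat_iter)
    max_height <- flat_iter[max_ind]
    if (max_height <= settings$peak_threshold * sd(flat_iter)) break
    if (max_height <= settings$min_peak_height) break
    guess_freq <- freqs[max_ind]
    half <- 0.5 * max_height
    le <- ri <- NA_integer_
    if (max_ind > 1) {
      below <- which(flat_iter[seq_len(max_ind - 1)] <= half)
      if (length(below)) le <- max_ind - max(below)
    }
    if (max_ind < length(flat_iter)) {
      below <- which(flat_iter[(max_ind + 1):length(flat_iter)] <= half)
      if (length(below)) ri <- min(below)
    }
    short_side <- suppressWarnings(min(c(le, ri), na.rm = TRUE))
    guess_std <- if (is.finite(short_side)) {
      fwhm <- short_side * 2 * freq_res
      fwhm / (2 * sqrt(2 * log(2)))
    } else {
      mean(std_lim)
    }
    guess_std <- min(max(guess_std, std_lim[1]), std_lim[2])
    guess <- rbind(guess, c(guess_freq, max_height, guess_std))
    flat_iter <- flat_iter -
      max_height * exp(-(freqs - guess_freq)^2 / (2 * guess_std^2))
  }

  if (is.null(guess)) {
    return(tibble(center = numeric(), amplitude = numeric(), bandwidth = numeric()))
  }
  guess <- drop_edge_peaks(guess, range(freqs), bw_std_edge = 1.0)
  guess <- drop_overlapping_peaks(guess, settings$proximity_guard)
  if (nrow(guess) == 0) {
    return(tibble(center = numeric(), amplitude = numeric(), bandwidth = numeric()))
  }
  fitted <- refine_peaks(freqs, flattened, guess, settings)
  tibble(center = fitted[, 1], amplitude = fitted[, 2], bandwidth = fitted[, 3])
}

# Drop candidate peaks whose center lies within `bw_std_edge` Gaussian SDs of
# either edge of the fit range.
drop_edge_peaks <- function(guess, frange, bw_std_edge = 1.0) {
  keep <- (guess[, 1] - frange[1]) > bw_std_edge * guess[, 3] &
    (frange[2] - guess[, 1]) > bw_std_edge * guess[, 3]
  guess[keep, , drop = FALSE]
}

# Among candidates whose proximity bands (center +/- guard * SD) overlap,
# keep the taller one.
drop_overlapping_peaks <- function(guess, guard) {
  if (nrow(guess) <= 1) return(guess)
  ord <- order(guess[, 1])
  g <- guess[ord, , drop = FALSE]
  drop <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(g) - 1)) {
    if (g[i, 1] + guard * g[i, 3] > g[i + 1, 1] - guard * g[i + 1, 3]) {
      loser <- if (g[i, 2] < g[i + 1, 2]) i else i + 1
      drop[loser] <- TRUE
    }
  }
  g[!drop, , drop = FALSE]
}

# Joint bounded least-squares refinement of all Gaussian candidates
# (L-BFGS-B with analytic gradient). Bounds: center within 2 * 1.5 guessed
# SDs of its seed (clipped to the frequency range), amplitude >= 0, SD within
# the width limits.
refine_peaks <- function(freqs, flattened, guess, settings) {
  m <- nrow(guess)
  std_lim <- settings$gauss_std_limits
  frange <- range(freqs)
  cf_wander <- 2 * 1.5 * guess[, 3]
  lower <- as.vector(rbind(pmax(frange[1], guess[, 1] - cf_wander), 0, std_lim[1]))
  upper <- as.vector(rbind(pmin(frange[2], guess[, 1] + cf_wander), Inf, std_lim[2]))
  par0 <- as.vector(t(guess))

  obj <- function(p) {
    pk <- matrix(p, ncol = 3, byrow = TRUE)
    r <- gaussian_model(freqs, pk) - flattened
    sum(r^2)
  }
  grad <- function(p) {
    pk <- matrix(p, ncol = 3, byrow = TRUE)
    r <- gaussian_model(freqs, pk) - flattened
    g <- numeric(length(p))
    for (i in seq_len(m)) {
      d <- freqs - pk[i, 1]
      gi <- exp(-d^2 / (2 * pk[i, 3]^2))
      base <- 2 * r * gi
      g[3 * i - 2] <- sum(base * pk[i, 2] * d / pk[i, 3]^2)
      g[3 * i - 1] <- sum(base)
      g[3 * i] <- sum(base * pk[i, 2] * d^2 / pk[i, 3]^3)
    }
    g
  }
  fit <- tryCatch(
    optim(par0, obj, grad, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 200)),
    error = function(e) NULL
  )
  p <- if (is.null(fit)) par0 else fit$par
  out <- matrix(p, ncol = 3, byrow = TRUE)
  out[order(out[, 1]), , drop = FALSE]
}

#' Parameterize one power spectrum
#'
#' Full decomposition pipeline: trim the spectrum to the fit range, take
#' log10, fit the aperiodic component robustly, extract Gaussian peaks from
#' the flattened spectrum, subtract the peak model from the original
#' spectrum, refit the aperiodic component on the peak-removed spectrum, and
#' assemble the final model. Goodness of fit is reported on the fit grid as
#' the squared Pearson correlation between observed and modeled log10 power
#' (`r_squared`) and the mean absolute error (`mae`).
#'
#' Spectra with three or fewer in-range bins are refused a peak model and
#' return an aperiodic-only fit flagged `degenerate`.
#'
#' @param spectrum A data frame with `freq` and `power` columns (linear
#'   power), or a numeric vector of power with frequencies in `freqs`.
#' @param settings A [fit_settings()] object.
#' @param freqs Frequencies when `spectrum` is a bare vector.
#' @return An object of class `spectral_fit`; see [tidy.spectral_fit()] and
#'   [glance.spectral_fit()].
#' @export
#' @examples
#' sp <- synth_spectrum(1:40, c(1, 2), peaks = list(c(10, 0.5, 2)))
#' fit <- fit_spectrum(sp)
#' glance(fit)
fit_spectrum <- function(spectrum, settings = fit_settings(), freqs = NULL) {
  if (is.data.frame(spectrum)) {
    freqs <- spectrum$freq
    power <- spectrum$power
  } else {
    power <- spectrum
  }
  if (is.null(freqs) || length(freqs) != length(power)) {
    abort("spectrum must provide aligned `freq` and `power`.",
          class = "aperiodic_input_error")
  }
  sel <- freqs >= settings$freq_range[1] & freqs <= settings$freq_range[2]
  freqs <- freqs[sel]; power <- power[sel]
  if (length(freqs) < 3) {
    abort("fewer than 3 frequency bins inside the fit range.",
          class = "aperiodic_input_error")
  }
  if (any(!is.finite(power) | power <= 0)) {
    bad <- freqs[!is.finite(power) | power <= 0]
    abort(sprintf("nonpositive or non-finite power at: %s Hz",
                  paste(signif(bad, 4), collapse = ", ")),
          class = "aperiodic_input_error")
  }
  lf <- log10(freqs)
  lp <- log10(power)

  degenerate <- length(freqs) <= 3
  if (degenerate) {
    ap <- fit_aperiodic_initial(lf, lp)
    peaks <- tibble(center = numeric(), amplitude = numeric(), bandwidth = numeric())
    warn("spectrum has <= 3 in-range bins; returning an aperiodic-only fit.")
  } else {
    ap0 <- fit_aperiodic_robust(lf, lp, percentile_thresh = settings$ap_percentile)
    flat <- lp - (ap0[["offset"]] - ap0[["exponent"]] * lf)
    peaks <- extract_peaks(freqs, flat, settings)
    peak_fit <- gaussian_model(freqs, as.matrix(peaks))
    ap <- fit_aperiodic_initial(lf, lp - peak_fit)
  }
  model <- (ap[["offset"]] - ap[["exponent"]] * lf) +
    gaussian_model(freqs, as.matrix(peaks))
  rsq <- if (sd(lp) == 0 && sd(model) == 0) 1 else suppressWarnings(cor(lp, model)^2)
  if (is.na(rsq)) rsq <- if (all(abs(lp - model) < 1e-12)) 1 else 0
  structure(
    list(
      aperiodic = ap,
      peaks = peaks,
      r_squared = rsq,
      mae = mean(abs(lp - model)),
      settings = settings,
      freqs = freqs,
      log_power = lp,
      model = model,
      degenerate = degenerate
    ),
    class = "spectral_fit"
  )
}

#' Fit every spectrum in a long table
#'
#' Groups a long spectra table by everything that is not `freq` / `power` /
#' `n_segments` and runs [fit_spectrum()] per group.
#'
#' @param spectra Long tibble with `freq`, `power`, and identifying columns.
#' @param settings A [fit_settings()] object.
#' @return A tibble: one row per cell with the identifying columns plus
#'   `offset`, `exponent`, `n_peaks`, `r_squared`, `mae`, and a `peaks`
#'   list-column.
#' @export
fit_spectra <- function(spectra, settings = fit_settings()) {
  key_cols <- setdiff(names(spectra), c("freq", "power", "n_segments"))
  if (length(key_cols) == 0) {
    f <- fit_spectrum(spectra, settings)
    return(dplyr::bind_cols(glance(f), tibble(peaks = list(f$peaks))))
  }
  id <- do.call(paste, c(spectra[key_cols], sep = "\r"))
  idx <- split(seq_len(nrow(spectra)), factor(id, levels = unique(id)))
  rows <- purrr::map(idx, function(i) {
    f <- fit_spectrum(spectra[i, c("freq", "power")], settings)
    dplyr::bind_cols(
      spectra[i[1], key_cols],
      glance(f),
      tibble(peaks = list(f$peaks))
    )
  })
  dplyr::bind_rows(rows)
}

#' Long exponent table from per-cell fits
#'
#' Selects the indexing columns and the aperiodic exponent from a
#' [fit_spectra()] result, validating that no cell occurs twice.
#'
#' @param fits A [fit_spectra()] result.
#' @return A tibble of index columns plus `exponent` and `r_squared`.
#' @export
exponent_table <- function(fits) {
  key_cols <- intersect(
    c("participant", "session", "drug", "prime", "flanker", "period", "electrode"),
    names(fits)
  )
  if (anyDuplicated(fits[key_cols])) {
    abort("duplicate cell index in fit table.", class = "aperiodic_data_error")
  }
  dplyr::select(fits, dplyr::all_of(c(key_cols, "exponent", "r_squared")))
}

#' Brain-wide exponents: average across electrodes per participant and cell
#'
#' @param exponents An [exponent_table()] result containing an `electrode`
#'   column.
#' @return A tibble with one row per participant x condition cell:
#'   `exponent` (mean over contributing electrodes) and `n_electrodes`.
#' @export
brainwide_exponents <- function(exponents) {
  keys <- intersect(c("participant", "drug", "prime", "flanker", "period"),
                    names(exponents))
  exponents |>
    dplyr::filter(!is.na(.data$exponent)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_electrodes = dplyr::n(),
      exponent = mean(.data$exponent),
      .groups = "drop"
    )
}
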