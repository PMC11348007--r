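#' Generate multi-channel epochs with a known aperiodic slope
#'
#' Each trial and electrode receives an independent realization of spectrally
#' shaped Gaussian noise: white noise is shaped in the frequency domain with
#' amplitude proportional to `f^(-exponent/2)` (randomized phases, Hermitian
#' symmetry, zero DC), so the expected power spectral density follows
#' `10^offset * f^(-exponent)` exactly on the epoch's native frequency grid.
#' Oscillatory peaks are added in the time domain as amplitude-modulated
#' sinusoids whose center frequency jitters across trials by the peak's
#' bandwidth, which produces Gaussian-like bumps in the averaged PSD.
#'
#' @param exponent Target aperiodic exponent (>= 0); scalar, or one value per
#'   electrode.
#' @param offset Aperiodic offset in log10(uV^2/Hz) (scalar or per electrode).
#' @param peaks List of `c(center, amplitude, bandwidth)` triplets (log10
#'   bump height above the aperiodic component at the center frequency).
#' @param n_trials,n_electrodes Array dimensions.
#' @param duration_s Epoch length in seconds (default 1).
#' @param srate Sampling rate in Hz (default 256).
#' @param window_label `"pre_trial"` or `"within_trial"`.
#' @param t0_offset_ms Window start relative to target onset (defaults to
#'   -1200 for pre-trial, 0 for within-trial).
#' @param metadata Optional per-trial tibble (condition labels, correctness);
#'   must have `n_trials` rows.
#' @param seed Integer seed.
#'
#' @return An object of class `epoch_set`: a list with `data` (array
#'   trials x electrodes x samples, uV), `srate`, `window_label`,
#'   `t0_offset_ms`, `electrodes`, and `metadata`.
#' @export
#' @examples
#' ep <- synth_epochs(exponent = 2, n_trials = 5, n_electrodes = 2, seed = 1)
#' dim(ep$data)
synth_epochs <- function(exponent, offset = 2.0, peaks = list(),
                         n_trials = 96, n_electrodes = 60,
                         duration_s = 1, srate = 256,
                         window_label = c("within_trial", "pre_trial"),
                         t0_offset_ms = NULL, metadata = NULL, seed = 1L) {
  window_label <- match.arg(window_label)
  n <- round(duration_s * srate)
  if (n < 16) {
    abort("epoch window too short for spectral estimation.",
          class = "aperiodic_config_error")
  }
  if (any(exponent < 0)) {
    abort("`exponent` must be nonnegative.", class = "aperiodic_config_error")
  }
  exponent <- rep_len(exponent, n_electrodes)
  offset <- rep_len(offset, n_electrodes)
  if (!is.null(metadata) && nrow(metadata) != n_trials) {
    abort("`metadata` must have one row per trial.", class = "aperiodic_config_error")
  }
  t0_offset_ms <- t0_offset_ms %||% if (window_label == "pre_trial") -1200 else 0

  nf <- n %/% 2
  f <- seq_len(nf) * srate / n
  dat <- array(0, dim = c(n_trials, n_electrodes, n))
  with_seed(derive_seed(seed, "epochs", window_label), {
    for (e in seq_len(n_electrodes)) {
      # target one-sided PSD 10^b * f^-x; bin amplitude for an n-point DFT of
      # a real signal: |X_k|^2 * 2 / (n * srate) = PSD(f_k)
      amp <- sqrt(10^offset[e] * f^(-exponent[e]) * n * srate / 2)
      for (tr in seq_len(n_trials)) {
        ph <- runif(nf - 1, 0, 2 * pi)
        spec <- complex(length.out = n)
        spec[2:nf] <- amp[seq_len(nf - 1)] * exp(1i * ph)
        spec[nf + 1] <- amp[nf] * sqrt(2) * sign(runif(1) - 0.5)
        spec[n:(nf + 2)] <- Conj(spec[2:nf])
        x <- Re(fft(spec, inverse = TRUE)) / n
        dat[tr, e, ] <- x
      }
      for (pk in peaks) {
        dat[, e, ] <- dat[, e, ] +
          oscillation_trials(pk, n_trials, n, srate, 10^offset[e] * pk[[1]]^(-exponent[e]))
      }
    }
  })
  structure(
    list(
      data = dat,
      srate = srate,
      window_label = window_label,
      t0_offset_ms = t0_offset_ms,
      electrodes = sprintf("E%02d", seq_len(n_electrodes)),
      metadata = if (is.null(metadata)) NULL else as_tibble(metadata)
    ),
    class = "epoch_set"
  )
}

# Amplitude-modulated sinusoids for one electrode: per trial, a sinusoid at
# center + N(0, bandwidth) Hz with a slow random amplitude envelope. The RMS
# amplitude is calibrated so the averaged PSD gains roughly `amplitude` log10
# units over the aperiodic level `ap_power_center` at the center frequency
# (bump power spread over a Gaussian of SD `bandwidth`).
oscillation_trials <- function(pk, n_trials, n, srate, ap_power_center) {
  center <- pk[[1]]; height <- pk[[2]]; bw <- pk[[3]]
  t <- seq(0, n - 1) / srate
  bump_power <- ap_power_center * (10^height - 1) * sqrt(2 * pi) * bw
  a_rms <- sqrt(2 * bump_power)
  out <- matrix(0, n_trials, n)
  for (tr in seq_len(n_trials)) {
    fc <- center + rnorm(1, 0, bw)
    fm <- runif(1, 0.5, 2)
    env <- 1 + 0.5 * sin(2 * pi * fm * t + runif(1, 0, 2 * pi))
    env <- env / sqrt(mean(env^2))
    out[tr, ] <- a_rms * env * sin(2 * pi * fc * t + runif(1, 0, 2 * pi))
  }
  out
}

#' Generate epochs for one participant-session and analysis window
#'
#' Looks up the participant's subject effect and each trial's condition to set
#' the per-trial true exponent, then synthesizes the session's epochs trial by
#' trial. Pre-trial windows carry no condition-specific prime/flanker effects
#' beyond those the ground truth assigns to that period.
#'
#' @param trials Trial table rows for one participant-session (see
#'   [generate_design()]).
#' @param truth A [ground_truth()] object.
#' @param window_label `"pre_trial"` or `"within_trial"`.
#' @param n_electrodes Number of electrodes (default 60).
#' @param srate Sampling rate (default 256).
#' @param subject_effect Participant exponent offset (default drawn via
#'   [subject_effects()] is the caller's responsibility; default 0).
#' @param seed Integer seed.
#' @return An `epoch_set` whose `metadata` is `trials`.
#' @export
synth_session_epochs <- function(trials, truth = ground_truth(),
                                 window_label = c("within_trial", "pre_trial"),
                                 n_electrodes = 60, srate = 256,
                                 subject_effect = 0, seed = 1L) {
  window_label <- match.arg(window_label)
  stopifnot(nrow(trials) > 0, length(unique(trials$participant)) == 1)
  emap <- truth$spatial_effect_map %||% rep(1, n_electrodes)
  n <- round(1 * srate)
  dat <- array(0, dim = c(nrow(trials), n_electrodes, n))
  for (tr in seq_len(nrow(trials))) {
    x_tr <- cell_exponent(truth, trials$drug[tr], window_label,
                          trials$prime[tr], trials$flanker[tr],
                          subject_effect, emap)
    ep <- synth_epochs(
      exponent = x_tr, offset = truth$base_offset, peaks = truth$peaks,
      n_trials = 1, n_electrodes = n_electrodes, duration_s = 1, srate = srate,
      window_label = window_label,
      seed = derive_seed(seed, trials$participant[tr], trials$session[tr],
                         window_label, tr)
    )
    dat[tr, , ] <- ep$data[1, , ]
  }
  structure(
    list(
      data = dat,
      srate = srate,
      window_label = window_label,
      t0_offset_ms = if (window_label == "pre_trial") -1200 else 0,
      electrodes = sprintf("E%02d", seq_len(n_electrodes)),
      metadata = as_tibble(trials)
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d electrodes x %d samples @ %g Hz, %s window (t0 %+d ms)\n",
    d[1], d[2], d[3], x$srate, x$window_label, x$t0_offset_ms
  ))
  invisible(x)
}
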