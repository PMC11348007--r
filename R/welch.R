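#' Welch estimator settings
#'
#' Defaults follow the conventional event-related EEG choice of 0.25-second
#' Hamming-tapered segments with 50% overlap. At 256 Hz a 0.25-s segment is
#' 64 samples, which natively gives 4-Hz resolution; the default `n_fft`
#' policy zero-pads each segment to `max(256, segment samples)` points so the
#' spectrum is reported on a 1-Hz grid (33 bins across 3--35 Hz), matching the
#' default behavior of common Welch implementations.
#'
#' @param segment_s Segment length in seconds (default 0.25).
#' @param window Taper: `"hamming"` (default), `"hann"`, or `"boxcar"`.
#' @param overlap_fraction Fractional overlap in `[0, 1)` (default 0.5).
#' @param n_fft Transform length; `NULL` applies the default policy.
#' @param srate Sampling rate in Hz (default 256).
#' @param detrend `"constant"` (per-segment mean removal, default) or
#'   `"none"`.
#' @return An object of class `welch_settings`.
#' @export
welch_settings <- function(segment_s = 0.25, window = c("hamming", "hann", "boxcar"),
                           overlap_fraction = 0.5, n_fft = NULL, srate = 256,
                           detrend = c("constant", "none")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  nseg <- round(segment_s * srate)
  if (nseg < 8) {
    abort("segment length must be at least 8 samples.", class = "aperiodic_config_error")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must lie in [0, 1).", class = "aperiodic_config_error")
  }
  n_fft <- n_fft %||% max(256L, nseg)
  if (n_fft < nseg) {
    abort("`n_fft` must be >= the segment length.", class = "aperiodic_config_error")
  }
  structure(
    list(segment_s = segment_s, window = window,
         overlap_fraction = overlap_fraction, n_fft = as.integer(n_fft),
         srate = srate, detrend = detrend, n_segment = nseg),
    class = "welch_settings"
  )
}

taper_vector <- function(window, n) {
  k <- seq(0, n - 1)
  switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
    boxcar = rep(1, n)
  )
}

# Accumulate one-sided modified periodograms of every segment of `x`.
# Returns list(sum_power, n_segments); density scaling 1 / (srate * sum(w^2)),
# interior bins doubled.
welch_accumulate <- function(x, settings) {
  nseg <- settings$n_segment
  if (length(x) < nseg) {
    abort("signal shorter than one Welch segment.", class = "aperiodic_input_error")
  }
  hop <- max(1L, round(nseg * (1 - settings$overlap_fraction)))
  w <- taper_vector(settings$window, nseg)
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  nfft <- settings$n_fft
  nbins <- nfft %/% 2 + 1L
  segs <- matrix(0, nfft, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nseg - 1L)]
    if (settings$detrend == "constant") seg <- seg - mean(seg)
    segs[seq_len(nseg), i] <- seg * w
  }
  sp <- Mod(stats::mvfft(segs)[seq_len(nbins), , drop = FALSE])^2
  acc <- rowSums(sp) / (settings$srate * sum(w^2))
  acc[2:(nbins - 1L)] <- 2 * acc[2:(nbins - 1L)]
  list(sum_power = acc, n_segments = length(starts))
}

#' Welch power spectral density of a single signal
#'
#' Averages one-sided modified periodograms of overlapping tapered segments,
#' scaled as a density (uV^2/Hz): for white noise of variance `s2` the
#' spectrum integrates to approximately `s2`.
#'
#' @param x Numeric signal vector.
#' @param settings A [welch_settings()] object.
#' @return A tibble with `freq` (Hz, 0..Nyquist) and `power`, plus attribute
#'   `n_segments`.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / 256))
#' ps <- welch_psd(x, welch_settings())
#' ps$freq[which.max(ps$power)]
welch_psd <- function(x, settings = welch_settings()) {
  acc <- welch_accumulate(x, settings)
  nbins <- settings$n_fft %/% 2 + 1L
  out <- tibble(
    freq = seq(0, nbins - 1L) * settings$srate / settings$n_fft,
    power = acc$sum_power / acc$n_segments
  )
  attr(out, "n_segments") <- acc$n_segments
  out
}

#' Per-cell power spectra for an epoch set
#'
#' Estimates one spectrum per electrode x prime x flanker condition (the
#' epoch set's window supplies the period label), pooling Welch segments
#' across all correct trials of the cell before averaging. Incorrect trials
#' are excluded; a cell with no correct trials is reported in the
#' `missing_cells` attribute rather than silently producing NaN.
#'
#' @param epochs An `epoch_set` with per-trial `metadata` containing `prime`,
#'   `flanker`, `correct` (and optionally `participant`, `drug`).
#' @param settings A [welch_settings()] object; its `srate` is overridden by
#'   the epoch set's sampling rate.
#' @param trials Optional replacement trial table (defaults to
#'   `epochs$metadata`).
#' @return A long tibble `electrode`, `prime`, `flanker`, `period`, `freq`,
#'   `power`, `n_segments` (plus `participant`/`drug` when present in the
#'   trial table), with attribute `missing_cells`.
#' @export
condition_psd <- function(epochs, settings = welch_settings(), trials = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  trials <- trials %||% epochs$metadata
  if (is.null(trials)) {
    abort("no trial table: supply `trials` or generate epochs with metadata.",
          class = "aperiodic_input_error")
  }
  if (!"correct" %in% names(trials)) {
    abort("trial table lacks a `correct` column.", class = "aperiodic_input_error")
  }
  if (nrow(trials) != dim(epochs$data)[1]) {
    abort("trial table is not aligned with the epoch array.",
          class = "aperiodic_input_error")
  }
  settings$srate <- epochs$srate
  extra <- intersect(c("participant", "drug"), names(trials))
  cells <- dplyr::arrange(dplyr::distinct(trials[, c("prime", "flanker")]),
                          .data$prime, .data$flanker)
  nbins <- settings$n_fft %/% 2 + 1L
  freqs <- seq(0, nbins - 1L) * settings$srate / settings$n_fft
  out <- list(); missing <- list()
  for (ci in seq_len(nrow(cells))) {
    idx <- which(trials$prime == cells$prime[ci] &
                 trials$flanker == cells$flanker[ci] & trials$correct)
    for (e in seq_along(epochs$electrodes)) {
      if (length(idx) == 0L) {
        if (e == 1L) missing[[length(missing) + 1L]] <- cells[ci, ]
        next
      }
      acc <- rep(0, nbins); nsegs <- 0L
      for (tr in idx) {
        a <- welch_accumulate(epochs$data[tr, e, ], settings)
        acc <- acc + a$sum_power
        nsegs <- nsegs + a$n_segments
      }
      row <- tibble(
        electrode = epochs$electrodes[e],
        prime = cells$prime[ci], flanker = cells$flanker[ci],
        period = epochs$window_label,
        freq = freqs, power = acc / nsegs, n_segments = nsegs
      )
      for (col in extra) row[[col]] <- trials[[col]][idx[1]]
      out[[length(out) + 1L]] <- row
    }
  }
  res <- dplyr::bind_rows(out)
  miss <- if (length(missing)) dplyr::bind_rows(missing) else cells[0, ]
  miss$period <- rep(epochs$window_label, nrow(miss))
  if (nrow(miss) > 0) {
    warn(sprintf("%d condition cell(s) have no correct trials.", nrow(miss)))
  }
  attr(res, "missing_cells") <- miss
  res
}
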