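#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf(
    "<spectral_fit> offset %.3f, exponent %.3f, %d peak(s), R^2 %.4f, MAE %.4f%s\n",
    x$aperiodic[["offset"]], x$aperiodic[["exponent"]], nrow(x$peaks),
    x$r_squared, x$mae, if (x$degenerate) " [degenerate]" else ""
  ))
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Tidy a spectral fit into one row per peak
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return A tibble with columns `center`, `amplitude`, `bandwidth`.
#' @export
tidy.spectral_fit <- function(x, ...) {
  x$peaks
}

#' One-row summary of a spectral fit
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return A tibble with `offset`, `exponent`, `n_peaks`, `r_squared`, `mae`,
#'   `degenerate`.
#' @export
glance.spectral_fit <- function(x, ...) {
  tibble(
    offset = x$aperiodic[["offset"]],
    exponent = x$aperiodic[["exponent"]],
    n_peaks = nrow(x$peaks),
    r_squared = x$r_squared,
    mae = x$mae,
    degenerate = x$degenerate
  )
}

#' Reconstruct model components of a spectral fit on its fit grid
#'
#' @param x A `spectral_fit`.
#' @return A tibble with `freq`, `observed`, `model`, `aperiodic` (all log10
#'   power) and `flattened` (observed minus aperiodic).
#' @export
fit_components <- function(x) {
  stopifnot(inherits(x, "spectral_fit"))
  ap <- x$aperiodic[["offset"]] - x$aperiodic[["exponent"]] * log10(x$freqs)
  tibble(
    freq = x$freqs,
    observed = x$log_power,
    model = x$model,
    aperiodic = ap,
    flattened = x$log_power - ap
  )
}

#' Plot a spectral fit in log-log space
#'
#' Observed log10 power, the full model, and the aperiodic component alone.
#'
#' @param object A `spectral_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_fit <- function(object, ...) {
  comp <- fit_components(object) |>
    tidyr::pivot_longer(c("observed", "model", "aperiodic"),
                        names_to = "component", values_to = "log_power")
  ggplot2::ggplot(comp, ggplot2::aes(log10(.data$freq), .data$log_power,
                                     colour = .data$component,
                                     linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(observed = "solid", model = "dashed", aperiodic = "dotted")
    ) +
    ggplot2::labs(x = "log10 frequency (Hz)", y = "log10 power",
                  title = sprintf("exponent = %.2f, R² = %.3f",
                                  object$aperiodic[["exponent"]],
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}
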