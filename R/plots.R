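#' Plot the electrode statistic map of a cluster test
#'
#' Draws each electrode at its montage position, colored by the electrode
#' statistic, with members of significant clusters outlined.
#'
#' @param object A `cluster_test`.
#' @param montage The [montage_adjacency()] the test was run with.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_test <- function(object, montage, ...) {
  df <- dplyr::left_join(montage$positions, object$electrode_stats,
                         by = "electrode")
  sig <- unique(unlist(object$clusters$electrodes[object$clusters$significant]))
  df$in_cluster <- df$electrode %in% sig
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$statistic,
                                     colour = .data$in_cluster,
                                     stroke = ifelse(.data$in_cluster, 1.5, 0.2)),
                        shape = 21, size = 5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"),
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s map (%d permutations)", object$stat,
                                  object$n_perm),
                  fill = object$stat) +
    ggplot2::theme_void()
}

#' Condition-mean exponent plot
#'
#' Mean +/- SEM of the brain-wide aperiodic exponent per drug x prime x
#' flanker cell, faceted by analysis period.
#'
#' @param brainwide A [brainwide_exponents()] table.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(brainwide) {
  cm <- brainwide |>
    dplyr::group_by(.data$drug, .data$period, .data$prime, .data$flanker) |>
    dplyr::summarise(mean = mean(.data$exponent),
                     sem = sd(.data$exponent) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(condition = paste0(substr(.data$prime, 1, 1), "/",
                                     substr(.data$flanker, 1, 1)))
  ggplot2::ggplot(cm, ggplot2::aes(.data$condition, .data$mean,
                                   colour = .data$drug, group = .data$drug)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2,
                           position = ggplot2::position_dodge(0.3)) +
    ggplot2::facet_wrap(~period) +
    ggplot2::labs(x = "prime/flanker congruency (c = congruent, i = incongruent)",
                  y = "aperiodic exponent (mean ± SEM)") +
    ggplot2::theme_minimal()
}
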