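#' Fully within-subject factorial ANOVA on subject-by-cell means
#'
#' For a design in which every factor has two within-subject levels, each
#' main effect and interaction has one numerator degree of freedom and is
#' equivalent to a paired t test on per-subject contrast scores: every
#' subject's cell means are combined with +/-1 product coding (scaled so a
#' main effect's score is the difference of that subject's marginal means),
#' and `F = (mean / SE)^2` with df (1, n-1). With two levels per factor the
#' Greenhouse-Geisser sphericity correction is an identity, so no epsilon
#' adjustment is applied. Partial eta squared is `F / (F + df2)`.
#'
#' Rows that share a subject and cell (e.g. electrodes) are averaged first.
#' Missing or unbalanced cells raise an error naming the offending cells.
#'
#' @param data Long tibble containing the subject column, the factor columns,
#'   and the dependent variable.
#' @param dv Name of the dependent variable column (default `"exponent"`).
#' @param within Character vector of within-subject factor names (each with
#'   exactly 2 levels).
#' @param subject Name of the subject identifier column (default
#'   `"participant"`).
#' @return An object of class `rm_anova_fit`; `tidy()` returns the effect
#'   table, `glance()` the design summary, and `$level_means` holds marginal
#'   mean +/- SEM per factor level.
#' @export
#' @examples
#' tbl <- tidyr::expand_grid(participant = 1:6, drug = c("placebo", "MPH"))
#' tbl$exponent <- 3.4 + 0.1 * (tbl$drug == "MPH") + rnorm(12, 0, 0.05)
#' tidy(rm_anova(tbl, within = "drug"))
rm_anova <- function(data, dv = "exponent", within, subject = "participant") {
  data <- as_tibble(data)
  for (col in c(dv, within, subject)) {
    if (!col %in% names(data)) {
      abort(sprintf("column `%s` not found.", col), class = "aperiodic_input_error")
    }
  }
  cellmeans <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(subject, within)))) |>
    dplyr::summarise(.y = mean(.data[[dv]]), .groups = "drop")

  levels_by_factor <- lapply(within, function(f) factor_level_order(cellmeans[[f]]))
  names(levels_by_factor) <- within
  for (f in within) {
    if (length(levels_by_factor[[f]]) != 2) {
      abort(sprintf("factor `%s` must have exactly 2 levels.", f),
            class = "aperiodic_input_error")
    }
  }
  subjects <- unique(cellmeans[[subject]])
  n <- length(subjects)
  if (n < 2) abort("need at least 2 subjects.", class = "aperiodic_input_error")

  full_grid <- tidyr::expand_grid(!!!c(
    setNames(list(subjects), subject), levels_by_factor
  ))
  merged <- dplyr::left_join(full_grid, cellmeans,
                             by = c(subject, within))
  if (anyNA(merged$.y)) {
    bad <- merged[is.na(merged$.y), c(subject, within)]
    abort(paste0("missing cells:\n",
                 paste(utils::capture.output(print(as.data.frame(bad))),
                       collapse = "\n")),
          class = "aperiodic_input_error")
  }

  # +1 for the second (alphabetically/canonically later) level of each factor
  codes <- purrr::map2_dfc(within, levels_by_factor, function(f, lev) {
    tibble(!!f := ifelse(merged[[f]] == lev[2], 1, -1))
  })
  n_cells <- prod(lengths(levels_by_factor))

  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, paste, collapse = ":", simplify = FALSE)
  }))
  rows <- purrr::map_dfr(effects, function(eff) {
    fs <- strsplit(eff, ":", fixed = TRUE)[[1]]
    w <- Reduce(`*`, lapply(fs, function(f) codes[[f]]))
    scores <- tapply(merged$.y * w, merged[[subject]], sum) / (n_cells / 2)
    est <- mean(scores)
    se <- sd(scores) / sqrt(n)
    tstat <- if (se == 0) ifelse(est == 0, 0, Inf) else est / se
    Fstat <- tstat^2
    p <- if (is.infinite(Fstat)) 0 else pf(Fstat, 1, n - 1, lower.tail = FALSE)
    tibble(
      effect = eff, estimate = est, F = Fstat, df1 = 1, df2 = n - 1,
      p = p, partial_eta_sq = if (is.infinite(Fstat)) 1 else Fstat / (Fstat + (n - 1))
    )
  })

  level_means <- purrr::map_dfr(within, function(f) {
    per_subject <- merged |>
      dplyr::group_by(.data[[subject]], .data[[f]]) |>
      dplyr::summarise(.y = mean(.data$.y), .groups = "drop")
    per_subject |>
      dplyr::group_by(level = .data[[f]]) |>
      dplyr::summarise(
        mean = mean(.data$.y),
        sem = sd(.data$.y) / sqrt(dplyr::n()),
        .groups = "drop"
      ) |>
      dplyr::mutate(factor = f, .before = 1)
  })

  structure(
    list(effects = rows, level_means = level_means, n_subjects = n,
         within = within, dv = dv, subject = subject),
    class = "rm_anova_fit"
  )
}

factor_level_order <- function(x) {
  canonical <- list(
    c("placebo", "MPH"),
    c("pre_trial", "within_trial"),
    c("congruent", "incongruent")
  )
  ux <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
  for (ord in canonical) {
    if (setequal(ux, ord)) return(ord)
  }
  ux
}

#' @export
print.rm_anova_fit <- function(x, ...) {
  cat(sprintf("<rm_anova_fit> %d x ", x$n_subjects))
  cat(paste(rep("2", length(x$within)), collapse = " x "),
      "within-subject ANOVA on", x$dv, "\n")
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' Effect table of a within-subject ANOVA
#'
#' @param x An `rm_anova_fit`.
#' @param ... Unused.
#' @return A tibble with `effect`, `estimate` (contrast in units of the
#'   dependent variable), `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
tidy.rm_anova_fit <- function(x, ...) {
  x$effects
}

#' @export
glance.rm_anova_fit <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_factors = length(x$within),
         n_effects = nrow(x$effects))
}

#' Follow-up ANOVAs within each level of a splitting factor
#'
#' Partitions the data by `split_by`, runs [rm_anova()] on the remaining
#' factors within every level, and Bonferroni-corrects the p-values by the
#' number of levels.
#'
#' @inheritParams rm_anova
#' @param split_by Factor to partition by (e.g. `"period"`).
#' @return A tibble of effect rows with a leading `split_by` level column and
#'   `p_bonferroni = min(1, n_levels * p)`; the fitted `rm_anova_fit` objects
#'   are kept in the `fits` attribute.
#' @export
follow_up_anovas <- function(data, split_by, dv = "exponent", within,
                             subject = "participant") {
  lev <- factor_level_order(data[[split_by]])
  within <- setdiff(within, split_by)
  fits <- lapply(lev, function(l) {
    rm_anova(data[data[[split_by]] == l, ], dv = dv, within = within,
             subject = subject)
  })
  names(fits) <- lev
  out <- purrr::map_dfr(lev, function(l) {
    dplyr::mutate(tidy(fits[[l]]), !!split_by := l, .before = 1)
  })
  out$p_bonferroni <- pmin(1, length(lev) * out$p)
  attr(out, "fits") <- fits
  out
}
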