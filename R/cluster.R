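#' Electrode-space cluster-based permutation test
#'
#' Paired two-condition test over electrodes with max-statistic family-wise
#' error control. Per electrode, the observed statistic is a paired t (or its
#' square, an F with df 1, n-1) on the within-subject condition differences.
#' Electrodes exceeding the `sample_alpha` threshold are grouped into
#' connected clusters on the montage adjacency (separately by sign for the t
#' variant) and each cluster's mass is the sum of its member statistics. The
#' null distribution of the maximum cluster mass is built by randomly
#' flipping the sign of every subject's difference vector (exact
#' exchangeability under the paired null); a cluster's Monte-Carlo p-value is
#' `(1 + #(null >= observed)) / (1 + n_perm)`, so the observed labeling
#' always counts and p is never zero.
#'
#' @param data Long tibble with columns `subject`, `electrode`, and either a
#'   precomputed `diff`, or `condition` + `value` with exactly two condition
#'   levels (the difference is first level minus second, using factor level
#'   order or sorted unique values).
#' @param montage A [montage_adjacency()] object covering all electrodes.
#' @param stat `"F"` (default, threshold alpha .005) or `"paired_t"`
#'   (two-sided threshold alpha .05).
#' @param sample_alpha Electrode-level threshold alpha; default depends on
#'   `stat` as above.
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param cluster_alpha Cluster significance level (default .05).
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `cluster_test` with per-electrode statistics,
#'   a cluster table, and the null max-mass distribution; see
#'   [tidy.cluster_test()].
#' @export
cluster_permutation_test <- function(data, montage, stat = c("F", "paired_t"),
                                     sample_alpha = NULL, n_perm = 1000,
                                     cluster_alpha = 0.05, seed = 1L) {
  stat <- match.arg(stat)
  sample_alpha <- sample_alpha %||% if (stat == "F") 0.005 else 0.05
  D <- paired_diff_matrix(data, montage$names)
  n <- nrow(D)
  if (n < 2) {
    abort("cluster test needs at least 2 subjects.", class = "aperiodic_input_error")
  }
  ne <- ncol(D)
  adj <- adjacency_index(montage)

  m <- colMeans(D)
  v <- (colSums(D^2) / n - m^2) * n / (n - 1)
  tval <- m / sqrt(v / n)
  tval[v == 0 & m == 0] <- 0

  crit_t <- qt(1 - sample_alpha / 2, n - 1)
  if (stat == "F") {
    stat_obs <- tval^2
    supra <- which(stat_obs > qf(1 - sample_alpha, 1, n - 1))
  } else {
    stat_obs <- tval
    supra <- which(abs(tval) > crit_t)
  }

  observed <- observed_clusters(stat_obs, supra, adj, stat, montage$names)

  # Null: sign-flip permutations, vectorized over electrodes. Sums of squares
  # are invariant under sign flips, so only the means need recomputing.
  ss_n <- colSums(D^2) / n
  null_max <- with_seed(derive_seed(seed, "clusterperm"), {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    M <- crossprod(S, D) / n
    V <- sweep(-M^2, 2, ss_n, "+") * n / (n - 1)
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    vapply(seq_len(n_perm), function(p) {
      max_cluster_mass(Tm[p, ], adj, stat, n, sample_alpha, crit_t)
    }, numeric(1))
  })

  if (nrow(observed)) {
    obs_mass <- abs(observed$mass)
    observed$p_value <- vapply(obs_mass, function(mm) {
      (1 + sum(null_max >= mm)) / (1 + n_perm)
    }, numeric(1))
    observed$significant <- observed$p_value <= cluster_alpha
  }

  structure(
    list(
      electrode_stats = tibble(
        electrode = montage$names, statistic = stat_obs,
        suprathreshold = seq_len(ne) %in% supra
      ),
      clusters = observed,
      null_max = null_max,
      stat = stat, sample_alpha = sample_alpha, n_perm = n_perm,
      cluster_alpha = cluster_alpha, n_subjects = n, seed = seed
    ),
    class = "cluster_test"
  )
}

# Wide subjects x electrodes matrix of paired differences, columns ordered by
# `electrode_names`.
paired_diff_matrix <- function(data, electrode_names) {
  data <- as_tibble(data)
  if (!"diff" %in% names(data)) {
    if (!all(c("condition", "value") %in% names(data))) {
      abort("`data` needs either a `diff` column or `condition` + `value`.",
            class = "aperiodic_input_error")
    }
    lev <- if (is.factor(data$condition)) levels(data$condition)
           else sort(unique(data$condition))
    if (length(lev) != 2) {
      abort("`condition` must have exactly two levels.",
            class = "aperiodic_input_error")
    }
    wide <- tidyr::pivot_wider(data, names_from = "condition",
                               values_from = "value")
    data <- dplyr::mutate(wide, diff = .data[[lev[1]]] - .data[[lev[2]]])
  }
  missing_el <- setdiff(data$electrode, electrode_names)
  if (length(missing_el)) {
    abort(sprintf("electrodes not in the montage: %s",
                  paste(missing_el, collapse = ", ")),
          class = "aperiodic_input_error")
  }
  wide <- tidyr::pivot_wider(
    data[, c("subject", "electrode", "diff")],
    names_from = "electrode", values_from = "diff"
  )
  if (!all(electrode_names %in% names(wide))) {
    abort("every montage electrode needs data.", class = "aperiodic_input_error")
  }
  M <- as.matrix(wide[, electrode_names])
  if (anyNA(M)) {
    abort("paired differences contain missing values.",
          class = "aperiodic_input_error")
  }
  M
}

observed_clusters <- function(stat_obs, supra, adj, stat, names) {
  rows <- list()
  if (stat == "F") {
    groups <- connected_groups(supra, adj)
    for (g in groups) {
      rows[[length(rows) + 1]] <- tibble(
        electrodes = list(names[g]), n_electrodes = length(g),
        mass = sum(stat_obs[g]), sign = "positive"
      )
    }
  } else {
    for (sgn in c(1, -1)) {
      side <- supra[sign(stat_obs[supra]) == sgn]
      for (g in connected_groups(side, adj)) {
        rows[[length(rows) + 1]] <- tibble(
          electrodes = list(names[g]), n_electrodes = length(g),
          mass = sum(stat_obs[g]),
          sign = if (sgn > 0) "positive" else "negative"
        )
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(electrodes = list(), n_electrodes = integer(),
           mass = numeric(), sign = character())
  }
  out$p_value <- rep(NA_real_, nrow(out))
  out$significant <- rep(FALSE, nrow(out))
  if (nrow(out)) out <- out[order(-abs(out$mass)), ]
  out
}

# Maximum |cluster mass| for one permutation's t-values.
max_cluster_mass <- function(tv, adj, stat, n, sample_alpha, crit_t) {
  if (stat == "F") {
    fv <- tv^2
    supra <- which(fv > crit_t^2)  # qf(1-a,1,df) == qt(1-a/2,df)^2
    if (!length(supra)) return(0)
    if (length(supra) == 1) return(fv[supra])
    max(vapply(connected_groups(supra, adj),
               function(g) sum(fv[g]), numeric(1)))
  } else {
    best <- 0
    for (sgn in c(1, -1)) {
      side <- which(sgn * tv > crit_t)
      if (!length(side)) next
      if (length(side) == 1) {
        best <- max(best, abs(tv[side]))
      } else {
        best <- max(best, vapply(connected_groups(side, adj),
                                 function(g) abs(sum(tv[g])), numeric(1)))
      }
    }
    best
  }
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> %s statistic, %d subjects, %d permutations, sample alpha %.3g\n",
    x$stat, x$n_subjects, x$n_perm, x$sample_alpha
  ))
  if (nrow(x$clusters) == 0) {
    cat("no suprathreshold electrodes\n")
  } else {
    print(tidy(x))
  }
  invisible(x)
}

#' Tidy the cluster table of a permutation test
#'
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return A tibble with one row per cluster: member electrodes (comma
#'   separated), size, mass, sign, Monte-Carlo p-value, significance flag.
#' @export
tidy.cluster_test <- function(x, ...) {
  if (nrow(x$clusters) == 0) {
    return(tibble(electrodes = character(), n_electrodes = integer(),
                  mass = numeric(), sign = character(),
                  p_value = numeric(), significant = logical()))
  }
  dplyr::mutate(x$clusters,
                electrodes = purrr::map_chr(.data$electrodes, paste,
                                            collapse = ","),
                .before = 1)
}

#' Drug-contrast cluster tests per condition and period
#'
#' For each prime x flanker combination and each analysis period, runs the
#' paired-t cluster permutation test on the within-subject MPH minus placebo
#' exponent differences, mirroring the electrode-specific drug analysis of a
#' two-session pharmaco-EEG design.
#'
#' @param exponents Long [exponent_table()] with `participant`, `drug`,
#'   `prime`, `flanker`, `period`, `electrode`, `exponent`.
#' @param montage A [montage_adjacency()] object.
#' @param contrast Two drug labels, difference is first minus second
#'   (default `c("MPH", "placebo")`).
#' @param ... Passed to [cluster_permutation_test()] (`stat` defaults to
#'   `"paired_t"` here).
#' @param seed Integer seed (a distinct stream is derived per map).
#' @return A tibble with one row per condition x period: columns `prime`,
#'   `flanker`, `period`, `n_significant`, a `test` list-column of
#'   `cluster_test` objects, and a `clusters` list-column of tidy tables.
#' @export
electrodewise_condition_tests <- function(exponents, montage,
                                          contrast = c("MPH", "placebo"),
                                          ..., seed = 1L) {
  cells <- tidyr::expand_grid(
    prime = unique(exponents$prime),
    flanker = unique(exponents$flanker),
    period = unique(exponents$period)
  )
  res <- purrr::pmap(cells, function(prime, flanker, period) {
    sub <- exponents[exponents$prime == prime & exponents$flanker == flanker &
                     exponents$period == period, ]
    wide <- tidyr::pivot_wider(
      sub[, c("participant", "electrode", "drug", "exponent")],
      names_from = "drug", values_from = "exponent"
    )
    dat <- tibble(
      subject = wide$participant, electrode = wide$electrode,
      diff = wide[[contrast[1]]] - wide[[contrast[2]]]
    )
    cluster_permutation_test(
      dat, montage, stat = "paired_t", ...,
      seed = derive_seed(seed, prime, flanker, period)
    )
  })
  cells$test <- res
  cells$clusters <- purrr::map(res, tidy)
  cells$n_significant <- purrr::map_int(res, ~ sum(.x$clusters$significant))
  cells
}
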