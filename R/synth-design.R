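#' Task design parameters
#'
#' Describes the factorial prime-flanker task: a two-session (placebo vs
#' methylphenidate, MPH) within-subject design in which every trial crosses
#' prime congruency with flanker congruency. Trials are equally divided into
#' blocks and the four prime x flanker conditions occur equally often within
#' every block.
#'
#' @param n_participants Number of participants (default 25).
#' @param sessions Character vector of the two drug labels, in session order.
#' @param n_trials Trials per session (default 384). Must be divisible by
#'   `n_blocks` and by the number of conditions, and each block must contain
#'   a whole number of trials per condition.
#' @param n_blocks Blocks per session (default 4).
#' @param accuracy Probability of a correct response, either a single value or
#'   a named vector over the four conditions (`"congruent/congruent"`, ...,
#'   prime first). Default 1 so all trials survive the correct-only filter.
#' @param rsi_jitter_ms Response-stimulus interval jitter bounds in ms.
#' @param event_timing_ms Named numeric vector of event durations in ms
#'   (fixation, prime, mask, target, response window).
#'
#' @return An object of class `task_design` (a named list).
#' @export
#' @examples
#' task_design()
task_design <- function(n_participants = 25,
                        sessions = c("placebo", "MPH"),
                        n_trials = 384,
                        n_blocks = 4,
                        accuracy = 1.0,
                        rsi_jitter_ms = c(1000, 1200),
                        event_timing_ms = c(fixation = 100, prime = 30, mask = 30,
                                            target = 100, response_window = 2000)) {
  conditions <- condition_grid()
  n_cond <- nrow(conditions)
  if (n_trials %% n_blocks != 0L) {
    abort("`n_trials` must be divisible by `n_blocks`.", class = "aperiodic_config_error")
  }
  if (n_trials %% n_cond != 0L || (n_trials / n_blocks) %% n_cond != 0L) {
    abort(sprintf(
      "`n_trials` must allow each of the %d conditions to occur equally often within every block.",
      n_cond
    ), class = "aperiodic_config_error")
  }
  if (length(sessions) != 2L) {
    abort("`sessions` must contain exactly two drug labels.", class = "aperiodic_config_error")
  }
  if (length(accuracy) == 1L) {
    accuracy <- setNames(rep(accuracy, n_cond), condition_labels(conditions))
  }
  if (any(accuracy < 0 | accuracy > 1)) {
    abort("`accuracy` values must lie in [0, 1].", class = "aperiodic_config_error")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      sessions = sessions,
      n_trials = as.integer(n_trials),
      n_blocks = as.integer(n_blocks),
      conditions = conditions,
      accuracy = accuracy,
      rsi_jitter_ms = rsi_jitter_ms,
      event_timing_ms = event_timing_ms
    ),
    class = "task_design"
  )
}

condition_grid <- function() {
  tidyr::expand_grid(
    prime = c("congruent", "incongruent"),
    flanker = c("congruent", "incongruent")
  )
}

condition_labels <- function(grid = condition_grid()) {
  paste(grid$prime, grid$flanker, sep = "/")
}

#' Generate a randomized trial table for the full study
#'
#' Instantiates a [task_design()] into a long trial table: every participant
#' completes both drug sessions, each session holds `n_trials` trials split
#' into equal blocks, and within every block the four prime x flanker
#' conditions appear equally often in seeded random order. Correctness is
#' drawn per trial from the design's per-condition accuracy.
#'
#' @param design A [task_design()] object.
#' @param seed Integer seed; identical seeds reproduce the table exactly.
#'
#' @return A tibble with columns `participant`, `session`, `drug`, `block`,
#'   `trial` (1-based index within session), `prime`, `flanker`, `correct`.
#' @export
#' @examples
#' d <- generate_design(task_design(n_participants = 2), seed = 1)
#' dplyr::count(d, participant, drug, prime, flanker)
generate_design <- function(design = task_design(), seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  per_block <- design$n_trials / design$n_blocks
  per_cond_block <- per_block / nrow(design$conditions)

  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(design$n_participants), function(p) {
      # drug order counterbalanced by randomizing which session gets which label
      drug_order <- sample(design$sessions)
      purrr::map_dfr(1:2, function(s) {
        blocks <- purrr::map_dfr(seq_len(design$n_blocks), function(b) {
          cells <- design$conditions[rep(seq_len(nrow(design$conditions)), per_cond_block), ]
          cells[sample(nrow(cells)), ]
        })
        blocks$block <- rep(seq_len(design$n_blocks), each = per_block)
        blocks$trial <- seq_len(design$n_trials)
        blocks$participant <- p
        blocks$session <- s
        blocks$drug <- drug_order[s]
        blocks
      })
    })
    acc <- design$accuracy[paste(rows$prime, rows$flanker, sep = "/")]
    rows$correct <- runif(nrow(rows)) < acc
    dplyr::select(
      as_tibble(rows),
      "participant", "session", "drug", "block", "trial", "prime", "flanker", "correct"
    )
  })
}
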