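EMOTION_CONDITIONS <- c("anger", "fear", "sad", "happy")
SHAPE_CONDITION <- "shapes"

#' Generate the pseudorandomized block paradigm
#'
#' Builds the emotional-faces block schedule: three blocks of each of the four
#' emotion conditions (twelve contiguous 1-s stimuli per block) and six
#' shape-control blocks (six 1-s stimuli per block), ordered pseudorandomly so
#' that no two consecutive blocks share a condition. Inter-block rest is
#' spread uniformly so the task fills the run.
#'
#' @param seed Integer seed; fully determines the schedule.
#' @param n_volumes Number of volumes in the run.
#' @param tr Repetition time in seconds.
#' @param include_identity_control Add three modeled-but-uncontrasted
#'   identity-morph control blocks (off by default).
#' @return A tibble with one row per 1-s stimulus: `onset`, `duration`,
#'   `trial_type`, `block`. Attributes `n_volumes` and `tr` record the run
#'   the schedule was built for.
#' @export
#' @examples
#' sched <- make_paradigm(seed = 1)
#' dplyr::n_distinct(sched$block) # 18 blocks
make_paradigm <- function(seed = 0, n_volumes = 378, tr = 2,
                          include_identity_control = FALSE) {
  assert_that(is_count(n_volumes, 2), "n_volumes must be an integer >= 2")
  assert_that(tr > 0, "tr must be positive")
  block_labels <- c(rep(EMOTION_CONDITIONS, each = 3), rep(SHAPE_CONDITION, 6))
  stim_per_block <- c(rep(12L, 12), rep(6L, 6))
  if (include_identity_control) {
    block_labels <- c(block_labels, rep("identity", 3))
    stim_per_block <- c(stim_per_block, rep(6L, 3))
  }
  ord <- with_seed(substream_seed(seed, "paradigm"), {
    repeat {
      cand <- sample.int(length(block_labels))
      if (!any(block_labels[cand][-1] == block_labels[cand][-length(cand)])) break
    }
    cand
  })
  labels <- block_labels[ord]
  n_stim <- stim_per_block[ord]
  durations <- n_stim # contiguous 1-s stimuli -> block length in seconds
  total <- n_volumes * tr
  rest <- total - sum(durations)
  assert_that(rest >= 0, "paradigm does not fit in the run")
  gap <- rest / (length(labels) + 1) # uniform fill: leading, inter-block, trailing rest
  block_onset <- gap + cumsum(c(0, head(durations + gap, -1)))
  purrr::map_dfr(seq_along(labels), function(b) {
    tibble(
      onset = block_onset[b] + seq_len(n_stim[b]) - 1,
      duration = 1,
      trial_type = labels[b],
      block = b
    )
  }) |>
    structure(n_volumes = as.integer(n_volumes), tr = tr)
}

# Block-level view of a stimulus schedule: one row per block.
schedule_blocks <- function(schedule) {
  schedule |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      onset = min(.data$onset),
      duration = sum(.data$duration),
      trial_type = .data$trial_type[1],
      .groups = "drop"
    )
}
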