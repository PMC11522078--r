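#' The multiplication problem set
#'
#' Builds the full crossing of multiplicands 12--14 with "easy" multipliers
#' 6--9 and "hard" multipliers 16--19: 24 unique problems, 12 per difficulty.
#' Easy and hard problems share the multiplicands (and the spoken operator),
#' so the two categories differ only in the second operand.
#'
#' @return A tibble with one row per problem and columns `multiplicand`,
#'   `multiplier`, `difficulty` (factor, `easy`/`hard`) and `correct_answer`.
#' @examples
#' generate_problem_set()
#' @export
generate_problem_set <- function() {
  easy <- tidyr::expand_grid(multiplicand = 12:14, multiplier = 6:9)
  hard <- tidyr::expand_grid(multiplicand = 12:14, multiplier = 16:19)
  dplyr::bind_rows(
    dplyr::mutate(easy, difficulty = "easy"),
    dplyr::mutate(hard, difficulty = "hard")
  ) |>
    dplyr::mutate(
      difficulty = factor(.data$difficulty, levels = c("easy", "hard")),
      correct_answer = .data$multiplicand * .data$multiplier
    )
}

# Fixed phase onsets (ms from trial onset) for the pre-response first part:
# 750 baseline, cue + 4000 anticipation, three 750 ms sounds, 6000 minimum
# response window. The second number ends at 7000 ms; no response is allowed
# before 13000 ms.
phase_constants <- function() {
  list(
    baseline1_onset   = 0,
    baseline_ms       = 750,
    cue_onset         = 750,
    anticipation_ms   = 4000,
    sound1_onset      = 4750,   # multiplicand
    sound2_onset      = 5500,   # operator ("times")
    sound3_onset      = 6250,   # multiplier
    sound_ms          = 750,
    second_number_offset = 7000,
    min_response_ms   = 6000,
    min_response_end  = 13000,
    # second part, relative to its own onset (= response_end)
    baseline2_ms      = 750,
    confirm_onset     = 750,
    wait_ms           = 4000,   # from confirmation-sound onset
    feedback_onset    = 4750,
    feedback_ms       = 4000,   # total, from feedback-sound onset
    second_part_ms    = 8750
  )
}

#' Complete a trial timeline given the response time
#'
#' The first part of a trial (baseline, cue, anticipation, the three sounds
#' and the minimum response window) has fixed onsets; everything after the
#' response is anchored to `response_end`. `rt_ms` is measured from the
#' offset of the second number and cannot undercut the 6000 ms minimum
#' response window.
#'
#' @param rt_ms Response time in ms from second-number offset (>= 6000).
#' @param iti_ms Inter-trial interval in ms.
#' @return A one-row tibble of phase onsets/durations in ms from trial onset.
#' @export
complete_timeline <- function(rt_ms, iti_ms) {
  pc <- phase_constants()
  if (any(rt_ms < pc$min_response_ms)) {
    stop("rt_ms must be >= the 6000 ms minimum response window")
  }
  response_end <- pc$second_number_offset + rt_ms
  tibble::tibble(
    cue_onset = pc$cue_onset,
    sound1_onset = pc$sound1_onset,
    sound2_onset = pc$sound2_onset,
    sound3_onset = pc$sound3_onset,
    second_number_offset = pc$second_number_offset,
    min_response_end = pc$min_response_end,
    response_end = response_end,
    part2_onset = response_end,
    confirm_onset = response_end + pc$confirm_onset,
    feedback_onset = response_end + pc$feedback_onset,
    trial_end = response_end + pc$second_part_ms,
    iti_ms = iti_ms
  )
}

#' Generate a randomized 72-trial session
#'
#' Each of the 24 problems is repeated three times in a seed-determined
#' random order (72 experimental trials, split into two contiguous blocks of
#' 36), preceded by four practice trials (two easy, two hard) that are
#' flagged and discarded from all analyses. Per-trial inter-trial intervals
#' are drawn uniformly in \[750, 1250\] ms.
#'
#' @param seed Integer seed; the same seed reproduces the same session.
#' @param participant Participant identifier stored in the output.
#' @return A tibble with one row per trial: `participant`, `trial`
#'   (0-based), `is_practice`, `block`, `cue`, `repetition`, the problem
#'   columns of [generate_problem_set()], and `iti_ms`.
#' @export
generate_session <- function(seed = 1L, participant = 1L) {
  problems <- generate_problem_set()
  rng <- derived_rng(seed, participant)
  order <- rng(function() sample.int(72L))
  itis <- rng(function() stats::runif(76L, 750, 1250))
  practice_idx <- rng(function() c(
    sample(which(problems$difficulty == "easy"), 2L),
    sample(which(problems$difficulty == "hard"), 2L)
  ))

  experimental <- problems[rep(seq_len(24L), each = 3L)[order], ]
  session <- dplyr::bind_rows(
    dplyr::mutate(problems[practice_idx, ], is_practice = TRUE),
    dplyr::mutate(experimental, is_practice = FALSE)
  )
  session |>
    dplyr::mutate(
      participant = participant,
      trial = seq_len(nrow(session)) - 1L,
      block = ifelse(.data$is_practice, 0L,
                     ifelse(cumsum(!.data$is_practice) <= 36L, 1L, 2L)),
      cue = .data$difficulty,
      iti_ms = itis[seq_len(nrow(session))],
      .before = 1L
    ) |>
    dplyr::group_by(.data$is_practice, .data$multiplicand, .data$multiplier) |>
    dplyr::mutate(repetition = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::relocate("is_practice", .after = "trial")
}

# Deterministic per-participant RNG stream derived from one root seed.
# Returns a closure that evaluates `f` under the derived stream without
# disturbing the caller's RNG state.
derived_rng <- function(seed, id) {
  derived <- (as.numeric(seed) * 48271 + as.numeric(id) * 69621) %% 2147483629
  state <- NULL
  first <- TRUE
  function(f) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (first) {
      set.seed(as.integer(derived))
      first <<- FALSE
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    out <- f()
    state <<- get(".Random.seed", envir = globalenv())
    out
  }
}
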