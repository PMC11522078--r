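test_that("invalid correlation matrices are rejected with a diagnostic", {
  R <- default_trait_correlations()
  Rbad <- R
  Rbad[1, 2] <- 0.95; Rbad[2, 1] <- 0.95; Rbad[1, 3] <- -0.9; Rbad[3, 1] <- -0.9
  Rbad[2, 3] <- 0.9; Rbad[3, 2] <- 0.9
  expect_error(cohort_config(target_correlations = Rbad), "eigenvalue")
  Rasym <- R; Rasym[1, 2] <- 0.1
  expect_error(cohort_config(target_correlations = Rasym), "symmetric")
  Rdiag <- R; diag(Rdiag) <- c(1, 1, 1, 1, 1, 2)
  expect_error(cohort_config(target_correlations = Rdiag), "diagonal")
})

test_that("an identity target yields uncorrelated traits", {
  R <- diag(6)
  dimnames(R) <- dimnames(default_trait_correlations())
  co <- simulate_cohort(cohort_config(n_participants = 5000, seed = 5,
                                      target_correlations = R))
  p <- co$participants
  cm <- stats::cor(p[, c("amas", "tai", "stai", "pmp", "acc_trait", "lat_trait")])
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.05))
})

test_that("questionnaire scores respect their ranges and sum their items", {
  co <- simulate_cohort(cohort_config(n_participants = 70, seed = 3))
  p <- co$participants
  expect_true(all(p$amas >= 9 & p$amas <= 45))
  expect_true(all(p$tai >= 20 & p$tai <= 80))
  expect_true(all(p$stai >= 20 & p$stai <= 80))
  expect_true(all(p$pmp >= 0 & p$pmp <= 30))
  expect_true(all(p$p_easy > 0 & p$p_easy < 1))
  expect_true(all(p$p_hard > 0 & p$p_hard < 1))
  # easy is easier than hard in expectation
  expect_gt(mean(p$p_easy), mean(p$p_hard))
  # totals equal item sums
  sums <- co$items |>
    dplyr::group_by(participant, questionnaire) |>
    dplyr::summarise(total = sum(response), .groups = "drop") |>
    tidyr::pivot_wider(names_from = questionnaire, values_from = total)
  expect_equal(sums$amas[order(sums$participant)], p$amas)
  expect_equal(sums$pmp[order(sums$participant)], p$pmp)
})

test_that("item internal consistency lands near its configured target", {
  co <- simulate_cohort(cohort_config(n_participants = 1500, seed = 8))
  targets <- c(amas = 0.89, tai = 0.93, stai = 0.90, pmp = 0.85)
  for (q in names(targets)) {
    wide <- co$items |>
      dplyr::filter(questionnaire == q) |>
      tidyr::pivot_wider(id_cols = participant, names_from = item,
                         values_from = response)
    expect_lt(abs(cronbach_alpha(wide[, -1]) - targets[[q]]), 0.05)
  }
})

test_that("a noiseless trial peaks exactly at the expected latency", {
  cfg <- cohort_config(n_participants = 1, seed = 1, innovation_sd_au = 0,
                       blink_rate_hz = 0, latency_jitter_sd = 0,
                       anticipation_gain = 0, error_gain = 0)
  co <- simulate_cohort(cfg)
  plan <- dplyr::filter(generate_session(1, 1), !is_practice, cue == "hard")[1, ]
  tr <- simulate_trial(co$participants[1, ], plan, cfg)
  peak_ms <- tr$samples$time_ms[which.max(tr$samples$pupil_au)]
  expected_ms <- 7000 + co$participants$lat_hard_s[1] * 1000
  expect_lte(abs(peak_ms - expected_ms), 2)
  expect_true(all(tr$samples$valid))
  expect_gte(tr$rt_ms, 6000)
})

test_that("with zero gain and zero noise the trace is exactly the baseline", {
  cfg <- cohort_config(n_participants = 1, seed = 2, dilation_gain_au = 0,
                       innovation_sd_au = 0, blink_rate_hz = 0)
  co <- simulate_cohort(cfg)
  plan <- dplyr::filter(generate_session(1, 1), !is_practice)[1, ]
  tr <- simulate_trial(co$participants[1, ], plan, cfg)
  expect_equal(tr$samples$pupil_au,
               rep(co$participants$baseline_au[1], nrow(tr$samples)))
})

test_that("blinks appear as invalid gaps at the configured rate", {
  cfg <- cohort_config(n_participants = 1, seed = 4, blink_rate_hz = 0.25)
  co <- simulate_cohort(cfg)
  plan <- dplyr::filter(generate_session(1, 1), !is_practice)[1, ]
  set.seed(7)
  tr <- simulate_trial(co$participants[1, ], plan, cfg)
  expect_gt(mean(!tr$samples$valid), 0)
  expect_true(all(tr$samples$pupil_au[!tr$samples$valid] == 0))
  cfg0 <- cohort_config(n_participants = 1, seed = 4, blink_rate_hz = 0)
  tr0 <- simulate_trial(co$participants[1, ], plan, cfg0)
  expect_equal(mean(!tr0$samples$valid), 0)
})

test_that("sample counts follow 500 Hz arithmetic and streams are reproducible", {
  s <- tiny_study()
  one <- dplyr::filter(s$samples, participant == 1, trial == 4)
  tl <- dplyr::filter(s$trials, participant == 1, trial == 4)
  expect_equal(nrow(one), tl$trial_end / 2)
  # regenerating the same config reproduces the study exactly
  s2 <- simulate_study(cohort_config(n_participants = 8, seed = 42),
                       n_trials = 12)
  expect_equal(s$samples$pupil_au, s2$samples$pupil_au)
  expect_equal(s$trials$accuracy, s2$trials$accuracy)
})

test_that("the epoched generator injects a cue effect only inside its window", {
  d <- simulate_epoched_cohort(n_participants = 60, n_trials = 40,
                               cue_amp = 1, seed = 21)
  w <- attr(d, "effect_window")
  expect_length(w, 2)
  by_cue <- d |>
    dplyr::group_by(time_s, cue) |>
    dplyr::summarise(m = mean(pupil), .groups = "drop") |>
    tidyr::pivot_wider(names_from = cue, values_from = m) |>
    dplyr::mutate(diff = hard - easy)
  inside <- by_cue$time_s >= w[1] & by_cue$time_s <= w[2]
  expect_gt(mean(by_cue$diff[by_cue$time_s == 6]), 0.8)
  expect_lt(max(abs(by_cue$diff[!inside])), 0.35)
  # null flag removes the coupling entirely
  d0 <- simulate_epoched_cohort(n_participants = 60, n_trials = 40,
                                cue_amp = 1, null = TRUE, seed = 21)
  by0 <- d0 |>
    dplyr::group_by(time_s, cue) |>
    dplyr::summarise(m = mean(pupil), .groups = "drop") |>
    tidyr::pivot_wider(names_from = cue, values_from = m)
  expect_lt(max(abs(by0$hard - by0$easy)), 0.35)
})
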