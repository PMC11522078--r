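test_that("fold assignment is deterministic and as even as possible", {
  tr72 <- tidyr::expand_grid(participant = 1:2, trial = 0:71)
  f <- assign_folds(tr72)
  counts <- dplyr::count(f, participant, fold)
  expect_true(all(counts$n == 24))
  expect_identical(f, assign_folds(tr72))
  tr70 <- tidyr::expand_grid(participant = 1L, trial = 0:69)
  f70 <- dplyr::count(assign_folds(tr70), fold)
  expect_equal(sort(f70$n, decreasing = TRUE), c(24, 23, 23))
})

test_that("timepoint models agree with an ordinary-regression oracle when
           between-participant variance is zero", {
  set.seed(10)
  n <- 400
  d <- tibble::tibble(
    participant = rep(1:20, each = n / 20),
    trial = rep(1:(n / 20), 20),
    x = stats::rnorm(n))
  d$pupil <- 0.3 * d$x + stats::rnorm(n)  # no participant effect at all
  ols <- summary(stats::lm(pupil ~ x, data = d))$coefficients
  for (m in c("satterthwaite", "normal")) {
    fit <- fit_timepoint_model(d, ~ x, df_method = m)
    expect_equal(unname(fit$t[fit$effect == "x"]), ols["x", "t value"],
                 tolerance = 0.02)
    expect_equal(unname(fit$estimate[fit$effect == "x"]), ols["x", "Estimate"],
                 tolerance = 0.02)
  }
  # identically-zero outcome: estimates collapse to zero
  d0 <- d; d0$pupil <- 0
  fit0 <- suppressWarnings(fit_timepoint_model(d0, ~ x, df_method = "normal"))
  expect_true(all(abs(fit0$estimate) < 1e-8))
})

test_that("simulated effects of known size are recovered without bias", {
  set.seed(11)
  reps <- 20
  est <- numeric(reps)
  for (i in 1:reps) {
    d <- tibble::tibble(participant = rep(1:20, each = 30),
                        trial = rep(1:30, 20),
                        x = rep(c(-0.5, 0.5), 300))
    d$pupil <- 0.4 * d$x + stats::rnorm(600, 0, 1) +
      rep(stats::rnorm(20, 0, 0.5), each = 30)
    est[i] <- fit_timepoint_model(d, ~ x, df_method = "normal")$estimate[2]
  }
  mc_se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.4), 2 * mc_se + 0.02)
})

test_that("consensus clusters equal a brute-force scan", {
  grid <- seq(0.5, 6, by = 0.5)
  base <- tidyr::expand_grid(rotation = 1:3, time_s = grid, effect = "x")
  # all |t| = 3: one cluster spanning the grid
  all3 <- dplyr::mutate(base, t = 3)
  cl <- consensus_clusters(all3)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start_s, cl$end_s), range(grid))
  # one rotation dipping to 1.9 at one timepoint splits the cluster there
  dip <- dplyr::mutate(all3, t = ifelse(rotation == 2 & time_s == 3, 1.9, t))
  cl2 <- consensus_clusters(dip)
  expect_equal(nrow(cl2), 2)
  expect_true(all(cl2$end_s < 3 | cl2$start_s > 3))
  # random t-fields match an independent scan
  set.seed(12)
  for (i in 1:10) {
    rnd <- dplyr::mutate(base, t = stats::rnorm(dplyr::n(), 0, 2.5))
    got <- consensus_clusters(rnd)
    hits <- tapply(abs(rnd$t), rnd$time_s, min) > 2
    r <- rle(as.vector(hits))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    expect_equal(nrow(got), sum(r$values))
    if (sum(r$values)) {
      expect_equal(got$start_s, grid[starts[r$values]])
      expect_equal(got$end_s, grid[ends[r$values]])
    }
  }
})

test_that("a strong injected cue effect is detected at its true window", {
  d <- simulate_epoched_cohort(n_participants = 16, n_trials = 24,
                               cue_amp = 0.8, seed = 31)
  w <- attr(d, "effect_window")
  cv <- crossvalidated_effect_test(d, ~ cue_c * amas_z)
  eff <- cv$effects[cv$effects$effect == "cue_c", ]
  expect_lt(eff$p, 0.05)
  expect_gt(eff$estimate, 0)
  sel <- cv$selection[cv$selection$effect == "cue_c", ]
  expect_true(all(sel$time_s >= w[1] & sel$time_s <= w[2]))
  # every trial contributes exactly one value to the final model
  expect_equal(unique(cv$effects$n_trials), 16 * 24)
  # consensus cluster for the cue overlaps the injected window
  ccl <- cv$clusters[cv$clusters$effect == "cue_c", ]
  expect_gt(nrow(ccl), 0)
  expect_true(any(ccl$start_s <= w[2] & ccl$end_s >= w[1]))
  # the whole analysis is a pure function of its inputs
  cv2 <- crossvalidated_effect_test(d, ~ cue_c * amas_z)
  expect_equal(cv$effects, cv2$effects)
  expect_equal(cv$selection, cv2$selection)
})

test_that("the liberal per-timepoint scan localizes effects and stays flat
           under constant outcomes", {
  d <- simulate_epoched_cohort(n_participants = 16, n_trials = 24,
                               cue_amp = 0.8, seed = 32)
  w <- attr(d, "effect_window")
  ls <- liberal_scan(d, ~ cue_c)
  m <- ls$minima[ls$minima$effect == "cue_c", ]
  expect_lt(m$p_min, 0.01)
  expect_true(m$time_s >= w[1] && m$time_s <= w[2])
  # constant outcome: non-intercept effects are null everywhere
  d0 <- d; d0$pupil <- 5
  ls0 <- suppressWarnings(liberal_scan(d0, ~ cue_c))
  t0 <- ls0$scan$t[ls0$scan$effect == "cue_c"]
  expect_true(all(abs(t0[is.finite(t0)]) < 1e-6))
})

test_that("per-timepoint mixed-model p-values are uniform under the null", {
  # fixed-timepoint p-values across independent null cohorts
  set.seed(13)
  ps <- numeric(120)
  for (i in seq_along(ps)) {
    d <- simulate_epoched_cohort(n_participants = 10, n_trials = 8,
                                 time_s = seq(1, 3, by = 1), null = TRUE,
                                 seed = 7000 + i)
    sc <- liberal_scan(d, ~ cue_c)$scan
    ps[i] <- sc$p[sc$effect == "cue_c" & sc$time_s == 2]
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
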