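test_that("artifact detection flags steps and extends runs by 100 ms", {
  # clean constant trace: nothing flagged
  expect_false(any(detect_artifacts(rep(5, 1000))))
  # single large step at t = 2000 ms on a noisy trace: masked interval
  # must cover [1900, 2100] ms
  set.seed(1)
  t_ms <- seq(0, 4000 - 2, by = 2)
  x <- 4000 + stats::rnorm(length(t_ms), 0, 5)
  x[t_ms >= 2000] <- x[t_ms >= 2000] + 50 * stats::mad(diff(x))
  mask <- detect_artifacts(x, sample_ms = 2)
  expect_true(all(mask[t_ms >= 1900 & t_ms <= 2100]))
  expect_false(mask[1])
  # all-missing trace: full mask with a warning
  expect_warning(m <- detect_artifacts(rep(5, 10), valid = rep(FALSE, 10)),
                 "missing")
  expect_true(all(m))
})

test_that("simulated blinks are caught by the default artifact settings", {
  cfg <- cohort_config(n_participants = 1, seed = 6, blink_rate_hz = 0.4)
  co <- simulate_cohort(cfg)
  plan <- dplyr::filter(generate_session(1, 1), !is_practice)[1, ]
  set.seed(11)
  tr <- simulate_trial(co$participants[1, ], plan, cfg)
  expect_gt(sum(!tr$samples$valid), 0)
  mask <- detect_artifacts(tr$samples$pupil_au, tr$samples$valid)
  expect_gte(mean(mask[!tr$samples$valid]), 0.95)
})

test_that("missing-data rejection uses a strict 40% rule", {
  expect_true(reject_missing(c(rep(TRUE, 41), rep(FALSE, 59))))
  expect_false(reject_missing(c(rep(TRUE, 40), rep(FALSE, 60))))
  expect_false(reject_missing(rep(FALSE, 100)))
})

test_that("gap interpolation is linear inside and flat at the edges", {
  t_ms <- seq(0, 198, by = 2)
  ramp <- 3 + 0.25 * t_ms
  mask <- rep(FALSE, 100); mask[40:60] <- TRUE
  expect_equal(interpolate_gaps(ramp, mask, t_ms), ramp)
  # edge gap: flat extrapolation from the first valid value
  mask2 <- rep(FALSE, 100); mask2[1:10] <- TRUE
  out <- interpolate_gaps(ramp, mask2, t_ms)
  expect_equal(out[1:10], rep(ramp[11], 10))
  # random masks on a smooth trace: reconstruction error below the noise floor
  set.seed(2)
  for (rep_i in 1:5) {
    x <- sin(seq(0, 2 * pi, length.out = 500)) * 100 + 4000
    m <- rep(FALSE, 500)
    m[sample(2:499, 60)] <- FALSE  # keep edges intact
    m[sample(2:499, 60)] <- TRUE
    out <- interpolate_gaps(x, m, seq_len(500) * 2)
    expect_lt(max(abs(out - x)), 1)
  }
})

test_that("spline smoothing passes lines and slow content, kills fast content", {
  t_ms <- seq(0, 20000 - 2, by = 2)
  line <- 2 + 0.001 * t_ms
  expect_equal(smooth_spline_trace(line, t_ms), line, tolerance = 1e-9)
  mid <- t_ms > 2000 & t_ms < 18000
  s10 <- smooth_spline_trace(sin(2 * pi * 10 * t_ms / 1000), t_ms)
  expect_lt(max(abs(s10[mid])), 0.1)   # >= 90% attenuation at 10 Hz
  s05 <- smooth_spline_trace(sin(2 * pi * 0.5 * t_ms / 1000), t_ms)
  expect_gt(max(abs(s05[mid])), 0.9)   # >= 90% preservation at 0.5 Hz
})

test_that("median binning equals a brute-force oracle", {
  expect_equal(downsample_median(rep(7, 100), seq(0, 198, 2))$pupil,
               rep(7, 8))
  b <- downsample_median(c(3, 9, 100), c(0, 10, 20), bin_ms = 25)
  expect_equal(b$pupil, 9)
  set.seed(3)
  for (rep_i in 1:10) {
    n <- sample(50:400, 1)
    t_ms <- sort(stats::runif(n, 0, 3000))
    x <- stats::rnorm(n)
    got <- downsample_median(x, t_ms, bin_ms = 25)
    # oracle: independent re-binning
    want <- vapply(split(x, floor(t_ms / 25)), stats::median, numeric(1))
    expect_equal(got$pupil, unname(want))
    expect_equal(got$bin_ms, as.numeric(names(want)) * 25)
  }
})

test_that("participant z-transform matches its two-pass definition", {
  set.seed(4)
  x <- stats::rnorm(500, 4000, 300)
  z <- ztransform_participant(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  expect_equal(z, (x - mean(x)) / stats::sd(x))
  # affine copies of the same trace z-transform identically
  expect_equal(ztransform_participant(3 + 0.5 * x), z)
  expect_error(ztransform_participant(rep(1, 10), participant = "P9"), "P9")
})

test_that("baseline alignment subtracts the first 750 ms and is idempotent", {
  t_ms <- seq(12.5, by = 25, length.out = 100)
  x <- c(rep(0.7, 30), stats::rnorm(70))
  al <- baseline_align(x, t_ms)
  expect_equal(al$baseline, 0.7)
  expect_equal(al$pupil[1:30], rep(0, 30))
  al2 <- baseline_align(al$pupil, t_ms)
  expect_equal(al2$pupil, al$pupil)
  expect_equal(al2$baseline, 0)
  # flat trial aligns to all zeros
  expect_equal(baseline_align(rep(2.2, 100), t_ms)$pupil, rep(0, 100))
  # fully missing baseline flags the trial
  expect_true(baseline_align(c(rep(NA, 30), stats::rnorm(70)),
                             t_ms)$rejected_baseline_missing)
})

test_that("extreme-baseline rejection applies the +/- 2 SD rule", {
  b <- c(0, 0, 0, 0, 10)
  want <- abs(b - mean(b)) > 2 * stats::sd(b)
  expect_equal(reject_extreme_baseline(b), want)
  expect_equal(reject_extreme_baseline(rep(1.5, 20)), rep(FALSE, 20))
  set.seed(5)
  g <- stats::rnorm(20000)
  expect_lt(abs(mean(reject_extreme_baseline(g)) - 2 * stats::pnorm(-2)), 0.01)
})

test_that("feature extraction finds the peak after the second number", {
  t_ms <- seq(12.5, by = 25, length.out = 800)
  x <- exp(-0.5 * ((t_ms - 12000) / 2000)^2)  # peak 5 s after 7000 ms offset
  f <- extract_features(x, t_ms, search_end_ms = 20000)
  expect_lte(abs(f$peak_latency_s - 5), 0.025)
  expect_equal(f$max_dilation, max(x[t_ms >= 7000 & t_ms <= 20000]))
  # monotone series peaks at the window end
  f2 <- extract_features(seq_along(t_ms) * 0.01, t_ms, search_end_ms = 15000)
  expect_equal(f2$peak_latency_s, (max(t_ms[t_ms <= 15000]) - 7000) / 1000)
  expect_warning(f3 <- extract_features(x, t_ms, search_start_ms = 30000,
                                        search_end_ms = 40000), "empty")
  expect_true(is.na(f3$max_dilation))
})

test_that("the full chain keeps QC books straight on a small cohort", {
  s <- tiny_study()
  pre <- tiny_preprocessed()
  # every non-practice trial is accounted for exactly once in the QC table
  expect_equal(nrow(pre$qc), sum(!s$trials$is_practice))
  expect_equal(sum(pre$qc$kept) + sum(pre$qc$rejected_missing |
                                        pre$qc$rejected_baseline),
               nrow(pre$qc))
  # epochs only contain kept trials and are baseline-aligned per part
  kept <- dplyr::filter(pre$qc, kept)
  expect_equal(nrow(dplyr::distinct(pre$epochs, participant, trial)),
               nrow(kept))
  base_means <- pre$epochs |>
    dplyr::filter(time_ms < 750) |>
    dplyr::group_by(participant, trial, part) |>
    dplyr::summarise(m = mean(pupil_z), .groups = "drop")
  expect_lt(max(abs(base_means$m)), 1e-9)
  # per-participant discard summary has the right shape
  expect_equal(nrow(pre$discard), 8)
  expect_true(all(pre$discard$discard_pct >= 0 & pre$discard$discard_pct <= 100))
})

test_that("group-level pupil dynamics recover the injected difficulty effects", {
  pre <- tiny_preprocessed()
  f <- pre$features
  # hard trials peak later and dilate more than easy trials on average
  expect_gt(mean(f$lat_hard - f$lat_easy), 0)
  expect_gt(mean(f$dil_hard - f$dil_easy), 0)
  expect_gt(mean(f$acc_easy - f$acc_hard, na.rm = TRUE), 0)
})
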