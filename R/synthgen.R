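#' Default between-participant trait correlation matrix
#'
#' Target correlations among the observed questionnaire totals (AMAS, TAI,
#' STAI, PMP) and the two continuous latent traits driving in-task behaviour
#' (`acc_trait`, expected accuracy; `lat_trait`, expected peak latency of
#' the pupil response). The AMAS row and the TAI/STAI--latency entries match
#' the values reported for the study cohort; the remaining pairs are
#' realistic defaults chosen once (see the methods vignette).
#'
#' @return A symmetric 6 x 6 correlation matrix with unit diagonal.
#' @export
default_trait_correlations <- function() {
  v <- c("amas", "tai", "stai", "pmp", "acc_trait", "lat_trait")
  R <- matrix(c(
    1.00,  0.41,  0.23, -0.30, -0.36,  0.48,
    0.41,  1.00,  0.55, -0.15, -0.12,  0.42,
    0.23,  0.55,  1.00, -0.05, -0.05,  0.14,
   -0.30, -0.15, -0.05,  1.00,  0.45, -0.35,
   -0.36, -0.12, -0.05,  0.45,  1.00, -0.40,
    0.48,  0.42,  0.14, -0.35, -0.40,  1.00), 6, 6,
    dimnames = list(v, v))
  R
}

# Questionnaire item-generation constants. `alpha_cont` is the internal
# consistency of the continuous item layer; it is set above the observed
# target so that, after the items are discretised, Cronbach's alpha of the
# categorical responses lands on `alpha_target`. `attenuation` is the
# correlation between the observed total and its latent trait (analytic
# sum-score shrinkage times the discretisation loss), pinned from a one-off
# large-n calibration; it is used to disattenuate the latent copula
# correlations so the *observed* totals hit the target matrix.
questionnaire_specs <- function() {
  list(
    amas = list(k = 9L,  levels = 5L, alpha_cont = 0.905, alpha_target = 0.89,
                probs = c(0.20, 0.25, 0.30, 0.15, 0.10), attenuation = 0.937),
    tai  = list(k = 20L, levels = 4L, alpha_cont = 0.945, alpha_target = 0.93,
                probs = c(0.25, 0.40, 0.25, 0.10), attenuation = 0.959),
    stai = list(k = 20L, levels = 4L, alpha_cont = 0.915, alpha_target = 0.90,
                probs = c(0.22, 0.36, 0.32, 0.10), attenuation = 0.946),
    pmp  = list(k = 30L, levels = 2L, alpha_cont = 0.930, alpha_target = 0.85,
                difficulty = seq(0.64, 0.97, length.out = 30L),
                attenuation = 0.877)
  )
}

#' Configuration of the synthetic cohort
#'
#' Bundles every tunable of the generative model: cohort size, the target
#' correlation structure among traits, questionnaire score ranges and
#' internal consistency, the pupil trace model (tonic baseline in arbitrary
#' eye-tracker units, gamma-shaped effort kernel, difficulty-dependent
#' amplitude and latency), the AR(1) measurement-noise model, and the blink
#' model. `null_cohort = TRUE` removes every anxiety--pupil and
#' difficulty--pupil coupling (flat amplitudes and latencies, no
#' anticipation or error-feedback bumps, difficulty-independent accuracy),
#' which is what the type-I-error simulations rely on.
#'
#' @param n_participants Number of participants.
#' @param seed Root RNG seed; per-participant streams are derived from it.
#' @param target_correlations Symmetric positive semi-definite correlation
#'   matrix over (amas, tai, stai, pmp, acc_trait, lat_trait).
#' @param null_cohort Remove all trait/difficulty couplings to the pupil.
#' @param baseline_mean_au,baseline_sd_au Tonic pupil baseline (arbitrary units).
#' @param dilation_gain_au Amplitude of the effort kernel for easy trials (a.u.);
#'   0 yields trace = baseline + noise exactly.
#' @param hard_gain_factor Multiplier on the amplitude for hard trials.
#' @param kernel_shape Shape of the gamma effort kernel.
#' @param anticipation_gain,error_gain Amplitudes of the cue-anticipation and
#'   error-feedback bumps, as fractions of `dilation_gain_au`.
#' @param latency_easy_s,latency_easy_sd,latency_hard_s,latency_hard_sd
#'   Between-participant mean/sd of expected peak latency (seconds from the
#'   offset of the second number).
#' @param latency_jitter_sd Trial-level latency jitter (s).
#' @param ar_phi,innovation_sd_au AR(1) noise at 500 Hz.
#' @param blink_rate_hz Blinks per second; 0 disables blinks.
#' @param blink_dur_ms Range of blink durations (ms).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 70L,
                          seed = 1L,
                          target_correlations = default_trait_correlations(),
                          null_cohort = FALSE,
                          baseline_mean_au = 4000,
                          baseline_sd_au = 600,
                          dilation_gain_au = 500,
                          hard_gain_factor = 1.25,
                          kernel_shape = 3,
                          anticipation_gain = 0.15,
                          error_gain = 0.30,
                          latency_easy_s = 8.9, latency_easy_sd = 3.0,
                          latency_hard_s = 15.5, latency_hard_sd = 6.4,
                          latency_jitter_sd = 2.0,
                          ar_phi = 0.99,
                          innovation_sd_au = 7,
                          blink_rate_hz = 0.25,
                          blink_dur_ms = c(100, 300)) {
  R <- target_correlations
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("target_correlations must be symmetric")
  if (!isTRUE(all.equal(unname(diag(R)), rep(1, nrow(R)))))
    stop("target_correlations must have a unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target_correlations is not positive semi-definite: smallest eigenvalue ",
         format(min(ev)))
  structure(
    list(n_participants = as.integer(n_participants), seed = seed,
         target_correlations = R, null_cohort = isTRUE(null_cohort),
         baseline_mean_au = baseline_mean_au, baseline_sd_au = baseline_sd_au,
         dilation_gain_au = dilation_gain_au, hard_gain_factor = hard_gain_factor,
         kernel_shape = kernel_shape, anticipation_gain = anticipation_gain,
         error_gain = error_gain,
         latency_easy_s = latency_easy_s, latency_easy_sd = latency_easy_sd,
         latency_hard_s = latency_hard_s, latency_hard_sd = latency_hard_sd,
         latency_jitter_sd = latency_jitter_sd,
         ar_phi = ar_phi, innovation_sd_au = innovation_sd_au,
         blink_rate_hz = blink_rate_hz, blink_dur_ms = blink_dur_ms),
    class = "cohort_config")
}

# disattenuate the target matrix to the latent scale and check it is still
# a valid correlation matrix
latent_correlations <- function(R) {
  qs <- questionnaire_specs()
  att <- c(amas = qs$amas$attenuation, tai = qs$tai$attenuation,
           stai = qs$stai$attenuation, pmp = qs$pmp$attenuation,
           acc_trait = 1, lat_trait = 1)
  att <- att[colnames(R)]
  RL <- R / outer(att, att)
  diag(RL) <- 1
  ev <- eigen(RL, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("disattenuated latent correlation matrix is not positive ",
         "semi-definite: smallest eigenvalue ", format(min(ev)),
         "; weaken the target correlations")
  RL
}

# categorical item responses with a one-factor structure: each item loads
# lambda on the questionnaire's latent trait, unique noise otherwise, and
# the continuous response is cut at fixed normal thresholds
draw_items <- function(z, spec) {
  n <- length(z)
  rbar <- spec$alpha_cont / (spec$k - spec$alpha_cont * (spec$k - 1))
  lam <- sqrt(rbar)
  y <- outer(z, rep(lam, spec$k)) +
    matrix(stats::rnorm(n * spec$k), ncol = spec$k) * sqrt(1 - lam^2)
  if (spec$levels == 2L) {
    resp <- t(t(y) > stats::qnorm(1 - spec$difficulty)) * 1L
  } else {
    th <- stats::qnorm(cumsum(spec$probs)[-spec$levels])
    resp <- matrix(findInterval(y, th) + 1L, ncol = spec$k)
  }
  resp
}

#' Simulate a cohort of participant profiles
#'
#' Draws latent traits from a Gaussian copula whose correlation matrix is
#' disattenuated so that the *observed* questionnaire totals reproduce the
#' configured target correlations, then maps them to item responses
#' (AMAS 9 items 1--5, TAI/STAI 20 items 1--4, PMP 30 binary items) at the
#' configured internal consistency, to per-difficulty accuracy
#' probabilities, expected peak latencies, and a tonic pupil baseline.
#'
#' @param config A [cohort_config()].
#' @return A list of class `pupil_cohort` with `participants` (one row per
#'   participant: questionnaire totals, latent traits, per-difficulty
#'   accuracy probabilities and expected latencies, tonic baseline) and
#'   `items` (long tibble of item-level responses).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  rng <- derived_rng(config$seed, 0L)
  rng(function() simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_participants
  RL <- latent_correlations(config$target_correlations)
  Z <- matrix(stats::rnorm(n * ncol(RL)), n) %*% chol(RL)
  colnames(Z) <- colnames(RL)
  qs <- questionnaire_specs()

  items <- list()
  totals <- list()
  for (q in names(qs)) {
    resp <- draw_items(Z[, q], qs[[q]])
    totals[[q]] <- rowSums(resp)
    items[[q]] <- tibble::tibble(
      participant = rep(seq_len(n), qs[[q]]$k),
      questionnaire = q,
      item = rep(seq_len(qs[[q]]$k), each = n),
      response = as.vector(resp))
  }

  acc <- Z[, "acc_trait"]
  lat <- Z[, "lat_trait"]
  if (config$null_cohort) {
    p_easy <- p_hard <- rep(0.75, n)
    lat_easy <- lat_hard <- rep(12.2, n)
  } else {
    p_easy <- stats::plogis(2.6 + 1.0 * acc)
    p_hard <- stats::plogis(0.55 + 1.5 * acc)
    lat_easy <- pmax(2, config$latency_easy_s + config$latency_easy_sd * lat)
    lat_hard <- pmax(3, config$latency_hard_s + config$latency_hard_sd * lat)
  }

  participants <- tibble::tibble(
    participant = seq_len(n),
    amas = totals$amas, tai = totals$tai, stai = totals$stai, pmp = totals$pmp,
    acc_trait = acc, lat_trait = lat,
    p_easy = p_easy, p_hard = p_hard,
    lat_easy_s = lat_easy, lat_hard_s = lat_hard,
    baseline_au = config$baseline_mean_au +
      config$baseline_sd_au * stats::rnorm(n))

  structure(list(participants = participants,
                 items = dplyr::bind_rows(items),
                 config = config),
            class = "pupil_cohort")
}

#' @export
print.pupil_cohort <- function(x, ...) {
  cat("Synthetic pupillometry cohort:", nrow(x$participants), "participants",
      if (x$config$null_cohort) "(null cohort: no injected couplings)" else "",
      "\n")
  print(x$participants, n = 5)
  invisible(x)
}

# AR(1) noise at the sampling rate via stats::filter (recursive)
ar1_noise <- function(n, phi, sd) {
  innov <- stats::rnorm(n, 0, sd)
  innov[1] <- stats::rnorm(1, 0, sd / sqrt(max(1 - phi^2, 1e-12)))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# gamma effort kernel normalized to peak 1 at `peak_ms`, rising from
# `onset_ms`; shape fixed, rate solved from the required mode
effort_kernel <- function(t_ms, onset_ms, peak_ms, shape) {
  mode_s <- (peak_ms - onset_ms) / 1000
  rate <- (shape - 1) / mode_s
  x <- pmax((t_ms - onset_ms) / 1000, 0)
  stats::dgamma(x, shape = shape, rate = rate) /
    stats::dgamma(mode_s, shape = shape, rate = rate)
}

#' Simulate one trial's raw 500 Hz pupil trace
#'
#' The trace is tonic baseline + dilation components + AR(1) noise sampled
#' every 2 ms. The main dilation component is a gamma-shaped effort kernel
#' rising from the onset of the spoken problem and peaking at the profile's
#' per-difficulty expected latency (plus trial jitter) after the offset of
#' the second number; its amplitude scales with difficulty. A smaller
#' anticipation bump follows hard cues and an error bump follows incorrect
#' feedback. Blinks are inserted as invalid gaps (pupil 0) flanked by
#' high-velocity edge samples. The vocal response time is the trial's peak
#' latency plus a response lag, floored at the 6000 ms minimum window.
#'
#' @param profile One row of `simulate_cohort()$participants`.
#' @param plan One row of [generate_session()].
#' @param config A [cohort_config()].
#' @return A list with `samples` (tibble: `time_ms`, `pupil_au`, `valid`),
#'   `timeline` (one-row tibble from [complete_timeline()]), `accuracy`
#'   (0/1) and `rt_ms`.
#' @export
simulate_trial <- function(profile, plan, config = cohort_config()) {
  hard <- plan$cue == "hard"
  base_lat <- if (hard) profile$lat_hard_s else profile$lat_easy_s
  jitter <- stats::rnorm(1, 0, config$latency_jitter_sd)
  lat_s <- max(1, base_lat + jitter)
  rt_ms <- max(6000, round((lat_s + 0.5 + stats::rexp(1, 1)) * 1000 / 2) * 2)
  tl <- complete_timeline(rt_ms, plan$iti_ms)
  pc <- phase_constants()

  p_acc <- if (hard) profile$p_hard else profile$p_easy
  accuracy <- stats::rbinom(1, 1, p_acc)

  t_ms <- seq(0, tl$trial_end - 2, by = 2)
  n <- length(t_ms)
  gain <- config$dilation_gain_au
  amp <- gain * if (hard && !config$null_cohort) config$hard_gain_factor else 1
  trace <- profile$baseline_au +
    amp * effort_kernel(t_ms, pc$sound1_onset,
                        pc$second_number_offset + lat_s * 1000,
                        config$kernel_shape)
  if (!config$null_cohort) {
    if (hard && config$anticipation_gain > 0) {
      trace <- trace + gain * config$anticipation_gain *
        effort_kernel(t_ms, pc$cue_onset, pc$cue_onset + 2000, 2.5)
    }
    if (accuracy == 0 && config$error_gain > 0) {
      trace <- trace + gain * config$error_gain *
        effort_kernel(t_ms, tl$feedback_onset, tl$feedback_onset + 1200, 2.5)
    }
  }
  trace <- trace + ar1_noise(n, config$ar_phi, config$innovation_sd_au)

  valid <- rep(TRUE, n)
  if (config$blink_rate_hz > 0) {
    dur_s <- tl$trial_end / 1000
    n_blinks <- stats::rpois(1, config$blink_rate_hz * dur_s)
    if (n_blinks > 0) {
      starts <- sort(stats::runif(n_blinks, 0, tl$trial_end))
      durs <- stats::runif(n_blinks, config$blink_dur_ms[1], config$blink_dur_ms[2])
      for (b in seq_len(n_blinks)) {
        core <- t_ms >= starts[b] & t_ms < starts[b] + durs[b]
        valid[core] <- FALSE
        trace[core] <- 0
        # steep partial-occlusion edges just outside the flagged gap
        edge <- (t_ms >= starts[b] - 20 & t_ms < starts[b]) |
          (t_ms >= starts[b] + durs[b] & t_ms < starts[b] + durs[b] + 20)
        trace[edge & valid] <- trace[edge & valid] * 0.4
      }
    }
  }

  list(samples = tibble::tibble(time_ms = t_ms, pupil_au = trace, valid = valid),
       timeline = tl, accuracy = accuracy, rt_ms = rt_ms)
}

#' Simulate a full study: cohort, sessions, and raw traces
#'
#' Convenience wrapper generating participant profiles, one randomized
#' session per participant, and a raw 500 Hz trace for every trial
#' (including the four practice trials, which downstream preprocessing
#' discards). Per-participant RNG streams are derived deterministically
#' from the root seed, so any participant can be regenerated independently.
#'
#' @param config A [cohort_config()].
#' @param n_trials Optional cap on experimental trials per participant
#'   (default the full 72); practice trials are always included.
#' @return A list of class `pupil_study`: `participants`, `items`, `trials`
#'   (session plan + timeline + accuracy + rt per trial), `samples`
#'   (long 500 Hz sample table), `config`.
#' @export
simulate_study <- function(config = cohort_config(), n_trials = 72L) {
  cohort <- simulate_cohort(config)
  parts <- cohort$participants
  trials <- vector("list", nrow(parts))
  samples <- vector("list", nrow(parts))
  for (i in seq_len(nrow(parts))) {
    session <- generate_session(config$seed, parts$participant[i])
    session <- dplyr::bind_rows(
      dplyr::filter(session, .data$is_practice),
      dplyr::slice_head(dplyr::filter(session, !.data$is_practice),
                        n = n_trials))
    rng <- derived_rng(config$seed, 1000L + parts$participant[i])
    sim <- rng(function()
      lapply(seq_len(nrow(session)), function(j)
        simulate_trial(parts[i, ], session[j, ], config)))
    trials[[i]] <- dplyr::bind_cols(
      session,
      dplyr::bind_rows(lapply(sim, function(s)
        dplyr::bind_cols(dplyr::select(s$timeline, -"iti_ms"),
                         tibble::tibble(accuracy = s$accuracy,
                                        rt_ms = s$rt_ms)))))
    samples[[i]] <- dplyr::bind_rows(lapply(seq_along(sim), function(j)
      dplyr::mutate(sim[[j]]$samples,
                    participant = parts$participant[i],
                    trial = session$trial[j], .before = 1)))
  }
  structure(list(participants = parts, items = cohort$items,
                 trials = dplyr::bind_rows(trials),
                 samples = dplyr::bind_rows(samples),
                 config = config),
            class = "pupil_study")
}

#' @export
print.pupil_study <- function(x, ...) {
  cat("Synthetic pupillometry study:", nrow(x$participants), "participants,",
      nrow(x$trials), "trials,", nrow(x$samples), "samples\n")
  invisible(x)
}

#' Fast generator of analysis-ready epoched cohorts
#'
#' Generates binned, z-scaled pupil series directly on a common timepoint
#' grid, skipping the raw 500 Hz layer. Used for inference-level
#' simulations (type-I error, power, selection accuracy) where hundreds of
#' replicate cohorts are needed. Each trial is a participant intercept plus
#' optional injected effects inside a known Gaussian time window plus AR(1)
#' noise across bins; with `null = TRUE` all effect amplitudes are zero, so
#' the pupil series is independent of cue and anxiety everywhere.
#'
#' @param n_participants,n_trials Cohort dimensions.
#' @param time_s Timepoint grid (seconds).
#' @param cue_amp Amplitude of the cue (hard - easy) effect inside the window.
#' @param amas_cue_amp Amplitude of the cue-by-anxiety interaction.
#' @param effect_center,effect_width Center/sd (s) of the injected Gaussian
#'   effect window; the ground-truth window is reported as an attribute.
#' @param peak_structure Add a per-trial gamma-like dilation bump whose peak
#'   time is later on hard trials (for latency-recovery checks).
#' @param null Zero all injected couplings.
#' @param ar_phi Serial correlation of the trial noise across neighbouring
#'   bins (AR(1) coefficient at the grid pitch). The default 0.08 is the
#'   correlation the raw-trace model (AR(1) with phi 0.99 at 500 Hz)
#'   induces between bins 0.5 s apart, so the fast generator matches the
#'   binned output of the full pipeline.
#' @param seed RNG seed.
#' @return A long tibble (participant, trial, cue, amas_z, fold-ready) with
#'   one row per trial x timepoint and attribute `effect_window` (the
#'   ground-truth interval in seconds).
#' @export
simulate_epoched_cohort <- function(n_participants = 20L, n_trials = 24L,
                                    time_s = seq(0.5, 12, by = 0.5),
                                    cue_amp = 0.6, amas_cue_amp = 0,
                                    effect_center = 6, effect_width = 1.5,
                                    peak_structure = FALSE,
                                    null = FALSE, ar_phi = 0.08, seed = 1L) {
  rng <- derived_rng(seed, 99L)
  rng(function() {
    if (null) cue_amp <- amas_cue_amp <- 0
    nt <- length(time_s)
    amas_z <- stats::rnorm(n_participants)
    b0 <- stats::rnorm(n_participants, 0, 0.5)
    grid <- tidyr::expand_grid(participant = seq_len(n_participants),
                               trial = seq_len(n_trials))
    grid$cue <- factor(ifelse(grid$trial %% 2L == 0L, "hard", "easy"),
                       levels = c("easy", "hard"))
    cue_c <- ifelse(grid$cue == "hard", 0.5, -0.5)
    w <- exp(-0.5 * ((time_s - effect_center) / effect_width)^2)
    n_cells <- nrow(grid)
    noise <- matrix(stats::rnorm(n_cells * nt, 0, 0.6), n_cells, nt)
    for (j in 2:nt) noise[, j] <- ar_phi * noise[, j - 1] + noise[, j]
    mu <- b0[grid$participant] +
      outer(cue_amp * cue_c + amas_cue_amp * cue_c * amas_z[grid$participant], w)
    if (peak_structure && !null) {
      peak_t <- ifelse(grid$cue == "hard", 8, 5) + stats::rnorm(n_cells, 0, 0.8)
      mu <- mu + 1.5 * exp(-0.5 * (outer(-peak_t, time_s, `+`) / 1.8)^2)
    }
    out <- tidyr::expand_grid(grid, time_s = time_s)
    out$pupil <- as.vector(t(mu + noise))
    out$amas_z <- amas_z[out$participant]
    out$cue_c <- ifelse(out$cue == "hard", 0.5, -0.5)
    attr(out, "effect_window") <- effect_center + c(-1, 1) * 2 * effect_width
    out
  })
}
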