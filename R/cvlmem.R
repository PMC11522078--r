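#' Deterministic fold assignment
#'
#' Assigns each participant's kept trials to `n_folds` folds by within-
#' participant trial rank: fold = (rank - 1) mod `n_folds` + 1. The split
#' is deterministic and as even as possible (72 trials give 24/24/24;
#' 70 give 24/23/23).
#'
#' @param trials A data frame with `participant` and `trial` columns (one
#'   row per trial).
#' @param n_folds Number of folds (default 3).
#' @return The input with a `fold` column added.
#' @export
assign_folds <- function(trials, n_folds = 3L) {
  trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(fold = (dplyr::row_number() - 1L) %% n_folds + 1L) |>
    dplyr::ungroup()
}

# pupil ~ fixed + (1 | participant)
lmem_formula <- function(fixed) {
  rhs <- paste(deparse(fixed[[length(fixed)]]), collapse = " ")
  stats::as.formula(paste("pupil ~", rhs, "+ (1 | participant)"))
}

#' Intercept-only mixed model at one timepoint
#'
#' Fits `pupil ~ fixed + (1 | participant)` (random intercept per
#' participant, no random slopes) by maximum likelihood and returns the
#' t-statistic of every fixed effect. Degrees of freedom are Satterthwaite
#' (generally fractional) or a normal approximation (`df = Inf`,
#' p from the standard normal), selectable; the normal path is used for
#' the fast per-timepoint scans.
#'
#' @param data Rows of one timepoint: `pupil`, `participant`, and the
#'   covariates named in `fixed`.
#' @param fixed One-sided formula of fixed effects, e.g. `~ cue_c * amas_z`.
#' @param df_method `"satterthwaite"` or `"normal"`.
#' @param reml Use REML instead of maximum likelihood.
#' @return A tibble with one row per fixed-effect term (intercept
#'   included): `effect`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
fit_timepoint_model <- function(data, fixed, df_method = c("satterthwaite", "normal"),
                                reml = FALSE) {
  df_method <- match.arg(df_method)
  f <- lmem_formula(fixed)
  if (stats::sd(data$pupil) == 0) {
    # degenerate constant outcome: every effect is exactly null
    effs <- c("(Intercept)", attr(stats::terms(fixed), "term.labels"))
    return(tibble::tibble(effect = effs,
                          estimate = c(data$pupil[1], rep(0, length(effs) - 1)),
                          se = 0, t = 0, df = NA_real_, p = 1))
  }
  if (df_method == "satterthwaite") {
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(f, data = data, REML = reml)))
    cf <- stats::coef(summary(fit))
    tibble::tibble(effect = rownames(cf), estimate = cf[, "Estimate"],
                   se = cf[, "Std. Error"], t = cf[, "t value"],
                   df = cf[, "df"], p = cf[, "Pr(>|t|)"])
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(f, data = data, REML = reml)))
    cf <- stats::coef(summary(fit))
    tibble::tibble(effect = rownames(cf), estimate = cf[, "Estimate"],
                   se = cf[, "Std. Error"], t = cf[, "t value"],
                   df = Inf, p = 2 * stats::pnorm(-abs(cf[, "t value"])))
  }
}

# Per-timepoint scan. Uses lme4::refit() when the set of usable rows at a
# timepoint matches the previously fitted one (the common complete-grid
# case), which avoids rebuilding the model structure thousands of times.
scan_timepoints <- function(data, fixed, df_method = "normal", reml = FALSE) {
  vars <- all.vars(fixed)
  tps <- sort(unique(data$time_s))
  fit0 <- NULL
  pat0 <- NULL
  out <- vector("list", length(tps))
  f <- lmem_formula(fixed)
  for (k in seq_along(tps)) {
    d <- data[data$time_s == tps[k], , drop = FALSE]
    use <- stats::complete.cases(d[, c("pupil", "participant", vars)])
    d <- d[use, , drop = FALSE]
    if (nrow(d) == 0) next
    pat <- paste(d$participant, d$trial)
    res <- tryCatch({
      if (df_method == "normal" && !is.null(fit0) && identical(pat, pat0)) {
        fit <- suppressWarnings(suppressMessages(lme4::refit(fit0, d$pupil)))
      } else if (df_method == "normal") {
        fit <- suppressWarnings(suppressMessages(
          lme4::lmer(f, data = d, REML = reml)))
        fit0 <- fit
        pat0 <- pat
      } else {
        fit <- suppressWarnings(suppressMessages(
          lmerTest::lmer(f, data = d, REML = reml)))
      }
      cf <- stats::coef(summary(fit))
      if (df_method == "normal") {
        tibble::tibble(time_s = tps[k], effect = rownames(cf),
                       estimate = cf[, "Estimate"], se = cf[, "Std. Error"],
                       t = cf[, "t value"], df = Inf,
                       p = 2 * stats::pnorm(-abs(cf[, "t value"])))
      } else {
        tibble::tibble(time_s = tps[k], effect = rownames(cf),
                       estimate = cf[, "Estimate"], se = cf[, "Std. Error"],
                       t = cf[, "t value"], df = cf[, "df"],
                       p = cf[, "Pr(>|t|)"])
      }
    }, error = function(e) NULL)
    out[[k]] <- res
  }
  dplyr::bind_rows(out)
}

#' Crossvalidated timepoint-selection mixed-model test
#'
#' For each of `n_folds` rotations, two folds form the training set on
#' which an intercept-only mixed model is fitted at every timepoint; the
#' timepoint with the peak |t| is selected per fixed effect. Trials of the
#' held-out fold then contribute their pupil value at the timepoint that
#' was selected without them, so that after all rotations every trial is
#' associated with exactly one pupil value per effect. A final
#' intercept-only mixed model over all trials yields the reported t, df
#' and p per effect (Satterthwaite df). Consensus clusters are maximal
#' contiguous runs of timepoints where all rotations show |t| above the
#' threshold; a confirmatory model on the within-cluster mean pupil value
#' is fitted for each cluster.
#'
#' @param data Long analysis table: `participant`, `trial`, `time_s`,
#'   `pupil`, covariates, and optionally `fold` (assigned by
#'   [assign_folds()] when absent).
#' @param fixed One-sided fixed-effects formula, e.g. `~ cue_c * amas_z`.
#' @param n_folds Number of folds/rotations (default 3).
#' @param threshold Consensus |t| threshold (default 2).
#' @param scan_df_method df method for the per-timepoint scans (`"normal"`
#'   default, for speed; selection only needs the peak |t|).
#' @param final_df_method df method for the final and confirmatory models.
#' @param reml Use REML rather than maximum likelihood.
#' @return An object of class `cv_lmem` with `effects` (final t/df/p per
#'   effect), `selection` (per-rotation selected timepoints),
#'   `timepoint_stats` (the full training-fold t fields), `clusters`,
#'   and `cluster_tests`.
#' @export
crossvalidated_effect_test <- function(data, fixed, n_folds = 3L, threshold = 2,
                                       scan_df_method = "normal",
                                       final_df_method = "satterthwaite",
                                       reml = FALSE) {
  if (!"fold" %in% names(data)) {
    folds <- assign_folds(dplyr::distinct(data, .data$participant, .data$trial),
                          n_folds)
    data <- dplyr::left_join(data, folds, by = c("participant", "trial"))
  }
  tps <- sort(unique(data$time_s))

  stats_all <- vector("list", n_folds)
  selection <- vector("list", n_folds)
  for (r in seq_len(n_folds)) {
    train <- data[data$fold != r, , drop = FALSE]
    stopifnot(all(train$fold != r))  # no-leakage guard
    st <- scan_timepoints(train, fixed, df_method = scan_df_method, reml = reml)
    st$rotation <- r
    stats_all[[r]] <- st
    selection[[r]] <- st |>
      dplyr::filter(.data$effect != "(Intercept)") |>
      dplyr::group_by(.data$effect) |>
      dplyr::slice_max(abs(.data$t), n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(rotation = r, .data$effect, .data$time_s, .data$t)
  }
  timepoint_stats <- dplyr::bind_rows(stats_all)
  selection <- dplyr::bind_rows(selection)

  # each trial contributes its pupil value at the timepoint selected by the
  # rotation in which that trial was held out
  effects_list <- unique(selection$effect)
  vars <- all.vars(fixed)
  final <- vector("list", length(effects_list))
  for (i in seq_along(effects_list)) {
    eff <- effects_list[i]
    sel <- selection[selection$effect == eff, ]
    picked <- dplyr::inner_join(
      data, dplyr::transmute(sel, fold = .data$rotation, .data$time_s),
      by = c("fold", "time_s"))
    picked <- picked[stats::complete.cases(picked[, c("pupil", vars)]), ]
    fit <- fit_timepoint_model(picked, fixed, df_method = final_df_method,
                               reml = reml)
    final[[i]] <- dplyr::mutate(dplyr::filter(fit, .data$effect == eff),
                                n_trials = nrow(picked))
  }
  effects <- dplyr::bind_rows(final)

  clusters <- consensus_clusters(timepoint_stats, threshold = threshold)
  cluster_tests <- NULL
  if (nrow(clusters) > 0) {
    ct <- vector("list", nrow(clusters))
    for (i in seq_len(nrow(clusters))) {
      win <- data$time_s >= clusters$start_s[i] & data$time_s <= clusters$end_s[i]
      winmean <- data[win, ] |>
        dplyr::group_by(dplyr::across(dplyr::all_of(
          c("participant", "trial", "fold", vars)))) |>
        dplyr::summarise(pupil = mean(.data$pupil, na.rm = TRUE),
                         .groups = "drop")
      fit <- fit_timepoint_model(winmean, fixed, df_method = final_df_method,
                                 reml = reml)
      ct[[i]] <- dplyr::mutate(
        dplyr::filter(fit, .data$effect == clusters$effect[i]),
        start_s = clusters$start_s[i], end_s = clusters$end_s[i])
    }
    cluster_tests <- dplyr::bind_rows(ct)
  }

  structure(list(effects = effects, selection = selection,
                 timepoint_stats = timepoint_stats, clusters = clusters,
                 cluster_tests = cluster_tests, fixed = fixed,
                 n_folds = n_folds, threshold = threshold,
                 n_timepoints = length(tps)),
            class = "cv_lmem")
}

#' @export
print.cv_lmem <- function(x, ...) {
  cat("Crossvalidated mixed-model timepoint selection (",
      x$n_folds, " folds, ", x$n_timepoints, " timepoints)\n", sep = "")
  print(x$effects)
  if (nrow(x$clusters)) {
    cat("consensus clusters (all rotations |t| > ", x$threshold, "):\n", sep = "")
    print(x$clusters)
  } else cat("no consensus clusters\n")
  invisible(x)
}

#' Consensus clusters across rotations
#'
#' Maximal contiguous runs of timepoints at which *every* rotation's
#' training-fold t-statistic exceeds the threshold in absolute value.
#'
#' @param timepoint_stats Tibble with `rotation`, `time_s`, `effect`, `t`
#'   (as produced inside [crossvalidated_effect_test()]).
#' @param threshold |t| threshold (default 2).
#' @return A tibble: `effect`, `start_s`, `end_s`, `n_timepoints`,
#'   `min_abs_t` (the smallest per-rotation-minimum |t| in the run).
#' @export
consensus_clusters <- function(timepoint_stats, threshold = 2) {
  n_rot <- length(unique(timepoint_stats$rotation))
  per_tp <- timepoint_stats |>
    dplyr::filter(.data$effect != "(Intercept)") |>
    dplyr::group_by(.data$effect, .data$time_s) |>
    dplyr::summarise(min_abs_t = ifelse(dplyr::n() == n_rot,
                                        min(abs(.data$t)), NA_real_),
                     .groups = "drop") |>
    dplyr::arrange(.data$effect, .data$time_s)

  out <- per_tp |>
    dplyr::group_by(.data$effect) |>
    dplyr::group_modify(function(d, key) {
      hit <- !is.na(d$min_abs_t) & d$min_abs_t > threshold
      if (!any(hit)) return(tibble::tibble())
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- which(r$values)
      tibble::tibble(start_s = d$time_s[starts[keep]],
                     end_s = d$time_s[ends[keep]],
                     n_timepoints = r$lengths[keep],
                     min_abs_t = vapply(keep, function(i)
                       min(d$min_abs_t[starts[i]:ends[i]]), numeric(1)))
    }) |>
    dplyr::ungroup()
  if (nrow(out) == 0)
    out <- tibble::tibble(effect = character(), start_s = numeric(),
                          end_s = numeric(), n_timepoints = integer(),
                          min_abs_t = numeric())
  out
}

#' Liberal per-timepoint scan
#'
#' The most liberal analysis variant: an intercept-only mixed model at
#' every timepoint on the full dataset, with no correction for multiple
#' comparisons; reports the whole p-value field and each effect's minimum
#' p with its location.
#'
#' @inheritParams crossvalidated_effect_test
#' @param df_method df method for the per-timepoint fits.
#' @return A list of class `liberal_scan`: `scan` (per-timepoint tibble)
#'   and `minima` (per effect: `p_min`, `time_s`).
#' @export
liberal_scan <- function(data, fixed, df_method = "normal", reml = FALSE) {
  sc <- scan_timepoints(data, fixed, df_method = df_method, reml = reml)
  minima <- sc |>
    dplyr::filter(.data$effect != "(Intercept)") |>
    dplyr::group_by(.data$effect) |>
    dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("effect", p_min = "p", "time_s")
  structure(list(scan = sc, minima = minima, fixed = fixed),
            class = "liberal_scan")
}

#' @export
print.liberal_scan <- function(x, ...) {
  cat("Per-timepoint mixed models, uncorrected; minimum p per effect:\n")
  print(x$minima)
  invisible(x)
}
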