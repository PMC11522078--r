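#' Time course of pupil dilation by cue and anxiety group
#'
#' Per-bin means with standard-error ribbons for the first part of the
#' trial, split by cue difficulty and a median split of a participant
#' trait (plotting aid only; inference elsewhere is parametric). Vertical
#' lines mark the phase onsets (cue, first sound, second-number offset,
#' minimum response end).
#'
#' @param epochs The `epochs` table of a `pupil_preprocessed`.
#' @param trials Trial table (for the cue).
#' @param participants Participant table holding `split_var`.
#' @param split_var Trait used for the median split (default `"amas"`).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(epochs, trials, participants, split_var = "amas") {
  pc <- phase_constants()
  grp <- participants |>
    dplyr::transmute(.data$participant,
                     group = median_split(.data[[split_var]]))
  d <- epochs |>
    dplyr::filter(.data$part == "first") |>
    dplyr::inner_join(dplyr::select(trials, "participant", "trial", "cue"),
                      by = c("participant", "trial")) |>
    dplyr::inner_join(grp, by = "participant") |>
    dplyr::group_by(.data$time_ms, .data$cue, .data$group) |>
    dplyr::summarise(m = mean(.data$pupil_z, na.rm = TRUE),
                     se = stats::sd(.data$pupil_z, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$pupil_z))),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms / 1000, y = .data$m,
                                  color = .data$cue, fill = .data$cue)) +
    ggplot2::geom_vline(xintercept = c(pc$cue_onset, pc$sound1_onset,
                                       pc$second_number_offset,
                                       pc$min_response_end) / 1000,
                        linetype = "dashed", color = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group,
                        labeller = ggplot2::labeller(
                          group = function(g) paste(split_var, g))) +
    ggplot2::labs(x = "time from trial onset (s)",
                  y = "pupil size (z, baseline-aligned)", color = "cue",
                  fill = "cue") +
    ggplot2::theme_minimal()
}

#' @describeIn power_curve Plot power against sample size, one curve per
#'   effect size.
#' @param object A `pupil_power` tibble.
#' @param ... Unused.
#' @method autoplot pupil_power
#' @export
autoplot.pupil_power <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$power,
                                       color = factor(.data$partial_r2))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = "sample size", y = "power",
                  color = expression(partial ~ R^2)) +
    ggplot2::theme_minimal()
}

#' @describeIn best_subset BIC of every subset against its size, best
#'   model highlighted.
#' @param object A `pupil_bsr`.
#' @param ... Unused.
#' @method autoplot pupil_bsr
#' @export
autoplot.pupil_bsr <- function(object, ...) {
  m <- dplyr::mutate(object$models, best = dplyr::row_number() == 1)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$n_predictors, y = .data$bic)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$best), show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$null_bic, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c("grey40", "red3")) +
    ggplot2::labs(x = "number of predictors", y = "BIC",
                  title = paste("best-subset regression of", object$outcome)) +
    ggplot2::theme_minimal()
}

#' @describeIn crossvalidated_effect_test Training-fold t-statistic fields
#'   per rotation with the consensus threshold and selected timepoints.
#' @param object A `cv_lmem`.
#' @param ... Unused.
#' @method autoplot cv_lmem
#' @export
autoplot.cv_lmem <- function(object, ...) {
  d <- dplyr::filter(object$timepoint_stats, .data$effect != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$t,
                                  color = factor(.data$rotation))) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$selection, size = 2) +
    ggplot2::facet_wrap(~effect, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "t statistic (training folds)",
                  color = "rotation") +
    ggplot2::theme_minimal()
}
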