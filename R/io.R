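#' Analysis configuration
#'
#' All tunables of the preprocessing and analysis chain in one validated
#' object. Defaults equal the protocol's stated constants where stated
#' (750 ms baselines, 100 ms gap extension, 40% missingness limit, 25 ms
#' bins, +/- 2 SD baseline rejection, 3 folds, consensus |t| > 2); the
#' velocity threshold (16 MAD units) and spline smoothing (spar 0.6,
#' 25 knots/s) are package defaults documented in the methods vignette.
#' Unknown arguments are rejected. The configuration is embedded (with its
#' hash) in every result bundle for provenance.
#'
#' @param sample_ms Sampling interval, ms (500 Hz = 2 ms).
#' @param velocity_k Artifact velocity threshold in MAD units.
#' @param extend_ms Artifact-run extension per side, ms.
#' @param missing_threshold Maximum tolerated missing fraction per trial.
#' @param spline_spar,knots_per_s Cubic smoothing-spline parameters.
#' @param bin_ms Downsampling bin width, ms.
#' @param baseline_ms Baseline window length, ms.
#' @param baseline_sd_limit Baseline rejection bound, SD units.
#' @param n_folds Crossvalidation folds.
#' @param consensus_threshold Consensus |t| threshold.
#' @param grid_step_s Analysis timepoint-grid pitch, seconds.
#' @param horizon_quantile First-part grid horizon as a quantile of the
#'   response-time distribution.
#' @param ... Rejected; catches misspelled keys.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(sample_ms = 2, velocity_k = 16, extend_ms = 100,
                            missing_threshold = 0.40,
                            spline_spar = 0.6, knots_per_s = 25,
                            bin_ms = 25, baseline_ms = 750,
                            baseline_sd_limit = 2,
                            n_folds = 3L, consensus_threshold = 2,
                            grid_step_s = 0.5, horizon_quantile = 0.9,
                            ...) {
  extra <- list(...)
  if (length(extra) > 0)
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  structure(list(sample_ms = sample_ms, velocity_k = velocity_k,
                 extend_ms = extend_ms, missing_threshold = missing_threshold,
                 spline_spar = spline_spar, knots_per_s = knots_per_s,
                 bin_ms = bin_ms, baseline_ms = baseline_ms,
                 baseline_sd_limit = baseline_sd_limit, n_folds = n_folds,
                 consensus_threshold = consensus_threshold,
                 grid_step_s = grid_step_s,
                 horizon_quantile = horizon_quantile),
            class = "analysis_config")
}

#' Configuration hash
#'
#' Stable hash of a configuration object, embedded in result bundles so a
#' result can be traced to the exact settings that produced it.
#'
#' @param config Any configuration object.
#' @return A character hash.
#' @export
config_hash <- function(config) rlang::hash(config)

# required columns per table kind
table_schemas <- function() {
  list(samples = c("participant", "trial", "time_ms", "pupil_au", "valid"),
       trials = c("participant", "trial", "is_practice", "cue",
                  "multiplicand", "multiplier", "iti_ms"),
       participants = c("participant", "amas", "tai", "stai", "pmp"),
       items = c("participant", "questionnaire", "item", "response"),
       features = c("participant", "baseline_ps_au", "max_dilation",
                    "peak_latency_s", "accuracy"))
}

#' Read a delimited study table with schema validation
#'
#' Columns are matched by header name (order-free). Missing required
#' columns or malformed rows abort with a message naming the columns or
#' the offending line.
#'
#' @param path CSV file path.
#' @param kind One of `"samples"`, `"trials"`, `"participants"`,
#'   `"items"`, `"features"`.
#' @return A tibble.
#' @export
read_study_table <- function(path, kind = names(table_schemas())) {
  kind <- match.arg(kind)
  required <- table_schemas()[[kind]]
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prb <- readr::problems(out)
  if (nrow(prb) > 0)
    stop("malformed rows in ", path, ": first problem at line ", prb$row[1],
         " (", prb$expected[1], ")")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0)
    stop("schema mismatch in ", path, ": missing columns ",
         paste(missing, collapse = ", "))
  out
}

#' Write a simulated study to delimited text files
#'
#' Writes `participants.csv`, `items.csv`, `trials.csv` and `samples.csv`
#' into `dir`. The files round-trip losslessly through [read_cohort()].
#'
#' @param study A `pupil_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$participants, file.path(dir, "participants.csv"))
  readr::write_csv(study$items, file.path(dir, "items.csv"))
  readr::write_csv(study$trials, file.path(dir, "trials.csv"))
  readr::write_csv(study$samples, file.path(dir, "samples.csv"))
  invisible(dir)
}

#' Read a study back from delimited text files
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list of class `pupil_study` (without a config).
#' @export
read_cohort <- function(dir) {
  structure(list(
    participants = read_study_table(file.path(dir, "participants.csv"),
                                    "participants"),
    items = read_study_table(file.path(dir, "items.csv"), "items"),
    trials = read_study_table(file.path(dir, "trials.csv"), "trials"),
    samples = read_study_table(file.path(dir, "samples.csv"), "samples")),
    class = "pupil_study")
}

#' Build the long analysis table for the timecourse models
#'
#' Takes the preprocessed first-part epochs onto a common timepoint grid
#' (every `grid_step_s`, up to the `horizon_quantile` of the response-time
#' distribution; trials that ended earlier are missing at later
#' timepoints and drop from those timepoints' fits), assigns folds, and
#' attaches sum-coded and z-scored covariates: `cue_c` (-0.5 easy / +0.5
#' hard), `amas_z`, `tai_z`, `stai_z` (z-scored questionnaire totals) and
#' `acc_c` (trial accuracy, 0/1 centered).
#'
#' @param pre A `pupil_preprocessed` from [preprocess_cohort()].
#' @param trials The trial table (for cue, accuracy, response times).
#' @param participants The participant table (questionnaire totals).
#' @param config An [analysis_config()].
#' @return A long tibble: participant, trial, fold, `time_s`, `pupil`,
#'   covariates.
#' @export
build_analysis_table <- function(pre, trials, participants,
                                 config = analysis_config()) {
  step_ms <- config$grid_step_s * 1000
  trials <- dplyr::filter(trials, !.data$is_practice)
  horizon <- stats::quantile(trials$response_end, config$horizon_quantile)
  tab <- pre$epochs |>
    dplyr::filter(.data$part == "first",
                  .data$bin_ms %% step_ms == 0,
                  .data$bin_ms <= horizon) |>
    dplyr::transmute(.data$participant, .data$trial,
                     time_s = .data$bin_ms / 1000, pupil = .data$pupil_z)
  covars <- trials |>
    dplyr::transmute(.data$participant, .data$trial,
                     cue_c = ifelse(.data$cue == "hard", 0.5, -0.5),
                     acc_c = .data$accuracy - mean(.data$accuracy))
  pcov <- participants |>
    dplyr::transmute(.data$participant,
                     amas_z = zscore(.data$amas),
                     tai_z = zscore(.data$tai),
                     stai_z = zscore(.data$stai))
  folds <- assign_folds(dplyr::distinct(tab, .data$participant, .data$trial),
                        config$n_folds)
  tab |>
    dplyr::inner_join(covars, by = c("participant", "trial")) |>
    dplyr::inner_join(pcov, by = "participant") |>
    dplyr::inner_join(folds, by = c("participant", "trial"))
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, feature extraction, the crossvalidated
#' timecourse models, best-subset regression of each anxiety questionnaire
#' on the performance and pupil features, and the psychometric
#' descriptives/correlations/clustering, returning one bundle with the
#' configuration and its hash embedded. Any stage failure aborts with the
#' stage name and the config hash.
#'
#' @param study A `pupil_study` (simulated or read from disk).
#' @param config An [analysis_config()].
#' @param fixed Fixed-effects formula for the timecourse models.
#' @param outcomes Questionnaire outcomes for the best-subset stage.
#' @return A list of class `pupil_pipeline`.
#' @export
run_pipeline <- function(study, config = analysis_config(),
                         fixed = ~ cue_c * amas_z,
                         outcomes = c("amas", "tai", "stai")) {
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed (config ", hash, "): ",
           conditionMessage(e), call. = FALSE))
  }
  pre <- stage("preprocess", preprocess_cohort(study$samples, study$trials,
                                               config))
  tab <- stage("analysis-table",
               build_analysis_table(pre, study$trials, study$participants,
                                    config))
  cv <- stage("timecourse", crossvalidated_effect_test(
    tab, fixed, n_folds = config$n_folds,
    threshold = config$consensus_threshold))
  feats <- dplyr::inner_join(pre$features, study$participants,
                             by = "participant")
  bsr <- stage("features", purrr::map(
    rlang::set_names(outcomes),
    function(o) best_subset(feats, o,
                            c("accuracy", "pmp", "baseline_ps_au",
                              "max_dilation", "peak_latency_s"))))
  psych <- stage("psychometrics", list(
    descriptives = describe_cohort(
      feats, vars = c("amas", "tai", "stai", "pmp", "accuracy",
                      "peak_latency_s", "max_dilation"),
      items = study$items),
    correlations = correlation_table(
      feats, c("amas", "tai", "stai", "pmp", "accuracy", "peak_latency_s")),
    difficulty_tests = list(
      accuracy = paired_t(feats$acc_easy, feats$acc_hard),
      latency = paired_t(feats$lat_easy, feats$lat_hard),
      dilation = paired_t(feats$dil_easy, feats$dil_hard)),
    clusters = cluster_ma_accuracy(feats)))
  structure(list(preprocessed = pre, analysis_table = tab, timecourse = cv,
                 best_subsets = bsr, psychometrics = psych,
                 features = feats, config = config, config_hash = hash),
            class = "pupil_pipeline")
}

#' @export
print.pupil_pipeline <- function(x, ...) {
  cat("Pupillometry analysis bundle (config ", x$config_hash, ")\n", sep = "")
  print(x$timecourse)
  cat("\nbest subset per outcome:\n")
  for (o in names(x$best_subsets))
    cat(" ", o, "->", x$best_subsets[[o]]$models$subset[1],
        "(BIC", round(x$best_subsets[[o]]$models$bic[1], 2), ")\n")
  invisible(x)
}

#' Write a pipeline result bundle as delimited text
#'
#' Writes the per-effect results, clusters, ranked model tables, feature
#' table, QC, descriptives and correlations as CSV, plus the configuration
#' (deparsed text) and its hash.
#'
#' @param bundle A `pupil_pipeline`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$timecourse$effects, file.path(dir, "effects.csv"))
  readr::write_csv(bundle$timecourse$clusters, file.path(dir, "clusters.csv"))
  for (o in names(bundle$best_subsets))
    readr::write_csv(bundle$best_subsets[[o]]$models,
                     file.path(dir, paste0("models_", o, ".csv")))
  readr::write_csv(bundle$features, file.path(dir, "features.csv"))
  readr::write_csv(bundle$preprocessed$qc, file.path(dir, "trial_qc.csv"))
  readr::write_csv(bundle$psychometrics$descriptives,
                   file.path(dir, "descriptives.csv"))
  readr::write_csv(bundle$psychometrics$correlations,
                   file.path(dir, "correlations.csv"))
  writeLines(c(paste("# config hash:", bundle$config_hash),
               deparse(unclass(bundle$config))),
             file.path(dir, "config.txt"))
  invisible(dir)
}
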