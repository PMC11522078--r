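#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with two-sided p from
#' t = r sqrt(n - 2) / sqrt(1 - r^2) on n - 2 df, and a 95% confidence
#' interval via the Fisher z transform,
#' tanh(atanh(r) +/- z_crit / sqrt(n - 3)). Perfectly correlated input
#' returns the degenerate interval \[r, r\].
#'
#' @param x,y Numeric vectors (n >= 4, finite, non-constant).
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `r`, `n`, `df`, `statistic`, `p_value`,
#'   `conf_low`, `conf_high`.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    return(tibble::tibble(r = sign(r), n = n, df = n - 2, statistic = Inf * sign(r),
                          p_value = 0, conf_low = sign(r), conf_high = sign(r)))
  }
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
  tibble::tibble(r = r, n = n, df = n - 2, statistic = tstat,
                 p_value = 2 * stats::pt(-abs(tstat), n - 2),
                 conf_low = ci[1], conf_high = ci[2])
}

#' Pairwise correlation table
#'
#' All pairwise Pearson correlations among the given columns, with
#' confidence intervals and significance markers (`***` p < .001, `**`
#' < .01, `*` < .05, `.` < .1).
#'
#' @param data A data frame.
#' @param vars Character vector of numeric columns (default: all numeric).
#' @return A tibble with one row per unordered pair.
#' @export
correlation_table <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, logical(1))]
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    dplyr::mutate(pearson_ci(data[[pr[1]]], data[[pr[2]]]),
                  var1 = pr[1], var2 = pr[2], .before = 1)
  }) |>
    dplyr::mutate(stars = dplyr::case_when(
      .data$p_value < .001 ~ "***", .data$p_value < .01 ~ "**",
      .data$p_value < .05 ~ "*", .data$p_value < .1 ~ ".", TRUE ~ ""))
}

#' Paired t test of easy vs hard summaries
#'
#' Classical paired t test (df = n - 1) of per-participant summaries under
#' the two difficulty conditions.
#'
#' @param easy,hard Paired numeric vectors.
#' @return A one-row tibble: `mean_easy`, `mean_hard`, `mean_diff`,
#'   `statistic`, `df`, `p_value`.
#' @export
paired_t <- function(easy, hard) {
  ok <- stats::complete.cases(easy, hard)
  easy <- easy[ok]; hard <- hard[ok]
  if (length(easy) < 2) stop("need at least 2 pairs")
  if (stats::sd(easy - hard) == 0) {
    if (all(hard == easy)) {
      # identical conditions: no effect, by convention t = 0
      return(tibble::tibble(mean_easy = mean(easy), mean_hard = mean(hard),
                            mean_diff = 0, statistic = 0,
                            df = length(easy) - 1, p_value = 1))
    }
    stop("zero variance of paired differences")
  }
  tt <- stats::t.test(hard, easy, paired = TRUE)
  tibble::tibble(mean_easy = mean(easy), mean_hard = mean(hard),
                 mean_diff = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
}

#' Cronbach's alpha
#'
#' Internal consistency alpha = k/(k-1) (1 - sum of item variances /
#' variance of the total score).
#'
#' @param items A numeric matrix or data frame, respondents x items
#'   (>= 2 items, >= 2 respondents).
#' @return Alpha (scalar).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2 || nrow(items) < 2) stop("need >= 2 items and >= 2 respondents")
  vt <- stats::var(rowSums(items))
  if (vt == 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

# moment-based skewness and excess kurtosis (bias-uncorrected)
moment_skew <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}
moment_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^4) / s^4 - 3
}

#' Descriptive statistics table
#'
#' Mean, median, SD, range, moment skewness, excess kurtosis and (where
#' item-level responses are supplied) Cronbach's alpha for each measure.
#'
#' @param data Per-participant table.
#' @param vars Columns to describe (default: all numeric except
#'   `participant`).
#' @param items Optional long item table (`participant`, `questionnaire`,
#'   `item`, `response`) for the alpha column.
#' @return A tibble with one row per measure.
#' @export
describe_cohort <- function(data, vars = NULL, items = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    "participant")
  out <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    tibble::tibble(measure = v, mean = mean(x, na.rm = TRUE),
                   median = stats::median(x, na.rm = TRUE),
                   sd = stats::sd(x, na.rm = TRUE),
                   min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
                   skew = moment_skew(x), kurtosis = moment_kurtosis(x))
  })
  if (!is.null(items)) {
    alphas <- items |>
      dplyr::group_by(.data$questionnaire) |>
      dplyr::group_modify(function(d, key) {
        wide <- tidyr::pivot_wider(d, id_cols = "participant",
                                   names_from = "item",
                                   values_from = "response")
        tibble::tibble(alpha = cronbach_alpha(wide[, -1]))
      }) |>
      dplyr::ungroup() |>
      dplyr::rename(measure = "questionnaire")
    out <- dplyr::left_join(out, alphas, by = "measure")
  }
  out
}

#' k-means clustering of anxiety and accuracy
#'
#' Standardizes the chosen features and runs best-of-`n_restarts` k-means
#' (default k = 2), to ask whether the cohort splits into a
#' high-anxiety/low-accuracy and a low-anxiety/high-accuracy subgroup.
#' The cluster labelled 1 is the one with the higher mean on the first
#' feature, so solutions are comparable across runs.
#'
#' @param data Per-participant table.
#' @param vars Features to cluster on (standardized internally).
#' @param k Number of clusters.
#' @param seed RNG seed for the restarts.
#' @param n_restarts Random restarts (best inertia kept).
#' @return An object of class `pupil_clusters`: `assignments` (tibble of
#'   participant, cluster), `centers` (standardized), `centers_raw`
#'   (original units), `inertia`, `sizes`, `k`, `seed`.
#' @export
cluster_ma_accuracy <- function(data, vars = c("amas", "accuracy"), k = 2L,
                                seed = 123L, n_restarts = 50L) {
  stopifnot(all(vars %in% names(data)))
  X <- scale(as.matrix(data[, vars]))
  if (nrow(X) < k) stop("fewer observations than clusters")
  rng <- derived_rng(seed, 7L)
  km <- rng(function() stats::kmeans(X, centers = k, nstart = n_restarts))
  # relabel so cluster 1 has the higher mean on the first feature
  ord <- order(km$centers[, 1], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  assign <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  centers_raw <- t(t(centers) * attr(X, "scaled:scale") +
                     attr(X, "scaled:center"))
  structure(list(
    assignments = tibble::tibble(participant = data$participant,
                                 cluster = assign),
    centers = centers, centers_raw = centers_raw,
    inertia = km$tot.withinss, sizes = tabulate(assign, k),
    k = k, vars = vars, seed = seed),
    class = "pupil_clusters")
}

#' @export
print.pupil_clusters <- function(x, ...) {
  cat("k-means (k =", x$k, ") on standardized", paste(x$vars, collapse = ", "),
      "; sizes:", paste(x$sizes, collapse = "/"), "\n")
  cat("cluster centers (original units):\n")
  print(round(x$centers_raw, 2))
  invisible(x)
}

#' Median-split labels
#'
#' Labels observations `low`/`high` by the median (used only for plotting;
#' all inference in the pipeline is parametric).
#'
#' @param x Numeric vector.
#' @return A factor with levels `low`, `high`.
#' @export
median_split <- function(x) {
  factor(ifelse(x > stats::median(x, na.rm = TRUE), "high", "low"),
         levels = c("low", "high"))
}
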