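#' z-score a vector (n-1 denominator)
#'
#' @param x Numeric vector.
#' @return `x` centered and scaled to unit sample variance.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

#' BIC of the intercept-only Gaussian model
#'
#' Gaussian maximum-likelihood BIC of the null (intercept-only) regression,
#' counting intercept plus residual variance as parameters:
#' BIC = -2 logLik + 2 ln(n) with the ML variance SSE/n. Because the
#' outcome is z-scored before modelling, the null BIC depends only on n:
#' at n = 70 it is 206.14 for *any* outcome.
#'
#' @param outcome Numeric outcome vector, z-scored (n-1 denominator).
#' @return The BIC (scalar).
#' @export
null_bic <- function(outcome) {
  if (length(outcome) < 3) stop("need at least 3 observations")
  stats::BIC(stats::lm(outcome ~ 1))
}

#' BIC-approximate Bayes factor
#'
#' Evidence for model A over model B from their BICs:
#' BF(A, B) = exp((BIC_B - BIC_A) / 2), the unit-information-prior
#' approximation that lets BIC differences be read directly as strength of
#' evidence. Antisymmetric (BF(A,B) * BF(B,A) = 1) and transitive.
#'
#' @param bic_a,bic_b BICs of the two models (finite; vectorized).
#' @return The Bayes factor favoring A.
#' @export
bayes_factor <- function(bic_a, bic_b) {
  stopifnot(all(is.finite(bic_a)), all(is.finite(bic_b)))
  exp((bic_b - bic_a) / 2)
}

#' Best-subset regression ranked by BIC
#'
#' Fits all 2^p ordinary least-squares models over subsets of the
#' predictors (including the null model) for a z-scored outcome, and ranks
#' them by BIC. Complexity is penalized by the BIC's k ln(n) term, and BIC
#' differences convert to Bayes factors against the null. Leave-one-out
#' crossvalidated R-squared is computed per subset. Predictors are used on
#' their native scales; only the outcome is z-scored.
#'
#' @param data Per-participant feature table.
#' @param outcome Name of the outcome column (z-scored internally).
#' @param predictors Character vector of predictor columns (at most 15).
#' @param compute_cv Also compute LOO cv-R-squared per subset.
#' @return An object of class `pupil_bsr`; its `models` tibble has one row
#'   per subset (`subset`, `n_predictors`, `r2`, `adj_r2`, `bic`,
#'   `loglik`, `bf_vs_null`, `cv_r2`, `cv_r2_raw`), ranked by BIC.
#' @export
best_subset <- function(data, outcome, predictors, compute_cv = TRUE) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  p <- length(predictors)
  if (p > 15) stop("at most 15 predictors supported (2^p models)")
  d <- data[stats::complete.cases(data[, c(outcome, predictors)]), ]
  n <- nrow(d)
  if (n < p + 3)
    stop("need at least ", p + 3, " complete observations to fit the ",
         "largest subset with a residual degree of freedom")
  y <- zscore(d[[outcome]])
  d$.y <- y

  qrx <- qr(as.matrix(cbind(1, d[predictors])))
  if (qrx$rank < p + 1)
    warning("predictors are collinear; least-squares fits still returned")

  subsets <- lapply(0:(2^p - 1), function(m) predictors[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
  rows <- lapply(subsets, function(s) {
    f <- if (length(s)) stats::reformulate(s, ".y") else .y ~ 1
    fit <- stats::lm(f, data = d)
    sm <- summary(fit)
    cv <- if (compute_cv) loo_cv(d, ".y", s, z_outcome = FALSE) else
      list(cv_r2 = NA_real_, cv_r2_raw = NA_real_)
    tibble::tibble(
      subset = if (length(s)) paste(s, collapse = " + ") else "(null)",
      n_predictors = length(s),
      r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
      bic = stats::BIC(fit), loglik = as.numeric(stats::logLik(fit)),
      cv_r2 = cv$cv_r2, cv_r2_raw = cv$cv_r2_raw)
  })
  models <- dplyr::bind_rows(rows)
  bic0 <- models$bic[models$subset == "(null)"]
  models$bf_vs_null <- bayes_factor(models$bic, bic0)
  models <- dplyr::arrange(models, .data$bic)
  structure(list(models = models, outcome = outcome, predictors = predictors,
                 n = n, null_bic = bic0),
            class = "pupil_bsr")
}

#' @export
print.pupil_bsr <- function(x, ...) {
  cat("Best-subset regression of", x$outcome, "(z-scored), n =", x$n, "\n")
  cat("null BIC:", round(x$null_bic, 2), "\n")
  print(x$models, n = 8)
  invisible(x)
}

#' Leave-one-subject-out crossvalidated R-squared
#'
#' Each participant is predicted from a model fitted on the other n - 1;
#' cv-R2 = 1 - sum((y_i - yhat_-i)^2) / sum((y_i - ybar)^2), with ybar the
#' full-sample mean. The reported `cv_r2` is floored at 0 (a model with no
#' out-of-sample skill reports 0); the raw value is also returned.
#'
#' @param data Feature table.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor columns (may be empty:
#'   the null model predicts the training mean).
#' @param z_outcome z-score the outcome first (default TRUE).
#' @return A list: `cv_r2` (floored), `cv_r2_raw`, `predictions` tibble.
#' @export
loo_cv <- function(data, outcome, predictors = character(), z_outcome = TRUE) {
  d <- data[stats::complete.cases(data[, c(outcome, predictors)]), ]
  n <- nrow(d)
  if (n < 3) stop("need at least 3 observations")
  y <- d[[outcome]]
  if (z_outcome) y <- zscore(y)
  d$.y <- y
  f <- if (length(predictors)) stats::reformulate(predictors, ".y") else .y ~ 1
  yhat <- vapply(seq_len(n), function(i) {
    fit <- stats::lm(f, data = d[-i, , drop = FALSE])
    unname(stats::predict(fit, newdata = d[i, , drop = FALSE]))
  }, numeric(1))
  raw <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(cv_r2 = max(0, raw), cv_r2_raw = raw,
       predictions = tibble::tibble(observed = y, predicted = yhat))
}

#' R-squared and adjusted R-squared from an F statistic
#'
#' Recovers R2 = uF / (uF + v) and adjusted R2 = 1 - (1 - R2)(u + v) / v
#' from a regression F statistic with u numerator and v denominator
#' degrees of freedom.
#'
#' @param f F statistic (>= 0).
#' @param u,v Numerator / denominator degrees of freedom (>= 1).
#' @return A one-row tibble: `r2`, `adj_r2`.
#' @export
adj_r2_from_f <- function(f, u, v) {
  stopifnot(all(f >= 0), all(u >= 1), all(v >= 1))
  r2 <- u * f / (u * f + v)
  tibble::tibble(r2 = r2, adj_r2 = 1 - (1 - r2) * (u + v) / v)
}

#' Power curves for a multivariate regression design
#'
#' Statistical power of the F test of a (partial) R-squared across a grid
#' of sample sizes, from the noncentral F distribution with
#' f2 = partial_r2 / (1 - partial_r2) and noncentrality
#' lambda = f2 (u + v + 1) (Cohen's convention) or lambda = f2 n
#' (total-N convention); v = n - u - 1.
#'
#' @param n Vector of sample sizes.
#' @param partial_r2 Vector of effect sizes in (0, 1).
#' @param u Numerator degrees of freedom (number of tested predictors).
#' @param alpha Type-I error rate.
#' @param convention `"cohen"` or `"total_n"`.
#' @return A tibble of class `pupil_power`: `n`, `partial_r2`, `u`,
#'   `alpha`, `power`.
#' @export
power_curve <- function(n, partial_r2, u = 1, alpha = 0.05,
                        convention = c("cohen", "total_n")) {
  convention <- match.arg(convention)
  stopifnot(all(partial_r2 > 0), all(partial_r2 < 1))
  grid <- tidyr::expand_grid(n = n, partial_r2 = partial_r2, u = u)
  grid <- dplyr::filter(grid, .data$n - .data$u - 1 >= 1)
  v <- grid$n - grid$u - 1
  f2 <- grid$partial_r2 / (1 - grid$partial_r2)
  lambda <- if (convention == "cohen") f2 * (grid$u + v + 1) else f2 * grid$n
  crit <- stats::qf(1 - alpha, grid$u, v)
  out <- dplyr::mutate(grid, alpha = alpha, convention = convention,
                       power = stats::pf(crit, .data$u, v, ncp = lambda,
                                         lower.tail = FALSE))
  class(out) <- c("pupil_power", class(out))
  out
}
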