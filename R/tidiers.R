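#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the final per-effect tests of a crossvalidated timecourse model
#'
#' @param x A `cv_lmem`.
#' @param ... Unused.
#' @return One row per fixed effect: estimate, se, t, df, p.
#' @method tidy cv_lmem
#' @export
tidy.cv_lmem <- function(x, ...) x$effects

#' @rdname tidy.cv_lmem
#' @method glance cv_lmem
#' @export
glance.cv_lmem <- function(x, ...) {
  tibble::tibble(n_folds = x$n_folds, n_timepoints = x$n_timepoints,
                 n_effects = nrow(x$effects), n_clusters = nrow(x$clusters),
                 threshold = x$threshold)
}

#' Tidy a best-subset regression
#'
#' @param x A `pupil_bsr`.
#' @param ... Unused.
#' @return The BIC-ranked model table.
#' @method tidy pupil_bsr
#' @export
tidy.pupil_bsr <- function(x, ...) x$models

#' @rdname tidy.pupil_bsr
#' @method glance pupil_bsr
#' @export
glance.pupil_bsr <- function(x, ...) {
  best <- x$models[1, ]
  tibble::tibble(outcome = x$outcome, n = x$n, null_bic = x$null_bic,
                 best_subset = best$subset, best_bic = best$bic,
                 best_adj_r2 = best$adj_r2, best_cv_r2 = best$cv_r2,
                 bf_vs_null = best$bf_vs_null)
}

#' Tidy a k-means cluster solution
#'
#' @param x A `pupil_clusters`.
#' @param ... Unused.
#' @return One row per cluster with sizes and standardized centers.
#' @method tidy pupil_clusters
#' @export
tidy.pupil_clusters <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k), size = x$sizes),
    tibble::as_tibble(x$centers))
}

#' @rdname tidy.pupil_clusters
#' @method glance pupil_clusters
#' @export
glance.pupil_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia,
                 n = nrow(x$assignments))
}
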