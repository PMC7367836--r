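# broom-style tidiers for the package's fitted/result objects.

#' Tidy an RT correlation analysis
#'
#' @param x an `rt_correlation` object.
#' @param ... unused.
#' @return Long tibble of pairwise correlations: `sample1`, `sample2`,
#'   `correlation`.
#' @export
tidy.rt_correlation <- function(x, ...) {
  cm <- x$cor
  as_tibble(cm, rownames = "sample1") %>%
    pivot_longer(-"sample1", names_to = "sample2",
                 values_to = "correlation")
}

#' Glance at an RT correlation analysis
#'
#' @param x an `rt_correlation` object.
#' @param ... unused.
#' @return One-row tibble: bins used, sample count, min/mean off-diagonal
#'   correlation, variance explained by PC1.
#' @export
glance.rt_correlation <- function(x, ...) {
  off <- x$cor[upper.tri(x$cor)]
  tibble(n_bins = x$n_bins, n_samples = ncol(x$cor),
         min_cor = min(off, na.rm = TRUE),
         mean_cor = mean(off, na.rm = TRUE),
         pc1_var_frac = x$sdev[1]^2 / sum(x$sdev^2))
}

#' Tidy RT signatures (per-cluster table)
#'
#' @param x an `rt_signatures` object.
#' @param ... unused.
#' @return The per-cluster tibble: size, centroid condition means,
#'   direction, label, raw and BH-adjusted paired t-test p-values.
#' @export
tidy.rt_signatures <- function(x, ...) x$clusters

#' Glance at RT signatures
#'
#' @param x an `rt_signatures` object.
#' @param ... unused.
#' @return One-row tibble: k, windows clustered, total within-cluster
#'   sum of squares.
#' @export
glance.rt_signatures <- function(x, ...) {
  tibble(k = nrow(x$clusters), n_windows = nrow(x$windows),
         tot_withinss = x$fit$tot.withinss)
}

#' Tidy a shuffle-enrichment result (null distribution)
#'
#' @param x an `enrichment_result` object.
#' @param ... unused.
#' @return Tibble with one row per null iteration (`iteration`,
#'   `null_overlap`).
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(iteration = seq_along(x$null), null_overlap = x$null)
}

#' Glance at a shuffle-enrichment result
#'
#' @param x an `enrichment_result` object.
#' @param ... unused.
#' @return One-row tibble: observed, null mean/SD, fold, empirical
#'   p-value, iterations, seed.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, fold = x$fold, p_value = x$p_value,
         n_iter = x$n_iter, seed = x$seed)
}

#' Tidy a metagene matrix (column means)
#'
#' @param x a `metagene_matrix` object.
#' @param ... unused.
#' @return Tibble with `column`, `position` (`"flank_left"`, `"body"`,
#'   `"flank_right"`), `mean_value` across genes.
#' @export
tidy.metagene_matrix <- function(x, ...) {
  nc <- ncol(x$matrix)
  pos <- rep("body", nc)
  pos[seq_len(x$flank_cols)] <- "flank_left"
  pos[(nc - x$flank_cols + 1):nc] <- "flank_right"
  tibble(column = seq_len(nc), position = pos,
         mean_value = colMeans(x$matrix, na.rm = TRUE))
}
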