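# Quality-control filters and normalization for raw count matrices.
# Fixed pipeline order: gene filters -> sample filter -> normalization.

#' Remove low-expression genes
#'
#' Drops every gene whose mean raw count across samples is strictly below
#' `min_mean`, or whose count is zero in strictly more than
#' `max_zero_frac` of the samples. A gene failing both rules is listed once,
#' under the zero-fraction rule, and recorded in `flagged_both`.
#'
#' @param mat Raw count matrix (genes x samples).
#' @param min_mean Mean-count threshold (default 10; strict `<`).
#' @param max_zero_frac Zero-fraction threshold (default 0.5; strict `>`).
#' @return List with `matrix` (retained genes, order preserved) and `report`
#'   (a `filter_report` with the removed gene lists and thresholds).
#' @export
filter_genes <- function(mat, min_mean = 10, max_zero_frac = 0.5) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) == 0L) {
    stop_coexloc("empty expression matrix", "coexloc_value_error")
  }
  mean_fail <- rowMeans(mat) < min_mean
  zero_fail <- rowMeans(mat == 0) > max_zero_frac
  both <- mean_fail & zero_fail
  report <- structure(list(
    genes_removed_low_mean = rownames(mat)[mean_fail & !zero_fail],
    genes_removed_zero_fraction = rownames(mat)[zero_fail],
    flagged_both = rownames(mat)[both],
    samples_removed_outlier = character(),
    thresholds = list(mean_min = min_mean, zero_fraction_max = max_zero_frac)
  ), class = "filter_report")
  keep <- !(mean_fail | zero_fail)
  if (!any(keep)) {
    stop_coexloc("all genes removed by expression filters",
                 "coexloc_pipeline_error", report = report)
  }
  list(matrix = mat[keep, , drop = FALSE], report = report)
}

#' Remove outlier samples by mean expression
#'
#' Computes each sample's mean expression and removes samples whose mean lies
#' strictly outside `grand_mean +/- k * SD`, where grand mean and SD are taken
#' over the per-sample means and the SD uses the population denominator `n`.
#' Single pass; no iteration.
#'
#' @param mat Gene-filtered count matrix.
#' @param sd_multiplier Width `k` of the retained interval (default 2).
#' @return List with `matrix` and `report` (a `filter_report`).
#' @export
filter_samples <- function(mat, sd_multiplier = 2) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) == 0L || nrow(mat) == 0L) {
    stop_coexloc("empty expression matrix", "coexloc_value_error")
  }
  m <- colMeans(mat)
  grand <- mean(m)
  sd_pop <- sqrt(mean((m - grand)^2))
  lo <- grand - sd_multiplier * sd_pop
  hi <- grand + sd_multiplier * sd_pop
  out <- m < lo | m > hi
  report <- structure(list(
    genes_removed_low_mean = character(),
    genes_removed_zero_fraction = character(),
    flagged_both = character(),
    samples_removed_outlier = colnames(mat)[out],
    thresholds = list(sample_sd_multiplier = sd_multiplier,
                      grand_mean = grand, sd = sd_pop)
  ), class = "filter_report")
  if (sum(!out) < 3L) {
    stop_coexloc("fewer than 3 samples remain after outlier filtering",
                 "coexloc_pipeline_error", report = report)
  }
  list(matrix = mat[, !out, drop = FALSE], report = report)
}

#' Library-size normalization: counts-per-million, then log2(x + 1)
#'
#' @param mat Filtered count matrix; every sample must have a positive total.
#' @return Matrix of `log2(CPM + 1)` values, same shape and dimnames.
#' @export
normalize_counts <- function(mat) {
  stopifnot(is.matrix(mat))
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    stop_coexloc(sprintf("sample(s) with zero total count: %s",
                         paste(colnames(mat)[totals <= 0], collapse = ", ")),
                 "coexloc_value_error")
  }
  log2(sweep(mat, 2L, totals, "/") * 1e6 + 1)
}

#' Full preprocessing pass in the fixed order
#'
#' Gene filters, then the sample filter, then CPM/log2 normalization.
#'
#' @inheritParams filter_genes
#' @inheritParams filter_samples
#' @param normalize Set `FALSE` to return filtered raw counts.
#' @return List with `matrix` and `report` (merged gene + sample report).
#' @export
preprocess_counts <- function(mat, min_mean = 10, max_zero_frac = 0.5,
                              sd_multiplier = 2, normalize = TRUE) {
  g <- filter_genes(mat, min_mean = min_mean, max_zero_frac = max_zero_frac)
  s <- filter_samples(g$matrix, sd_multiplier = sd_multiplier)
  report <- structure(list(
    genes_removed_low_mean = g$report$genes_removed_low_mean,
    genes_removed_zero_fraction = g$report$genes_removed_zero_fraction,
    flagged_both = g$report$flagged_both,
    samples_removed_outlier = s$report$samples_removed_outlier,
    thresholds = c(g$report$thresholds,
                   s$report$thresholds["sample_sd_multiplier"])
  ), class = "filter_report")
  out <- if (normalize) normalize_counts(s$matrix) else s$matrix
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("QC filter report\n")
  cat(sprintf("  genes removed (low mean only):   %d\n",
              length(x$genes_removed_low_mean)))
  cat(sprintf("  genes removed (zero fraction):   %d (of which %d also low-mean)\n",
              length(x$genes_removed_zero_fraction), length(x$flagged_both)))
  cat(sprintf("  samples removed (outlier mean):  %d\n",
              length(x$samples_removed_outlier)))
  invisible(x)
}
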