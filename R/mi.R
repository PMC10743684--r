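# Plug-in mutual information with equal-frequency (rank) binning, in bits.
# This is the estimator behind the ARACNe-style network inference stage.

#' Equal-frequency discretization
#'
#' Bins a numeric vector into (up to) `bins` equal-frequency bins with
#' breaks taken at order statistics, so tied values always share a bin. The assignment
#' is invariant under permutation of the observations and under strictly
#' monotone increasing transforms; when all values are distinct and
#' `length(x)` is divisible by `bins`, every bin holds exactly
#' `length(x)/bins` observations.
#'
#' @param x Numeric vector.
#' @param bins Number of bins (>= 1).
#' @return Integer bin codes in `1..bins` (fewer distinct codes under ties).
#' @export
discretize_equal_frequency <- function(x, bins) {
  stopifnot(is.numeric(x), length(x) >= 1L, is_count_scalar(bins), bins >= 1L)
  if (anyNA(x)) stop_coexloc("NA values cannot be discretized", "coexloc_value_error")
  n <- length(x)
  xs <- sort(x)
  # Bin boundaries are the order statistics at ranks floor(k*n/bins); being
  # data values, they are equivariant under strictly monotone transforms.
  pos <- unique(pmax(1L, pmin(n, floor(seq_len(bins - 1L) * n / bins))))
  brk <- unique(c(xs[1L], xs[pos], xs[n]))
  if (length(brk) < 2L) return(rep(1L, n))  # constant vector
  as.integer(cut(x, breaks = brk, include.lowest = TRUE))
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Mutual information of a joint count table (plug-in, bits)
#'
#' Direct evaluation of `sum p(x,y) log2(p(x,y) / (p(x) p(y)))` over the
#' empirical joint distribution. Exposed so the estimator can be checked
#' against hand-specified joint histograms.
#'
#' @param joint Matrix of nonnegative joint counts.
#' @return Mutual information in bits (>= 0).
#' @export
mi_from_joint <- function(joint) {
  stopifnot(is.matrix(joint), all(joint >= 0), sum(joint) > 0)
  hx <- entropy_bits(rowSums(joint))
  hy <- entropy_bits(colSums(joint))
  hxy <- entropy_bits(as.vector(joint))
  max(hx + hy - hxy, 0)
}

#' Estimate mutual information between two sample vectors
#'
#' Discretizes each vector with [discretize_equal_frequency()] and returns
#' the plug-in mutual information of the joint histogram, in bits. A constant
#' vector has zero entropy; the estimate is 0 and a degenerate-bin warning is
#' emitted. For `y == x` with all values distinct and `length(x)` divisible
#' by `bins`, the estimate is exactly `log2(bins)`.
#'
#' @param x,y Equal-length numeric vectors; `length(x) >= 4 * bins`.
#' @param bins Number of bins; default `floor(sqrt(length(x)))`.
#' @return Mutual information in bits.
#' @export
estimate_mi <- function(x, y, bins = floor(sqrt(length(x)))) {
  if (length(x) != length(y)) {
    stop_coexloc("x and y must have equal length", "coexloc_value_error")
  }
  stopifnot(is_count_scalar(bins), bins >= 1L)
  if (length(x) < 4L * bins) {
    stop_coexloc(sprintf("need >= 4*bins = %d observations, got %d",
                         4L * bins, length(x)), "coexloc_value_error")
  }
  bx <- discretize_equal_frequency(x, bins)
  by <- discretize_equal_frequency(y, bins)
  if (max(bx) == 1L || max(by) == 1L) {
    warning("degenerate binning (constant vector); MI is 0",
            call. = FALSE)
  }
  joint <- matrix(tabulate((bx - 1L) * bins + by, nbins = bins * bins),
                  nrow = bins, byrow = TRUE)
  mi_from_joint(joint)
}

#' Pairwise mutual-information matrix for all genes
#'
#' Computes the plug-in MI (bits) for every unordered gene pair of an
#' expression matrix, using one shared equal-frequency discretization per
#' gene. The result is symmetric with a zero diagonal by convention.
#'
#' @param mat Numeric matrix, genes in rows (>= 2), samples in columns.
#' @param bins Number of bins; default `floor(sqrt(ncol(mat)))`.
#' @return Symmetric nonnegative matrix of MI values in bits, dimnames as
#'   `rownames(mat)`, zero diagonal.
#' @export
mi_matrix <- function(mat, bins = floor(sqrt(ncol(mat)))) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  stopifnot(is_count_scalar(bins), bins >= 1L)
  if (ncol(mat) < 4L * bins) {
    stop_coexloc(sprintf("need >= 4*bins = %d samples, got %d",
                         4L * bins, ncol(mat)), "coexloc_value_error")
  }
  ng <- nrow(mat)
  n <- ncol(mat)
  D <- matrix(0L, ng, n)
  for (g in seq_len(ng)) D[g, ] <- discretize_equal_frequency(mat[g, ], bins)
  if (any(apply(D, 1L, max) == 1L)) {
    warning("degenerate binning (constant gene profile); its MI values are 0",
            call. = FALSE)
  }
  hm <- apply(D, 1L, function(d) entropy_bits(tabulate(d, nbins = bins)))
  M <- matrix(0, ng, ng, dimnames = list(rownames(mat), rownames(mat)))
  nb2 <- bins * bins
  for (i in seq_len(ng - 1L)) {
    di <- (D[i, ] - 1L) * bins
    for (j in (i + 1L):ng) {
      hxy <- entropy_bits(tabulate(di + D[j, ], nbins = nb2))
      M[i, j] <- M[j, i] <- max(hm[i] + hm[j] - hxy, 0)
    }
  }
  M
}
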