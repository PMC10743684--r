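# Per-community TF-motif over-representation: exact hypergeometric upper
# tail with one joint Benjamini-Hochberg correction per phenotype.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of at least `k`
#' successes when drawing `n` items without replacement from a universe of
#' `N` items containing `K` successes. Evaluated through the stable
#' log-space routine underlying [stats::phyper()].
#'
#' @param k Observed overlap.
#' @param n Draw (community) size.
#' @param K Success (TF target) count in the universe.
#' @param N Universe size.
#' @return Upper-tail probability in `(0, 1]`; `k = 0` gives exactly 1.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  for (v in list(k = k, n = n, K = K, N = N)) {
    if (!is_count_scalar(v) || v < 0) {
      stop_coexloc("k, n, K, N must be nonnegative integers", "coexloc_value_error")
    }
  }
  if (k > min(n, K) || n > N || K > N) {
    stop_coexloc(sprintf("invalid bounds: need 0 <= k <= min(n, K) <= N (k=%d n=%d K=%d N=%d)",
                         k, n, K, N), "coexloc_value_error")
  }
  if (k == 0L) return(1)
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up FDR adjustment with monotonicity enforced by the cumulative
#' minimum from the largest rank (the classic BH adjusted p-value).
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return q-values of the same length; empty in, empty out.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop_coexloc("p-values must lie in (0, 1]", "coexloc_value_error")
  }
  p.adjust(p, method = "BH")
}

#' Per-community TF enrichment
#'
#' One upper-tail hypergeometric test per (TF, community) pair with overlap
#' `k >= 1`, over a shared gene universe. By default the universe is the
#' intersection of the community gene union (the network side) with the
#' union of all motif-database candidate targets, so only testable genes
#' enter the null. BH-FDR is applied jointly across all emitted tests of the
#' phenotype; `significant` means `q < alpha`.
#'
#' @param communities Named list of gene-id sets (from [top_communities()]).
#' @param db A `motif_db`.
#' @param universe Optional explicit gene universe (character vector);
#'   `NULL` uses the network-by-database intersection described above.
#' @param alpha Significance level on q (default 0.05).
#' @return An `enrichment_result` data frame with columns `tf`, `community`,
#'   `k`, `n`, `K`, `N`, `p_value`, `q_value`, `significant`.
#' @export
enrich_communities <- function(communities, db, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(db, "motif_db"))
  if (length(communities) == 0L) {
    stop_coexloc("no communities to enrich", "coexloc_value_error")
  }
  if (is.null(universe)) {
    universe <- intersect(unique(unlist(communities)),
                          unique(unlist(db$targets)))
  }
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0L) stop_coexloc("empty enrichment universe", "coexloc_config_error")
  rows <- list()
  for (ti in seq_len(nrow(db))) {
    targets <- intersect(db$targets[[ti]], universe)
    K <- length(targets)
    if (K == 0L) next
    for (ci in names(communities)) {
      comm <- intersect(communities[[ci]], universe)
      n <- length(comm)
      k <- length(intersect(comm, targets))
      if (k < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        tf = db$tf[ti], community = ci, k = k, n = n, K = K, N = N,
        p_value = hypergeom_upper_tail(k, n, K, N),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    res <- data.frame(tf = character(), community = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical())
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- res$q_value < alpha
  res <- res[order(res$q_value, res$p_value, res$tf, res$community), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: %d (TF, community) tests, %d significant (q < 0.05 family)\n",
              nrow(x), sum(x$significant)))
  if (nrow(x)) print.data.frame(head(x, 10L))
  invisible(x)
}
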