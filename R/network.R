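# DPI pruning, top-k thresholding, and the co-expression network container.

#' Data-processing-inequality pruning of an MI matrix
#'
#' ARACNe's pruning rule: in every triangle (i, j, k) whose three MI values
#' all exceed the working floor, the edge (i, j) is removed when
#' `mi(i,j) < min(mi(i,k), mi(j,k)) * (1 - tolerance)` — the weakest edge of
#' an information triangle is taken as an indirect interaction. All removal
#' decisions are evaluated against the *original* matrix (simultaneous
#' removal), so the result is independent of any processing order.
#'
#' @param mi Symmetric nonnegative MI matrix (zero diagonal).
#' @param tolerance DPI tolerance in `[0, 1)`; larger keeps more edges.
#' @param floor Working MI floor; only triangles with all three values
#'   strictly above it are considered (default 0).
#' @return The pruned MI matrix; removed entries are set to 0.
#' @export
apply_dpi <- function(mi, tolerance = 0, floor = 0) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  if (max(abs(mi - t(mi))) > 1e-12) {
    stop_coexloc("MI matrix must be symmetric", "coexloc_value_error")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      tolerance < 0 || tolerance >= 1) {
    stop_coexloc("tolerance must lie in [0, 1)", "coexloc_usage_error")
  }
  ng <- nrow(mi)
  if (ng < 3L) return(mi)
  A <- mi
  A[A <= floor] <- -Inf
  diag(A) <- -Inf
  keep <- matrix(TRUE, ng, ng)
  for (i in seq_len(ng)) {
    # max over k of min(mi(i,k), mi(j,k)), for all j at once
    maxmin <- apply(pmin(A, matrix(A[i, ], ng, ng, byrow = TRUE)), 1L, max)
    keep[i, ] <- !(mi[i, ] > floor & mi[i, ] < maxmin * (1 - tolerance))
  }
  out <- mi * (keep & t(keep))
  diag(out) <- 0
  out
}

#' Threshold an MI matrix to its k strongest edges
#'
#' Selects the `k` largest positive off-diagonal MI values as an undirected
#' network. Ties at the cutoff are broken by lexicographic
#' `(gene_a, gene_b)` order, so the result is deterministic.
#'
#' @param mi Symmetric MI matrix with gene dimnames.
#' @param k Number of edges to keep (the study-scale convention is the top
#'   100,000 interactions; desk-scale runs use far fewer).
#' @param dpi_tolerance Optional annotation recorded on the network.
#' @return A `coexpression_network`: data frame of edges
#'   (`gene_a`, `gene_b`, `mi`) with attributes `nodes`, `k_threshold`,
#'   `dpi_tolerance`.
#' @export
top_k_edges <- function(mi, k = 100000L, dpi_tolerance = NA_real_) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi), !is.null(rownames(mi)))
  if (!is_count_scalar(k) || k < 1L) {
    stop_coexloc("k must be a positive integer", "coexloc_usage_error")
  }
  ids <- rownames(mi)
  ut <- which(upper.tri(mi) & mi > 0, arr.ind = TRUE)
  if (nrow(ut) < k) {
    warning(sprintf("only %d positive-MI pairs available; returning all (k = %d)",
                    nrow(ut), k), call. = FALSE)
  }
  a <- ids[ut[, 1L]]
  b <- ids[ut[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  w <- mi[ut]
  ord <- order(-w, a, b)
  sel <- ord[seq_len(min(k, length(ord)))]
  edges <- data.frame(gene_a = a[sel], gene_b = b[sel], mi = w[sel],
                      stringsAsFactors = FALSE)
  coexpression_network(edges, k_threshold = k, dpi_tolerance = dpi_tolerance)
}

#' Construct a co-expression network from an edge table
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `mi` (bits).
#' @param nodes Optional node set; defaults to the edge endpoints. Extra
#'   isolated nodes are allowed and become singleton communities downstream.
#' @param k_threshold,dpi_tolerance Provenance annotations.
#' @return A `coexpression_network` data frame.
#' @export
coexpression_network <- function(edges, nodes = NULL, k_threshold = NA_integer_,
                                 dpi_tolerance = NA_real_) {
  stopifnot(all(c("gene_a", "gene_b", "mi") %in% colnames(edges)))
  canon <- canonical_edges(data.frame(node_a = edges$gene_a,
                                      node_b = edges$gene_b,
                                      weight = edges$mi,
                                      stringsAsFactors = FALSE))
  net <- data.frame(gene_a = canon$node_a, gene_b = canon$node_b,
                    mi = canon$weight, stringsAsFactors = FALSE)
  endpoint <- unique(c(net$gene_a, net$gene_b))
  nodes <- if (is.null(nodes)) sort(endpoint) else sort(unique(as.character(nodes)))
  if (!all(endpoint %in% nodes)) {
    stop_coexloc("every edge endpoint must be in the node set",
                 "coexloc_value_error")
  }
  structure(net, nodes = nodes, k_threshold = k_threshold,
            dpi_tolerance = dpi_tolerance,
            class = c("coexpression_network", "data.frame"))
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("Co-expression network: %d nodes, %d edges (MI-weighted)\n",
              length(attr(x, "nodes")), nrow(x)))
  if (!is.na(attr(x, "k_threshold")))
    cat(sprintf("  top-k threshold: %d\n", attr(x, "k_threshold")))
  if (!is.na(attr(x, "dpi_tolerance")))
    cat(sprintf("  DPI tolerance:   %g\n", attr(x, "dpi_tolerance")))
  invisible(x)
}

#' Intra- versus inter-chromosomal edge statistics
#'
#' Classifies every network edge whose two endpoints are annotated as
#' intra-chromosomal (same chromosome) or inter-chromosomal; edges with an
#' unannotated endpoint are counted separately and excluded from the
#' fraction. The intra fraction is the quantity that drops when long-range
#' co-expression is lost.
#'
#' @param net A `coexpression_network`.
#' @param ann Gene annotation data frame (`gene_id`, `chromosome`).
#' @return A `locality_report` list: `n_edges`, `n_edges_annotated`,
#'   `n_intra`, `fraction_intra` (`NA` with `undefined = TRUE` if no edge is
#'   fully annotated), `per_chromosome_edge_counts` (intra edges per
#'   chromosome), `n_unannotated`.
#' @export
locality_stats <- function(net, ann) {
  stopifnot(inherits(net, "coexpression_network"))
  if (nrow(net) == 0L) {
    stop_coexloc("network has no edges", "coexloc_value_error")
  }
  chr <- stats::setNames(ann$chromosome, ann$gene_id)
  ca <- chr[net$gene_a]
  cb <- chr[net$gene_b]
  annotated <- !is.na(ca) & !is.na(cb)
  intra <- annotated & ca == cb
  per_chr <- table(ca[intra])
  n_ann <- sum(annotated)
  structure(list(
    n_edges = nrow(net),
    n_edges_annotated = n_ann,
    n_intra = sum(intra),
    fraction_intra = if (n_ann > 0L) sum(intra) / n_ann else NA_real_,
    undefined = n_ann == 0L,
    per_chromosome_edge_counts = as.list(per_chr),
    n_unannotated = sum(!annotated)
  ), class = "locality_report")
}

#' @export
print.locality_report <- function(x, ...) {
  cat(sprintf("Locality: %d/%d annotated edges intra-chromosomal (fraction %.3f)\n",
              x$n_intra, x$n_edges_annotated,
              if (x$undefined) NA else x$fraction_intra))
  if (x$n_unannotated > 0L)
    cat(sprintf("  %d edge(s) with unannotated endpoint excluded\n", x$n_unannotated))
  invisible(x)
}
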