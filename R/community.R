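# Louvain community detection with seeded restarts, modularity, and
# community-level chromosome statistics.

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ w_c / W - gamma * (s_c / 2W)^2 ]` where `w_c` is the total
#' intra-community edge weight, `s_c` the summed strength of the community's
#' nodes, `W` the total edge weight, and `gamma` the resolution.
#'
#' @param net A `coexpression_network`.
#' @param membership Named vector assigning every network node a community.
#' @param resolution Resolution `gamma` (default 1).
#' @return Modularity `Q` in `[-1, 1]`.
#' @export
modularity_q <- function(net, membership, resolution = 1) {
  stopifnot(inherits(net, "coexpression_network"))
  nodes <- attr(net, "nodes")
  if (!all(nodes %in% names(membership))) {
    stop_coexloc("membership must cover every network node", "coexloc_value_error")
  }
  W <- sum(net$mi)
  if (W <= 0) stop_coexloc("network has zero total weight", "coexloc_value_error")
  comm <- as.character(membership[nodes])
  names(comm) <- nodes
  strength <- stats::setNames(numeric(length(nodes)), nodes)
  agg_a <- tapply(net$mi, net$gene_a, sum)
  agg_b <- tapply(net$mi, net$gene_b, sum)
  strength[names(agg_a)] <- strength[names(agg_a)] + agg_a
  strength[names(agg_b)] <- strength[names(agg_b)] + agg_b
  intra <- tapply(net$mi[comm[net$gene_a] == comm[net$gene_b]],
                  comm[net$gene_a][comm[net$gene_a] == comm[net$gene_b]], sum)
  s_c <- tapply(strength, comm, sum)
  w_c <- stats::setNames(numeric(length(s_c)), names(s_c))
  if (length(intra)) w_c[names(intra)] <- intra
  sum(w_c / W - resolution * (s_c / (2 * W))^2)
}

#' Louvain communities with seeded restarts
#'
#' Runs `n_restarts` Louvain passes, each with a freshly shuffled node order
#' (Louvain is order-sensitive), and returns the partition with the highest
#' weighted modularity at the given resolution; ties go to the first restart
#' that attained the best `Q`. All shuffles derive from the master `seed`, so
#' the result is deterministic for fixed `(seed, n_restarts)`. Isolated
#' nodes (present in the node set but edgeless) each form a singleton
#' community.
#'
#' @param net A `coexpression_network`.
#' @param resolution Modularity resolution (default 1).
#' @param seed Master seed for the restart shuffles.
#' @param n_restarts Number of restarts (>= 1).
#' @return A `community_partition`: list with `membership` (named integer,
#'   ids renumbered `0..C-1` in size-rank order), `modularity`, `sizes`,
#'   `rank_by_size`, `resolution`, `seed`, `n_restarts`.
#' @export
louvain_communities <- function(net, resolution = 1, seed = 1L,
                                n_restarts = 10L) {
  stopifnot(inherits(net, "coexpression_network"))
  if (nrow(net) == 0L) stop_coexloc("empty network", "coexloc_value_error")
  stopifnot(is_count_scalar(n_restarts), n_restarts >= 1L)
  nodes <- attr(net, "nodes")
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$gene_a, to = net$gene_b),
    directed = FALSE, vertices = nodes)
  wts <- net$mi
  restart_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_restarts))
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    memb <- with_seed(restart_seeds[r], {
      perm <- sample(igraph::vcount(g))
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, weights = wts[order_edges_after_permute(g, gp)],
                                    resolution = resolution)
      m <- igraph::membership(cl)
      m[match(nodes, names(m))]
    })
    names(memb) <- nodes
    q <- modularity_q(net, memb, resolution)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  community_partition(best, net, resolution = resolution, seed = seed,
                      n_restarts = n_restarts, modularity = best_q)
}

# After igraph::permute the edge order is rebuilt; map original edge weights
# onto the permuted graph's edge order.
order_edges_after_permute <- function(g, gp) {
  el0 <- igraph::as_edgelist(g, names = TRUE)
  elp <- igraph::as_edgelist(gp, names = TRUE)
  key <- function(el) paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  match(key(elp), key(el0))
}

community_partition <- function(membership, net, resolution, seed, n_restarts,
                                modularity) {
  # renumber 0..C-1 by (size desc, smallest member gene id asc)
  groups <- split(names(membership), membership)
  ord <- order(-vapply(groups, length, 0L),
               vapply(groups, function(x) min(x), ""))
  groups <- groups[ord]
  new_id <- stats::setNames(seq_along(groups) - 1L, names(groups))
  memb <- stats::setNames(new_id[as.character(membership)], names(membership))
  sizes <- vapply(groups, length, 0L)
  names(sizes) <- as.character(seq_along(groups) - 1L)
  structure(list(
    membership = memb,
    modularity = modularity,
    sizes = sizes,
    rank_by_size = as.character(seq_along(groups) - 1L),
    resolution = resolution,
    seed = seed,
    n_restarts = n_restarts
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d communities over %d nodes, Q = %.4f (resolution %g)\n",
              length(x$sizes), length(x$membership), x$modularity, x$resolution))
  cat(sprintf("  largest sizes: %s\n",
              paste(head(sort(x$sizes, decreasing = TRUE), 5L), collapse = ", ")))
  invisible(x)
}

#' Largest communities by size
#'
#' Returns the `n` largest communities as gene-id sets, ordered by
#' (size descending, smallest member gene id ascending); the same rule
#' breaks ties at the cut. If fewer than `n` communities exist, all are
#' returned with a warning.
#'
#' @param partition A `community_partition`.
#' @param n Number of communities to keep (study convention: 20).
#' @return Named list of character vectors (names are community ids).
#' @export
top_communities <- function(partition, n = 20L) {
  stopifnot(inherits(partition, "community_partition"))
  if (!is_count_scalar(n) || n < 1L) {
    stop_coexloc("n must be a positive integer", "coexloc_usage_error")
  }
  groups <- split(names(partition$membership), partition$membership)
  ord <- order(-vapply(groups, length, 0L),
               vapply(groups, function(x) min(x), ""))
  groups <- groups[ord]
  if (length(groups) < n) {
    warning(sprintf("only %d communities exist (requested %d); returning all",
                    length(groups), n), call. = FALSE)
    n <- length(groups)
  }
  lapply(groups[seq_len(n)], sort)
}

#' Chromosome homogeneity of communities
#'
#' For each community, the share of its annotated members lying on the
#' community's plurality chromosome. Chromosome-pure communities score 1;
#' a community spread evenly over `c` chromosomes scores `1/c`.
#'
#' @param communities Named list of gene-id sets (e.g. [top_communities()]).
#' @param ann Gene annotation (`gene_id`, `chromosome`).
#' @return Named numeric vector of max chromosome shares (`NA` where no
#'   member is annotated).
#' @export
community_chromosome_homogeneity <- function(communities, ann) {
  chr <- stats::setNames(ann$chromosome, ann$gene_id)
  vapply(communities, function(genes) {
    cc <- chr[genes]
    cc <- cc[!is.na(cc)]
    if (!length(cc)) return(NA_real_)
    max(table(cc)) / length(cc)
  }, numeric(1))
}

#' Adjusted Rand index between recovered communities and planted modules
#'
#' Restricted to genes that belong to a planted module and appear in the
#' recovered communities (the standard planted-partition benchmark).
#'
#' @param communities Named list of gene-id sets.
#' @param truth `truth` element of a [generate_dataset()] result.
#' @return ARI in `[-1, 1]` (1 = perfect recovery).
#' @export
module_recovery_ari <- function(communities, truth) {
  memb <- stats::setNames(rep(names(communities),
                              lengths(communities)), unlist(communities))
  planted <- truth$module_of_gene
  genes <- intersect(names(memb), names(planted)[!is.na(planted)])
  if (!length(genes)) return(NA_real_)
  mclust::adjustedRandIndex(memb[genes], planted[genes])
}
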