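test_that("modularity hits closed forms and the brute-force pairwise sum", {
  set.seed(14)
  for (rep in 1:15) {
    n <- 10
    M <- random_mi_matrix(n, density = 0.5)
    if (sum(M) == 0) next
    net <- top_k_edges(M, k = sum(M[upper.tri(M)] > 0))
    nodes <- attr(net, "nodes")
    # all-in-one: Q = 0 at resolution 1
    one <- setNames(rep(1L, length(nodes)), nodes)
    expect_equal(modularity_q(net, one), 0, tolerance = 1e-12)
    # singletons: Q = -sum (s_i / 2W)^2
    singles <- setNames(seq_along(nodes), nodes)
    A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(net))) {
      A[net$gene_a[r], net$gene_b[r]] <- net$mi[r]
      A[net$gene_b[r], net$gene_a[r]] <- net$mi[r]
    }
    expect_equal(modularity_q(net, singles),
                 -sum((rowSums(A) / sum(A))^2), tolerance = 1e-12)
    # random partition vs brute force, including resolution != 1
    memb <- setNames(sample(1:3, length(nodes), replace = TRUE), nodes)
    for (res in c(1, 0.7)) {
      expect_equal(modularity_q(net, memb, res),
                   ref_modularity(net, memb, res), tolerance = 1e-12)
    }
  }
})

test_that("louvain recovers two joined 4-cliques at the exhaustive optimum", {
  # two 4-cliques joined by one edge
  cl1 <- t(combn(c("A1", "A2", "A3", "A4"), 2))
  cl2 <- t(combn(c("B1", "B2", "B3", "B4"), 2))
  edges <- rbind(cl1, cl2, c("A1", "B1"))
  net <- net_from_edges(edges[, 1], edges[, 2], w = 1)
  part <- louvain_communities(net, seed = 5L, n_restarts = 5L)
  groups <- split(names(part$membership), part$membership)
  expect_length(groups, 2L)
  expect_setequal(vapply(groups, function(g) paste(sort(g), collapse = ","), ""),
                  c("A1,A2,A3,A4", "B1,B2,B3,B4"))

  # exhaustive search over all partitions of the 8 nodes confirms optimality
  nodes <- attr(net, "nodes")
  best_q <- max(vapply(enumerate_partitions(nodes), function(p) {
    memb <- setNames(rep(seq_along(p), lengths(p)), unlist(p))
    modularity_q(net, memb[nodes])
  }, 0))
  expect_equal(part$modularity, best_q, tolerance = 1e-12)
})

test_that("single cliques stay whole and isolated nodes become singletons", {
  cl <- t(combn(sprintf("C%d", 1:5), 2))
  net <- net_from_edges(cl[, 1], cl[, 2], w = 1)
  part <- louvain_communities(net, seed = 1L, n_restarts = 3L)
  expect_length(part$sizes, 1L)

  with_iso <- net_from_edges(cl[, 1], cl[, 2], w = 1,
                             nodes = c(sprintf("C%d", 1:5), "Z1", "Z2"))
  part2 <- louvain_communities(with_iso, seed = 1L, n_restarts = 3L)
  expect_equal(unname(part2$sizes[as.character(part2$membership[c("Z1", "Z2")])]),
               c(1L, 1L))
  # zero-degree nodes do not change Q
  expect_equal(part2$modularity, part$modularity, tolerance = 1e-12)
})

test_that("louvain is deterministic and restart-monotone; Q beats baselines", {
  set.seed(15)
  M <- random_mi_matrix(25, density = 0.3)
  net <- top_k_edges(M, k = 60L)
  a <- louvain_communities(net, seed = 9L, n_restarts = 4L)
  b <- louvain_communities(net, seed = 9L, n_restarts = 4L)
  expect_identical(a$membership, b$membership)
  expect_identical(a$modularity, b$modularity)

  qs <- vapply(1:6, function(r)
    louvain_communities(net, seed = 9L, n_restarts = r)$modularity, 0)
  expect_true(all(diff(qs) >= 0))

  nodes <- attr(net, "nodes")
  expect_gte(a$modularity,
             modularity_q(net, setNames(rep(1L, length(nodes)), nodes)))
  expect_gte(a$modularity,
             modularity_q(net, setNames(seq_along(nodes), nodes)))
  expect_error(louvain_communities(net_from_edges(character(), character())),
               class = "coexloc_value_error")
})

test_that("top_communities ranks by size with lexicographic tie-breaks", {
  memb <- setNames(c(rep(1, 5), rep(2, 3), rep(3, 3), 4),
                   c(sprintf("A%d", 1:5), "C1", "C2", "C3", "B1", "B2", "B3", "Z"))
  part <- structure(list(membership = memb,
                         sizes = table(memb), rank_by_size = NULL,
                         modularity = 0.5, resolution = 1, seed = 1,
                         n_restarts = 1),
                    class = "community_partition")
  top <- top_communities(part, n = 2L)
  expect_length(top, 2L)
  expect_setequal(top[[1]], sprintf("A%d", 1:5))
  # size-3 tie: community containing "B1" precedes the one containing "C1"
  expect_setequal(top[[2]], c("B1", "B2", "B3"))

  expect_warning(all4 <- top_communities(part, n = 20L), "only 4 communities")
  expect_length(all4, 4L)
  expect_error(top_communities(part, n = 0L), class = "coexloc_usage_error")
})

test_that("chromosome homogeneity scores pure and even splits correctly", {
  ann <- data.frame(gene_id = sprintf("G%d", 1:8),
                    chromosome = c("1", "1", "1", "1", "1", "2", "3", "4"))
  comm <- list(pure = c("G1", "G2", "G3"),
               even = c("G5", "G6", "G7", "G8"),
               unknown = c("X1", "X2"))
  h <- community_chromosome_homogeneity(comm, ann)
  expect_equal(unname(h["pure"]), 1.0)
  expect_equal(unname(h["even"]), 0.25)
  expect_true(is.na(h["unknown"]))
})
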