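# Independent reference implementations used as oracles. These deliberately
# use the slowest, most literal formulation of each definition.

# DPI by exhaustive triangle scan: for every unordered triple with all three
# MI values strictly above `floor`, mark the edge that is weakest (below the
# tolerance-scaled minimum of the other two) for removal; apply all removals
# simultaneously against the original matrix.
ref_dpi <- function(M, tolerance = 0, floor = 0) {
  ng <- nrow(M)
  remove <- matrix(FALSE, ng, ng)
  if (ng >= 3L) {
    for (i in 1:(ng - 2L)) for (j in (i + 1L):(ng - 1L)) for (k in (j + 1L):ng) {
      ij <- M[i, j]; ik <- M[i, k]; jk <- M[j, k]
      if (ij > floor && ik > floor && jk > floor) {
        if (ij < min(ik, jk) * (1 - tolerance)) remove[i, j] <- remove[j, i] <- TRUE
        if (ik < min(ij, jk) * (1 - tolerance)) remove[i, k] <- remove[k, i] <- TRUE
        if (jk < min(ij, ik) * (1 - tolerance)) remove[j, k] <- remove[k, j] <- TRUE
      }
    }
  }
  out <- M
  out[remove] <- 0
  out
}

# Modularity as the literal pairwise double sum:
# Q = (1/2W) * sum_{i,j} [A_ij - gamma * s_i s_j / (2W)] * delta(c_i, c_j)
ref_modularity <- function(net, membership, resolution = 1) {
  nodes <- attr(net, "nodes")
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net))) {
    A[net$gene_a[r], net$gene_b[r]] <- A[net$gene_a[r], net$gene_b[r]] + net$mi[r]
    A[net$gene_b[r], net$gene_a[r]] <- A[net$gene_b[r], net$gene_a[r]] + net$mi[r]
  }
  W2 <- sum(A)           # 2W
  s <- rowSums(A)
  q <- 0
  for (i in nodes) for (j in nodes) {
    if (membership[i] == membership[j]) {
      q <- q + A[i, j] - resolution * s[i] * s[j] / W2
    }
  }
  unname(q / W2)
}

# All set partitions of a vector (Bell-number enumeration).
enumerate_partitions <- function(items) {
  if (length(items) == 1L) return(list(list(items)))
  rest <- enumerate_partitions(items[-1L])
  out <- list()
  for (p in rest) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(items[1L], q[[b]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1L]), p)
  }
  out
}

# Hypergeometric upper tail by direct combinatorial enumeration.
ref_hyper_upper <- function(k, n, K, N) {
  jmax <- min(n, K)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Classic BH step-up rejection set at level alpha.
ref_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# Random symmetric nonnegative MI-like matrix with zero diagonal.
random_mi_matrix <- function(n, density = 0.7) {
  M <- matrix(0, n, n)
  ut <- upper.tri(M)
  vals <- ifelse(runif(sum(ut)) < density, runif(sum(ut)), 0)
  M[ut] <- vals
  M <- M + t(M)
  dimnames(M) <- list(sprintf("G%03d", 1:n), sprintf("G%03d", 1:n))
  M
}

# Small network builder for community/grn tests.
net_from_edges <- function(a, b, w = 1, nodes = NULL) {
  coexpression_network(data.frame(gene_a = a, gene_b = b,
                                  mi = rep_len(w, length(a))), nodes = nodes)
}
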