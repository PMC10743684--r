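# TF-target regulatory network assembly and the downstream comparative
# statistics: topology, degree distributions, set sharing, per-target
# regulators, unique-TF subnetworks, and star structures.

#' Build a TF-target regulatory network from significant enrichments
#'
#' For every significant (TF, community) pair, adds directed edges from the
#' TF to genes of that community; with the default `"intersection"` rule only
#' community genes that are also motif-database candidate targets of the TF
#' receive an edge (each edge asserts motif evidence), while
#' `"whole-community"` links the TF to every community member. Edge sets are
#' unioned over communities with no duplicates.
#'
#' @param enrichments An `enrichment_result`.
#' @param communities Named list of gene-id sets used for the enrichment.
#' @param db The `motif_db` used for the enrichment.
#' @param phenotype Phenotype label carried on the network.
#' @param edge_rule `"intersection"` (default) or `"whole-community"`.
#' @return A `regulatory_network`: list with `phenotype`, `edges`
#'   (data frame `tf`, `target`), `tf_set`, `target_set`. Empty (with a
#'   warning) when nothing is significant.
#' @export
build_grn <- function(enrichments, communities, db, phenotype = "phenotype",
                      edge_rule = c("intersection", "whole-community")) {
  edge_rule <- match.arg(edge_rule)
  sig <- enrichments[enrichments$significant, , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(sig))) {
    tf <- sig$tf[i]
    comm <- communities[[sig$community[i]]]
    targets <- if (edge_rule == "intersection") {
      intersect(comm, db$targets[[match(tf, db$tf)]])
    } else {
      comm
    }
    if (length(targets)) {
      edges[[length(edges) + 1L]] <- data.frame(tf = tf, target = targets,
                                                stringsAsFactors = FALSE)
    }
  }
  if (!length(edges)) {
    warning(sprintf("no significant (TF, community) pairs for '%s'; empty GRN",
                    phenotype), call. = FALSE)
    e <- data.frame(tf = character(), target = character())
  } else {
    e <- unique(do.call(rbind, edges))
    e <- e[order(e$tf, e$target), , drop = FALSE]
    rownames(e) <- NULL
  }
  structure(list(phenotype = phenotype, edges = e,
                 tf_set = sort(unique(e$tf)),
                 target_set = sort(unique(e$target))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network '%s': %d TFs -> %d targets, %d edges\n",
              x$phenotype, length(x$tf_set), length(x$target_set),
              nrow(x$edges)))
  invisible(x)
}

#' Topological summary of a regulatory network
#'
#' Node, link, target and TF counts — the row schema of the published
#' per-phenotype GRN comparison table.
#'
#' @param grn A `regulatory_network`.
#' @return List with `n_nodes`, `n_links`, `n_targets`, `n_tfs`.
#' @export
grn_topology <- function(grn) {
  stopifnot(inherits(grn, "regulatory_network"))
  list(n_nodes = length(union(grn$tf_set, grn$target_set)),
       n_links = nrow(grn$edges),
       n_targets = length(grn$target_set),
       n_tfs = length(grn$tf_set))
}

#' Per-TF target-count (out-degree) distributions
#'
#' @param grns Named list of `regulatory_network`s.
#' @return Named list per phenotype: data frame (`tf`, `n_targets`, sorted
#'   by decreasing count) and `summary` (mean and quartiles).
#' @export
target_count_distribution <- function(grns) {
  stopifnot(length(grns) >= 1L)
  lapply(grns, function(g) {
    if (nrow(g$edges) == 0L) {
      return(list(counts = data.frame(tf = character(), n_targets = integer()),
                  summary = NULL))
    }
    tab <- table(g$edges$tf)
    counts <- data.frame(tf = names(tab), n_targets = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts <- counts[order(-counts$n_targets, counts$tf), ]
    rownames(counts) <- NULL
    list(counts = counts,
         summary = list(mean = mean(counts$n_targets),
                        quartiles = quantile(counts$n_targets,
                                             c(0.25, 0.5, 0.75), names = FALSE)))
  })
}

#' Exact Venn-region counts of TF or target sets across phenotypes
#'
#' For every nonempty subset of phenotypes, counts the elements present in
#' exactly that subset; also reports the elements shared by all phenotypes
#' and those unique to each.
#'
#' @param grns Named list of 2-5 `regulatory_network`s with distinct labels.
#' @param what `"tf"` or `"target"` sets.
#' @return List with `regions` (named by `"A&B"`-style keys), `shared_by_all`
#'   and `unique_to_each` (counts), plus `members` per region.
#' @export
set_intersections <- function(grns, what = c("tf", "target")) {
  what <- match.arg(what)
  labels <- names(grns)
  if (is.null(labels) || anyDuplicated(labels) || length(grns) < 2L) {
    stop_coexloc("grns must be a named list (>= 2) with distinct phenotype labels",
                 "coexloc_usage_error")
  }
  sets <- lapply(grns, function(g) if (what == "tf") g$tf_set else g$target_set)
  all_elems <- unique(unlist(sets))
  sig <- vapply(all_elems, function(e) {
    paste(labels[vapply(sets, function(s) e %in% s, logical(1))], collapse = "&")
  }, "")
  regions <- lapply(split(all_elems, sig), sort)
  list(
    regions = lengths(regions),
    members = regions,
    shared_by_all = sum(sig == paste(labels, collapse = "&")),
    unique_to_each = stats::setNames(
      vapply(labels, function(l) sum(sig == l), 0L), labels)
  )
}

#' Per-target regulator counts and chromosome coverage
#'
#' In-degree of every regulated gene, with its chromosome, plus the set of
#' chromosomes that carry at least one regulated target — the coverage that
#' shrinks when regulation concentrates on few chromosomes.
#'
#' @param grn A `regulatory_network`.
#' @param ann Gene annotation (`gene_id`, `chromosome`).
#' @return List with `per_target` (data frame `target`, `in_degree`,
#'   `chromosome`) and `chromosome_coverage` (sorted labels).
#' @export
regulators_per_target <- function(grn, ann) {
  chr <- stats::setNames(ann$chromosome, ann$gene_id)
  if (nrow(grn$edges) == 0L) {
    return(list(per_target = data.frame(target = character(),
                                        in_degree = integer(),
                                        chromosome = character()),
                chromosome_coverage = character()))
  }
  tab <- table(grn$edges$target)
  per <- data.frame(target = names(tab), in_degree = as.integer(tab),
                    chromosome = unname(chr[names(tab)]),
                    stringsAsFactors = FALSE)
  per <- per[order(-per$in_degree, per$target), ]
  rownames(per) <- NULL
  list(per_target = per,
       chromosome_coverage = sort(unique(per$chromosome[!is.na(per$chromosome)])))
}

#' Subnetworks of phenotype-unique TFs
#'
#' For each phenotype, the TFs absent from every other phenotype's TF set,
#' their edges, and for each such TF the chromosome multiset of its targets
#' with a purity flag (all targets on one chromosome).
#'
#' @param grns Named list of >= 2 `regulatory_network`s.
#' @param ann Gene annotation.
#' @return Named list per phenotype: `unique_tfs`, `edges`, and `per_tf`
#'   (list per TF with `chromosomes` table and `single_chromosome` flag).
#' @export
unique_tf_subnetworks <- function(grns, ann) {
  labels <- names(grns)
  if (is.null(labels) || length(grns) < 2L) {
    stop_coexloc("need >= 2 named grns", "coexloc_usage_error")
  }
  chr <- stats::setNames(ann$chromosome, ann$gene_id)
  out <- list()
  for (l in labels) {
    others <- unique(unlist(lapply(grns[setdiff(labels, l)],
                                   function(g) g$tf_set)))
    uniq <- setdiff(grns[[l]]$tf_set, others)
    edges <- grns[[l]]$edges[grns[[l]]$edges$tf %in% uniq, , drop = FALSE]
    per_tf <- lapply(stats::setNames(uniq, uniq), function(tf) {
      tg <- edges$target[edges$tf == tf]
      cc <- chr[tg]
      known <- cc[!is.na(cc)]
      list(chromosomes = table(known),
           single_chromosome = length(known) > 0L && length(unique(known)) == 1L)
    })
    out[[l]] <- list(unique_tfs = uniq, edges = edges, per_tf = per_tf)
  }
  out
}

#' Star-like structures in a regulatory network
#'
#' Treating the network as undirected, finds maximal stars: a center with at
#' least `min_leaves` neighbors of degree 1. Each star is flagged when all
#' its leaf genes share one chromosome — the signature of single-chromosome
#' regulation.
#'
#' @param grn A `regulatory_network`.
#' @param min_leaves Minimum number of degree-1 neighbors (>= 2).
#' @param ann Optional annotation for the chromosome flag.
#' @return List of stars: `center`, `leaves`, `single_chromosome` (`NA`
#'   without annotation).
#' @export
star_structures <- function(grn, min_leaves = 3L, ann = NULL) {
  if (!is_count_scalar(min_leaves) || min_leaves < 2L) {
    stop_coexloc("min_leaves must be an integer >= 2", "coexloc_usage_error")
  }
  e <- grn$edges
  if (nrow(e) == 0L) return(list())
  nodes <- unique(c(e$tf, e$target))
  deg <- table(c(e$tf, e$target))
  chr <- if (!is.null(ann)) stats::setNames(ann$chromosome, ann$gene_id) else NULL
  stars <- list()
  for (center in nodes) {
    nb <- unique(c(e$target[e$tf == center], e$tf[e$target == center]))
    leaves <- nb[deg[nb] == 1L]
    if (length(leaves) >= min_leaves) {
      flag <- NA
      if (!is.null(chr)) {
        cc <- chr[leaves]
        known <- cc[!is.na(cc)]
        flag <- length(known) == length(leaves) && length(unique(known)) == 1L
      }
      stars[[length(stars) + 1L]] <- list(center = center,
                                          leaves = sort(leaves),
                                          single_chromosome = flag)
    }
  }
  stars
}
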