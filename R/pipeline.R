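# End-to-end orchestration: simulate/load -> QC -> MI network -> communities
# -> enrichment -> GRN -> cross-phenotype comparison, with a deterministic
# manifest.

#' Run configuration for the full pipeline
#'
#' Collects every stage tunable in one place. Each phenotype entry either
#' names a synthetic regime (`list(regime = "cis")`) or points at input
#' files (`list(counts = ..., annotation = ..., motifs = ...)`). All
#' randomness flows from `master_seed` through named substreams, so two runs
#' with an identical config are byte-identical.
#'
#' @param phenotypes Named list of phenotype descriptors (see above).
#' @param synthetic Arguments for [synthetic_config()] shared by simulated
#'   phenotypes (`regime` and `seed` are filled per phenotype).
#' @param min_mean,max_zero_frac,sample_sd_multiplier QC thresholds.
#' @param bins MI bins; `NULL` = `floor(sqrt(n_samples))` after QC.
#' @param dpi_tolerance DPI tolerance for the run (default 0.15, the
#'   conventional ARACNe setting).
#' @param top_k Edges kept after thresholding (desk-scale default 2500;
#'   study-scale analyses use 100,000).
#' @param resolution,n_restarts,top_n_communities Louvain stage settings.
#' @param alpha,edge_rule Enrichment/GRN settings.
#' @param kmer Motif k-mer for the census (default the heptamer `CCGGAAG`).
#' @param master_seed Master seed.
#' @param output_dir Where artifacts and the manifest are written.
#' @return A `coexloc_config` list.
#' @export
coexloc_config <- function(phenotypes = list(cancer_like = list(regime = "cis"),
                                             healthy_like = list(regime = "trans")),
                           synthetic = list(),
                           min_mean = 10, max_zero_frac = 0.5,
                           sample_sd_multiplier = 2,
                           bins = NULL, dpi_tolerance = 0.15, top_k = 2500L,
                           resolution = 1, n_restarts = 10L,
                           top_n_communities = 20L,
                           alpha = 0.05,
                           edge_rule = c("intersection", "whole-community"),
                           kmer = "CCGGAAG",
                           master_seed = 1L,
                           output_dir = tempfile("coexloc_run_")) {
  edge_rule <- match.arg(edge_rule)
  if (is.null(names(phenotypes)) || anyDuplicated(names(phenotypes))) {
    stop_coexloc("phenotypes must be a uniquely named list", "coexloc_config_error")
  }
  for (ph in names(phenotypes)) {
    p <- phenotypes[[ph]]
    if (is.null(p$regime) &&
        !all(c("counts", "annotation", "motifs") %in% names(p))) {
      stop_coexloc(sprintf(
        "phenotype '%s' needs either 'regime' (simulate) or 'counts', 'annotation', 'motifs' paths",
        ph), "coexloc_config_error")
    }
  }
  structure(list(phenotypes = phenotypes, synthetic = synthetic,
                 min_mean = min_mean, max_zero_frac = max_zero_frac,
                 sample_sd_multiplier = sample_sd_multiplier,
                 bins = bins, dpi_tolerance = dpi_tolerance,
                 top_k = as.integer(top_k), resolution = resolution,
                 n_restarts = as.integer(n_restarts),
                 top_n_communities = as.integer(top_n_communities),
                 alpha = alpha, edge_rule = edge_rule, kmer = kmer,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = c("coexloc_config", "list"))
}

#' Infer a co-expression network from a normalized matrix
#'
#' Convenience wrapper: MI matrix, DPI pruning, top-k thresholding.
#'
#' @param mat Normalized expression matrix (genes x samples).
#' @param bins MI bins (`NULL` = `floor(sqrt(ncol(mat)))`).
#' @param dpi_tolerance DPI tolerance.
#' @param top_k Edges kept.
#' @return A `coexpression_network`.
#' @export
infer_gcn <- function(mat, bins = NULL, dpi_tolerance = 0, top_k = 100000L) {
  bins <- bins %||% floor(sqrt(ncol(mat)))
  M <- mi_matrix(mat, bins = bins)
  Mp <- apply_dpi(M, tolerance = dpi_tolerance)
  suppressWarnings(top_k_edges(Mp, k = top_k, dpi_tolerance = dpi_tolerance))
}

#' Execute the full pipeline
#'
#' Runs every stage per phenotype, writes all intermediate artifacts under
#' `config$output_dir/<phenotype>/`, then the cross-phenotype comparison
#' report and a manifest recording seeds, artifact checksums, package
#' version, and per-stage record counts. Any stage error aborts the run with
#' the failing stage named and a `failed/MARKER` file left beside the
#' partial outputs.
#'
#' @param config A `coexloc_config`.
#' @return The manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "coexloc_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  current_stage <- "setup"
  fail_marker <- function(e) {
    dir.create(file.path(config$output_dir, "failed"), showWarnings = FALSE)
    writeLines(c(current_stage, conditionMessage(e)),
               file.path(config$output_dir, "failed", "MARKER"))
    stop_coexloc(sprintf("pipeline failed at stage '%s': %s",
                         current_stage, conditionMessage(e)),
                 "coexloc_pipeline_error")
  }
  manifest <- list(package_version = as.character(utils::packageVersion("coexloc")),
                   master_seed = config$master_seed,
                   phenotypes = list(), artifacts = list())
  grns <- list()
  dbs <- list()
  anns <- list()

  tryCatch({
    current_stage <- "config"
    cfg_copy <- unclass(config)
    cfg_copy$output_dir <- NULL  # run location is not part of the run identity
    yaml::write_yaml(cfg_copy, file.path(config$output_dir, "config.yaml"))

    for (ph in names(config$phenotypes)) {
      pdesc <- config$phenotypes[[ph]]
      pdir <- file.path(config$output_dir, ph)
      dir.create(pdir, showWarnings = FALSE)
      counts_of <- list()

      current_stage <- paste0(ph, ":inputs")
      if (!is.null(pdesc$regime)) {
        seed_ph <- derive_seed(config$master_seed, paste0("simulate:", ph))
        scfg <- do.call(synthetic_config,
                        c(config$synthetic,
                          list(regime = pdesc$regime, seed = seed_ph)))
        ds <- generate_dataset(scfg)
        expr <- ds$expression; ann <- ds$annotation; db <- ds$motif_db
        write_expression_matrix(expr, file.path(pdir, "expression.tsv"))
        write_gene_annotation(ann, file.path(pdir, "annotation.tsv"))
        write_motif_db(db, file.path(pdir, "motifs.tsv"))
        truth_df <- data.frame(gene_id = names(ds$truth$module_of_gene),
                               module = ifelse(is.na(ds$truth$module_of_gene), "none",
                                               ds$truth$module_of_gene))
        write.table(truth_df, file.path(pdir, "ground_truth.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$phenotypes[[ph]]$simulate_seed <- seed_ph
      } else {
        expr <- read_expression_matrix(pdesc$counts)
        ann <- read_gene_annotation(pdesc$annotation)
        db <- read_motif_db(pdesc$motifs)
      }
      counts_of$genes_in <- nrow(expr); counts_of$samples_in <- ncol(expr)

      current_stage <- paste0(ph, ":preprocess")
      pre <- preprocess_counts(expr, min_mean = config$min_mean,
                               max_zero_frac = config$max_zero_frac,
                               sd_multiplier = config$sample_sd_multiplier)
      write_expression_matrix(pre$matrix, file.path(pdir, "normalized.tsv"))
      counts_of$genes_retained <- nrow(pre$matrix)
      counts_of$samples_retained <- ncol(pre$matrix)

      current_stage <- paste0(ph, ":gcn")
      net <- infer_gcn(pre$matrix, bins = config$bins,
                       dpi_tolerance = config$dpi_tolerance,
                       top_k = config$top_k)
      write_network(data.frame(node_a = net$gene_a, node_b = net$gene_b,
                               weight = net$mi),
                    file.path(pdir, "network.tsv"), format = "edgelist")
      loc <- locality_stats(net, ann)
      jsonlite::write_json(loc[c("n_edges", "n_edges_annotated", "n_intra",
                                 "fraction_intra", "per_chromosome_edge_counts")],
                           file.path(pdir, "locality.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      counts_of$edges <- nrow(net)
      counts_of$fraction_intra <- loc$fraction_intra

      current_stage <- paste0(ph, ":communities")
      part <- louvain_communities(net, resolution = config$resolution,
                                  seed = derive_seed(config$master_seed,
                                                     paste0("louvain:", ph)),
                                  n_restarts = config$n_restarts)
      comms <- suppressWarnings(top_communities(part, config$top_n_communities))
      comm_df <- data.frame(gene_id = unlist(comms),
                            community_id = rep(names(comms), lengths(comms)),
                            rank = rep(seq_along(comms) - 1L, lengths(comms)))
      write.table(comm_df, file.path(pdir, "communities.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts_of$communities <- length(part$sizes)
      counts_of$modularity <- part$modularity

      current_stage <- paste0(ph, ":enrich")
      enr <- enrich_communities(comms, db, alpha = config$alpha)
      grn <- suppressWarnings(build_grn(enr, comms, db, phenotype = ph,
                                        edge_rule = config$edge_rule))
      enr_out <- enr
      class(enr_out) <- "data.frame"
      write.table(enr_out, file.path(pdir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(grn$edges)) {
        write_network(data.frame(node_a = grn$edges$tf,
                                 node_b = grn$edges$target, weight = 1),
                      file.path(pdir, "grn.tsv"), format = "edgelist",
                      directed = TRUE)
      }
      counts_of$tests <- nrow(enr)
      counts_of$significant <- sum(enr$significant)
      counts_of$grn_edges <- nrow(grn$edges)

      grns[[ph]] <- grn
      dbs[[ph]] <- db
      anns[[ph]] <- ann
      manifest$phenotypes[[ph]] <- c(manifest$phenotypes[[ph]], counts_of)
    }

    current_stage <- "compare"
    if (length(grns) >= 2L) {
      ann_all <- unique(do.call(rbind, anns))
      report <- compare_grns(grns, ann_all, dbs[[1L]], kmer = config$kmer)
      jsonlite::write_json(report, file.path(config$output_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    current_stage <- "manifest"
    files <- sort(list.files(config$output_dir, recursive = TRUE,
                             full.names = FALSE))
    files <- setdiff(files, "manifest.json")
    sums <- tools::md5sum(file.path(config$output_dir, files))
    manifest$artifacts <- stats::setNames(as.list(unname(sums)), files)
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    if (inherits(e, "coexloc_error") &&
        grepl("pipeline failed at stage", conditionMessage(e))) stop(e)
    fail_marker(e)
  })
  invisible(manifest)
}

#' Cross-phenotype GRN comparison report
#'
#' Assembles the comparative statistics: per-phenotype topology rows,
#' target-count distributions, exact Venn-region counts over TF and target
#' sets, star structures, unique-TF subnetworks, and the motif k-mer census.
#'
#' @param grns Named list of `regulatory_network`s.
#' @param ann Gene annotation covering the union of targets.
#' @param db The `motif_db` (shared motif universe for the census).
#' @param kmer k-mer for [kmer_census()].
#' @return Nested list (JSON-serializable).
#' @export
compare_grns <- function(grns, ann, db, kmer = "CCGGAAG") {
  topo <- lapply(grns, grn_topology)
  dist <- target_count_distribution(grns)
  venn_tf <- set_intersections(grns, what = "tf")
  venn_tg <- set_intersections(grns, what = "target")
  stars <- lapply(grns, function(g) {
    s <- star_structures(g, min_leaves = 3L, ann = ann)
    list(n_stars = length(s),
         n_single_chromosome = sum(vapply(s, function(x) isTRUE(x$single_chromosome),
                                          logical(1))))
  })
  uniq <- unique_tf_subnetworks(grns, ann)
  uniq_summary <- lapply(uniq, function(u) {
    list(n_unique_tfs = length(u$unique_tfs),
         n_single_chromosome = sum(vapply(u$per_tf,
                                          function(p) isTRUE(p$single_chromosome),
                                          logical(1))))
  })
  census <- lapply(grns, function(g) {
    kc <- kmer_census(db, g, kmer)
    kc[c("n_tfs_with_kmer", "n_targets_regulated")]
  })
  cov <- lapply(grns, function(g) regulators_per_target(g, ann)$chromosome_coverage)
  list(topology = topo,
       target_count_summary = lapply(dist, `[[`, "summary"),
       venn_tf = list(regions = as.list(venn_tf$regions),
                      shared_by_all = venn_tf$shared_by_all,
                      unique_to_each = as.list(venn_tf$unique_to_each)),
       venn_target = list(regions = as.list(venn_tg$regions),
                          shared_by_all = venn_tg$shared_by_all,
                          unique_to_each = as.list(venn_tg$unique_to_each)),
       stars = stars,
       unique_tf = uniq_summary,
       kmer = list(kmer = kmer, census = census),
       chromosome_coverage = cov)
}
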