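#' Configuration for the synthetic expression generator
#'
#' Describes a planted-structure RNA-seq-like dataset: genes are assigned to
#' chromosomes round-robin, a set of co-expression modules is planted either
#' chromosome-confined (`regime = "cis"`, emulating the cancer-like loss of
#' long-range co-expression) or chromosome-spanning (`regime = "trans"`,
#' healthy-like), and counts are emitted from a negative binomial whose log
#' mean is driven by one Gaussian latent factor per module. A motif database
#' with true regulons (one planted module each, corrupted at rate
#' `target_noise`) plus size-matched random decoys gives the enrichment stage
#' a measurable specificity surface.
#'
#' Defaults are the packaged desk-scale study conditions: 400 genes on 10
#' chromosomes, 16 modules of 20 genes, 150 samples, latent-factor loading
#' 1.5, 10 true TFs at 10% target noise and 50 decoys.
#'
#' @param n_genes,n_samples,n_chromosomes,n_modules,module_size Problem sizes.
#' @param regime `"cis"` (modules chromosome-pure) or `"trans"`
#'   (chromosome-unconstrained module membership).
#' @param effect_beta Latent-factor loading on the natural-log mean of member
#'   genes; 0 turns the planted signal off.
#' @param baseline_log_mean Natural-log baseline count mean (default `log(150)`
#'   scale counts, comfortably above the QC mean filter).
#' @param dispersion Negative-binomial dispersion `phi` (variance
#'   `mu + phi * mu^2`); must be > 0.
#' @param n_true_tfs,n_decoy_tfs Numbers of planted-regulon and decoy TFs.
#' @param target_noise Fraction of each true regulon swapped for random
#'   non-module genes, in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 400L, n_samples = 150L,
                             n_chromosomes = 10L, n_modules = 16L,
                             module_size = 20L, regime = c("cis", "trans"),
                             effect_beta = 1.5, baseline_log_mean = 5,
                             dispersion = 0.15, n_true_tfs = 10L,
                             n_decoy_tfs = 50L, target_noise = 0.1,
                             seed = 1L) {
  regime <- match.arg(regime)
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size), regime = regime,
              effect_beta = effect_beta, baseline_log_mean = baseline_log_mean,
              dispersion = dispersion, n_true_tfs = as.integer(n_true_tfs),
              n_decoy_tfs = as.integer(n_decoy_tfs),
              target_noise = target_noise, seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1L || n_samples < 1L || n_chromosomes < 1L)
      stop_coexloc("n_genes, n_samples, n_chromosomes must be >= 1",
                   "coexloc_config_error")
    if (n_modules < 0L || module_size < 1L)
      stop_coexloc("n_modules must be >= 0 and module_size >= 1",
                   "coexloc_config_error")
    if (n_modules * module_size > n_genes)
      stop_coexloc("n_modules * module_size exceeds n_genes",
                   "coexloc_config_error")
    if (effect_beta < 0) stop_coexloc("effect_beta must be >= 0",
                                      "coexloc_config_error")
    if (dispersion <= 0) stop_coexloc("dispersion must be > 0",
                                      "coexloc_config_error")
    if (target_noise < 0 || target_noise > 1)
      stop_coexloc("target_noise must be in [0, 1]", "coexloc_config_error")
  })
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

#' Generate a synthetic dataset with planted co-expression and regulons
#'
#' See [synthetic_config()] for the generative model. In the cis regime every
#' planted module lies on one chromosome (a configuration error is raised if
#' chromosome capacity cannot hold the modules assigned to it); in the trans
#' regime members are sampled without chromosome constraint. Module genes
#' have negative-binomial counts with log mean
#' `baseline_log_mean + effect_beta * z_m` for a per-sample standard-normal
#' latent factor `z_m`; background genes use loading zero. True TF `i` gets
#' the planted module `((i - 1) %% n_modules) + 1` as regulon, with
#' `floor(target_noise * module_size)` members swapped for random non-module
#' genes; decoy TFs get uniform random target sets of the same size.
#'
#' @param config A `synthetic_config`.
#' @return A list of class `synthetic_dataset` with elements `expression`
#'   (genes x samples integer count matrix), `annotation` (gene_id,
#'   chromosome), `motif_db`, and `truth` (list with `module_of_gene`,
#'   `regulon_of_tf`, `true_tfs`, `decoy_tfs`, `regime`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)),
               length.out = cfg$n_genes)
  ann <- data.frame(gene_id = gene_ids, chromosome = chrom,
                    stringsAsFactors = FALSE)

  module_of <- rep(NA_integer_, cfg$n_genes)
  if (cfg$n_modules > 0L) {
    if (cfg$regime == "cis") {
      chr_of_module <- rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_modules)
      demand <- table(factor(chr_of_module, levels = seq_len(cfg$n_chromosomes)))
      capacity <- table(factor(as.integer(chrom), levels = seq_len(cfg$n_chromosomes)))
      if (any(demand * cfg$module_size > capacity)) {
        stop_coexloc("cis regime infeasible: module demand exceeds genes on a chromosome",
                     "coexloc_config_error")
      }
      for (m in seq_len(cfg$n_modules)) {
        pool <- which(chrom == as.character(chr_of_module[m]) & is.na(module_of))
        module_of[sample(pool, cfg$module_size)] <- m
      }
    } else {
      for (m in seq_len(cfg$n_modules)) {
        pool <- which(is.na(module_of))
        module_of[sample(pool, cfg$module_size)] <- m
      }
    }
  }

  # One standard-normal latent factor per module per sample drives the
  # log mean of member genes.
  z <- matrix(rnorm(max(cfg$n_modules, 1L) * cfg$n_samples),
              nrow = max(cfg$n_modules, 1L))
  log_mu <- matrix(cfg$baseline_log_mean, cfg$n_genes, cfg$n_samples)
  for (g in which(!is.na(module_of))) {
    log_mu[g, ] <- cfg$baseline_log_mean + cfg$effect_beta * z[module_of[g], ]
  }
  counts <- matrix(rnbinom(cfg$n_genes * cfg$n_samples,
                           mu = exp(log_mu), size = 1 / cfg$dispersion),
                   cfg$n_genes, cfg$n_samples,
                   dimnames = list(gene_ids, sprintf("S%03d", seq_len(cfg$n_samples))))

  # Regulons: true TFs inherit a planted module with a noise swap; decoys
  # draw uniform target sets of matched size.
  n_swap <- floor(cfg$target_noise * cfg$module_size)
  true_tfs <- if (cfg$n_true_tfs > 0L) sprintf("TF%02d", seq_len(cfg$n_true_tfs)) else character()
  decoy_tfs <- if (cfg$n_decoy_tfs > 0L) sprintf("DTF%02d", seq_len(cfg$n_decoy_tfs)) else character()
  regulons <- list()
  for (i in seq_along(true_tfs)) {
    m <- ((i - 1L) %% max(cfg$n_modules, 1L)) + 1L
    members <- gene_ids[which(module_of == m)]
    keep <- if (n_swap > 0L) sample(members, cfg$module_size - n_swap) else members
    outside <- setdiff(gene_ids[is.na(module_of) | module_of != m], members)
    noise <- if (n_swap > 0L) sample(outside, n_swap) else character()
    regulons[[true_tfs[i]]] <- sort(c(keep, noise))
  }
  for (d in decoy_tfs) {
    regulons[[d]] <- sort(sample(gene_ids, cfg$module_size))
  }
  all_tfs <- c(true_tfs, decoy_tfs)
  motifs <- vapply(all_tfs, function(x) random_iupac_motif(), "")
  db <- if (length(all_tfs)) motif_db(all_tfs, motifs, regulons[all_tfs]) else NULL

  truth <- list(
    module_of_gene = stats::setNames(module_of, gene_ids),
    regulon_of_tf = regulons,
    true_tfs = true_tfs,
    decoy_tfs = decoy_tfs,
    regime = cfg$regime
  )
  structure(list(expression = counts, annotation = ann, motif_db = db,
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

# Random IUPAC motif, ACGT-heavy with occasional degenerate symbols,
# length 8-12 -- plausible TFBS-like strings for fixtures.
random_iupac_motif <- function() {
  len <- sample(8:12, 1L)
  core <- c("A", "C", "G", "T")
  degen <- setdiff(IUPAC_ALPHABET, core)
  paste(ifelse(stats::runif(len) < 0.8, sample(core, len, replace = TRUE),
               sample(degen, len, replace = TRUE)), collapse = "")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Synthetic dataset (%s regime): %d genes x %d samples, ",
                     "%d chromosomes, %d modules of %d, %d true + %d decoy TFs\n"),
              cfg$regime, cfg$n_genes, cfg$n_samples, cfg$n_chromosomes,
              cfg$n_modules, cfg$module_size, cfg$n_true_tfs, cfg$n_decoy_tfs))
  invisible(x)
}

#' Planted-signal diagnostic: within- vs between-module correlation
#'
#' Samples gene pairs and reports the mean absolute Pearson correlation of
#' `log2(count + 1)` profiles within planted modules versus between modules.
#' Used to check that the generator actually plants a detectable signal.
#'
#' @param expression Count matrix from [generate_dataset()].
#' @param truth The dataset's `truth` element.
#' @param n_pairs Pairs sampled per stratum.
#' @param seed Sampling seed.
#' @return List with `within`, `between` (mean |r|; `within` is `NA` with
#'   `degenerate = TRUE` when no modules exist), and the pair counts used.
#' @export
module_signal_check <- function(expression, truth, n_pairs = 200L, seed = 1L) {
  mod <- truth$module_of_gene[rownames(expression)]
  lx <- log2(expression + 1)
  with_seed(seed, {
    in_mod <- names(mod)[!is.na(mod)]
    within_pairs <- list()
    if (length(in_mod)) {
      mods <- unique(mod[in_mod])
      for (i in seq_len(n_pairs)) {
        m <- sample(mods, 1L)
        within_pairs[[i]] <- sample(names(mod)[which(mod == m)], 2L)
      }
    }
    between_pairs <- lapply(seq_len(n_pairs), function(i) {
      repeat {
        p <- sample(rownames(expression), 2L)
        if (is.na(mod[p[1L]]) || is.na(mod[p[2L]]) || mod[p[1L]] != mod[p[2L]]) return(p)
      }
    })
    absr <- function(p) abs(cor(lx[p[1L], ], lx[p[2L], ]))
    within <- if (length(within_pairs)) mean(vapply(within_pairs, absr, 0)) else NA_real_
    between <- mean(vapply(between_pairs, absr, 0))
    list(within = within, between = between,
         n_within = length(within_pairs), n_between = length(between_pairs),
         degenerate = length(within_pairs) == 0L)
  })
}
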