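# Fixtures built in code at test time; nothing binary on disk.

write_expression_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# The documented 10-gene x 8-sample QC fixture:
#   G01-G04 retained (mean >= 10, zeros <= 50%); sample S8 is an extreme
#   outlier in these genes.
#   G05-G07 fail the mean rule only (mean 5, no zeros).
#   G08-G09 fail the zero rule only (5/8 zeros, mean 15).
#   G10 fails both (7/8 zeros, mean 1) -> listed under the zero rule.
qc_fixture_matrix <- function() {
  rows <- rbind(
    G01 = c(15, 20, 25, 30, 20, 15, 25, 500),
    G02 = c(20, 15, 30, 25, 15, 20, 30, 500),
    G03 = c(25, 30, 15, 20, 30, 25, 15, 500),
    G04 = c(30, 25, 20, 15, 25, 30, 20, 500),
    G05 = c(5, 5, 5, 5, 5, 5, 5, 5),
    G06 = c(4, 6, 4, 6, 4, 6, 4, 6),
    G07 = c(9, 9, 9, 9, 9, 9, 9, 9),
    G08 = c(0, 0, 0, 0, 0, 40, 40, 40),
    G09 = c(0, 0, 0, 0, 0, 38, 41, 41),
    G10 = c(0, 0, 0, 0, 0, 0, 0, 8)
  )
  colnames(rows) <- sprintf("S%d", 1:8)
  rows
}

# Tiny motif database with three TFs over a 6-gene universe.
tiny_motif_db <- function() {
  motif_db(tf = c("ZF5", "E2F", "ELK"),
           motif = c("GSGCGCGR", "GGCGSG", "RCCGGAAGTGN"),
           targets = list(c("G1", "G2", "G3"),
                          c("G4", "G5"),
                          c("G1", "G5", "G6")))
}

# Deterministic small synthetic config for unit tests (not the study-scale
# defaults; those are exercised by the acceptance suite).
small_synth <- function(regime = "cis", seed = 42L, ...) {
  synthetic_config(n_genes = 60L, n_samples = 64L, n_chromosomes = 5L,
                   n_modules = 4L, module_size = 10L, regime = regime,
                   n_true_tfs = 4L, n_decoy_tfs = 8L, seed = seed, ...)
}
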