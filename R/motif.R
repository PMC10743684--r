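# IUPAC degenerate nucleotide codes and k-mer matching over motif strings.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

validate_iupac <- function(s, context = NULL) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    stop_coexloc(sprintf("motif%s must be a non-empty string",
                         if (is.null(context)) "" else paste0(" for '", context, "'")),
                 "coexloc_format_error")
  }
  chars <- strsplit(toupper(s), "")[[1L]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) {
    stop_coexloc(sprintf("invalid IUPAC character(s) %s in motif '%s'%s",
                         paste(sQuote(bad), collapse = ", "), s,
                         if (is.null(context)) "" else paste0(" (TF '", context, "')")),
                 "coexloc_format_error")
  }
  invisible(toupper(s))
}

#' Test whether a motif contains a k-mer
#'
#' Two notions of containment are supported. `"literal"` asks whether the
#' k-mer occurs verbatim as a substring of the motif text — the convention
#' used when classifying published motif strings, under which e.g.
#' `NRSCGGAAGNN` does *not* contain `CCGGAAG` even though the degenerate
#' symbol `S` can denote `C`. `"iupac"` asks whether some window of the motif
#' can denote the k-mer under IUPAC degeneracy, i.e. every window symbol's
#' base set contains the corresponding k-mer base.
#'
#' @param motif IUPAC motif string.
#' @param kmer k-mer over `{A,C,G,T}` (IUPAC symbols are allowed in
#'   `"literal"` mode, where matching is plain text).
#' @param mode `"literal"` (default) or `"iupac"`.
#' @return Logical flag.
#' @export
motif_contains_kmer <- function(motif, kmer, mode = c("literal", "iupac")) {
  mode <- match.arg(mode)
  motif <- validate_iupac(motif)
  kmer <- validate_iupac(kmer)
  if (mode == "literal") {
    return(grepl(kmer, motif, fixed = TRUE))
  }
  mk <- strsplit(motif, "")[[1L]]
  kk <- strsplit(kmer, "")[[1L]]
  if (any(!kk %in% c("A", "C", "G", "T"))) {
    stop_coexloc("iupac-mode k-mer must be a concrete A/C/G/T string",
                 "coexloc_value_error")
  }
  w <- length(kk)
  if (length(mk) < w) return(FALSE)
  for (start in seq_len(length(mk) - w + 1L)) {
    win <- mk[start:(start + w - 1L)]
    ok <- all(vapply(seq_len(w),
                     function(i) kk[i] %in% IUPAC_SETS[[win[i]]], logical(1)))
    if (ok) return(TRUE)
  }
  FALSE
}

#' Census of a k-mer over the motifs behind a regulatory network
#'
#' Counts the TFs of a regulatory network whose binding motif contains the
#' k-mer, and the number of distinct genes those TFs regulate in the network
#' (the size of the union of their target sets).
#'
#' @param db A `motif_db`.
#' @param grn A `regulatory_network` built from `db`.
#' @param kmer k-mer string, e.g. the heptamer `"CCGGAAG"`.
#' @param mode Containment mode passed to [motif_contains_kmer()].
#' @return List with `n_tfs_with_kmer`, `n_targets_regulated`, and
#'   `tfs_with_kmer` (the TF names).
#' @export
kmer_census <- function(db, grn, kmer, mode = c("literal", "iupac")) {
  mode <- match.arg(mode)
  tfs <- intersect(grn$tf_set, db$tf)
  has <- vapply(tfs, function(tf) {
    motif_contains_kmer(db$motif[match(tf, db$tf)], kmer, mode = mode)
  }, logical(1))
  hit_tfs <- tfs[has]
  targets <- unique(grn$edges$target[grn$edges$tf %in% hit_tfs])
  list(n_tfs_with_kmer = length(hit_tfs),
       n_targets_regulated = length(targets),
       tfs_with_kmer = sort(hit_tfs))
}
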