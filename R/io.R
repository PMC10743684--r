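#' Read a gene-by-sample expression matrix
#'
#' Parses a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. All cells must be nonnegative
#' numbers; missing or non-numeric cells, negative values, duplicated gene or
#' sample identifiers, and ragged rows are load errors, never silently
#' repaired.
#'
#' @param path Path to a tab-separated expression file.
#' @return A numeric matrix (genes x samples) with unique row and column
#'   names, in file order.
#' @export
read_expression_matrix <- function(path) {
  raw <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character", fill = FALSE, quote = ""),
    error = function(e) stop_coexloc(
      sprintf("malformed expression file '%s': %s", path, conditionMessage(e)),
      "coexloc_format_error")
  )
  if (ncol(raw) < 2L) {
    stop_coexloc("expression file needs a gene-id column plus >= 1 sample column",
                 "coexloc_format_error")
  }
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(gene_ids)) {
    stop_coexloc(sprintf("duplicate gene id(s): %s",
                         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")),
                 "coexloc_identity_error")
  }
  if (anyDuplicated(sample_ids)) {
    stop_coexloc(sprintf("duplicate sample id(s): %s",
                         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
                 "coexloc_identity_error")
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_coexloc(sprintf("non-numeric or missing cell at gene '%s', sample '%s'",
                         gene_ids[bad[1L]], sample_ids[bad[2L]]),
                 "coexloc_value_error")
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop_coexloc(sprintf("negative cell at gene '%s', sample '%s'",
                         gene_ids[bad[1L]], sample_ids[bad[2L]]),
                 "coexloc_value_error")
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write an expression matrix as tab-separated text
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects tab-separated columns `gene_id`, `chromosome` and optionally
#' `cytoband`. Chromosome labels are opaque strings; only same-chromosome
#' membership is ever used downstream.
#'
#' @param path Path to the annotation file.
#' @return A data frame with columns `gene_id`, `chromosome` and, when
#'   present in the file, `cytoband`.
#' @export
read_gene_annotation <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  need <- c("gene_id", "chromosome")
  if (!all(need %in% colnames(ann))) {
    stop_coexloc("annotation file must have columns 'gene_id' and 'chromosome'",
                 "coexloc_format_error")
  }
  if (anyDuplicated(ann$gene_id)) {
    stop_coexloc(sprintf("duplicate annotation record(s) for: %s",
                         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", ")),
                 "coexloc_identity_error")
  }
  keep <- intersect(c("gene_id", "chromosome", "cytoband"), colnames(ann))
  ann[, keep, drop = FALSE]
}

#' @rdname read_gene_annotation
#' @param ann Annotation data frame.
#' @export
write_gene_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## --- Motif database ---------------------------------------------------------

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' Read a transcription-factor motif database
#'
#' The database is a flat tab-separated file with columns `tf`, `motif`
#' (an IUPAC degenerate nucleotide string) and `targets` (comma-separated
#' candidate target gene ids). One record per transcription factor.
#'
#' @param path Path to the motif file.
#' @return A `motif_db`: a data frame with character columns `tf`, `motif`
#'   and a list column `targets` of character vectors.
#' @export
read_motif_db <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  need <- c("tf", "motif", "targets")
  if (!all(need %in% colnames(raw))) {
    stop_coexloc("motif file must have columns 'tf', 'motif', 'targets'",
                 "coexloc_format_error")
  }
  targets <- lapply(strsplit(raw$targets, ","), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  motif_db(raw$tf, raw$motif, targets)
}

#' Construct and validate a motif database in memory
#'
#' @param tf Character vector of unique transcription-factor names.
#' @param motif Character vector of IUPAC motif strings.
#' @param targets List of character vectors of candidate target gene ids.
#' @return A validated `motif_db` data frame.
#' @export
motif_db <- function(tf, motif, targets) {
  stopifnot(length(tf) == length(motif), length(tf) == length(targets))
  if (anyDuplicated(tf)) {
    stop_coexloc(sprintf("duplicate TF name(s): %s",
                         paste(unique(tf[duplicated(tf)]), collapse = ", ")),
                 "coexloc_identity_error")
  }
  for (i in seq_along(tf)) {
    validate_iupac(motif[i], context = tf[i])
    if (length(targets[[i]]) == 0L) {
      stop_coexloc(sprintf("TF '%s' has an empty target list", tf[i]),
                   "coexloc_format_error")
    }
  }
  db <- data.frame(tf = tf, motif = motif, stringsAsFactors = FALSE)
  db$targets <- lapply(targets, unique)
  class(db) <- c("motif_db", "data.frame")
  db
}

#' @rdname read_motif_db
#' @param db A `motif_db`.
#' @export
write_motif_db <- function(db, path) {
  out <- data.frame(tf = db$tf, motif = db$motif,
                    targets = vapply(db$targets, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.motif_db <- function(x, ...) {
  cat(sprintf("Motif database: %d TFs, %d distinct candidate targets\n",
              nrow(x), length(unique(unlist(x$targets)))))
  invisible(x)
}

## --- Network files -----------------------------------------------------------

#' Write a network to disk
#'
#' Undirected networks are canonicalized so each edge appears once with
#' `node_a < node_b` lexicographically. Two formats are supported: a plain
#' tab-separated edge list (`node_a`, `node_b`, `weight`) and GraphML.
#'
#' @param edges Data frame with columns `node_a`, `node_b`, `weight`.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param directed Logical; directed edges are written as given.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("edgelist", "graphml"),
                          directed = FALSE) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_coexloc(
                       sprintf("unknown network format '%s'", format[1L]),
                       "coexloc_usage_error"))
  edges <- canonical_edges(edges, directed = directed)
  if (format == "edgelist") {
    out <- data.frame(node_a = edges$node_a, node_b = edges$node_b,
                      weight = sprintf("%.17g", edges$weight))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = directed)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "graphml"),
                         directed = FALSE) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_coexloc(
                       sprintf("unknown network format '%s'", format[1L]),
                       "coexloc_usage_error"))
  if (format == "edgelist") {
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", quote = "")
    if (!all(c("node_a", "node_b", "weight") %in% colnames(raw))) {
      stop_coexloc("edge list must have columns node_a, node_b, weight",
                   "coexloc_format_error")
    }
    edges <- data.frame(node_a = raw$node_a, node_b = raw$node_b,
                        weight = as.numeric(raw$weight),
                        stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(node_a = el$from, node_b = el$to,
                        weight = if ("weight" %in% colnames(el)) el$weight else 1,
                        stringsAsFactors = FALSE)
  }
  canonical_edges(edges, directed = directed)
}

# Canonical form: no self-loops, no duplicate edges; undirected endpoints
# ordered node_a < node_b, rows sorted for stable output.
canonical_edges <- function(edges, directed = FALSE) {
  stopifnot(all(c("node_a", "node_b", "weight") %in% colnames(edges)))
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (any(edges$node_a == edges$node_b)) {
    stop_coexloc("self-loop edges are not allowed", "coexloc_format_error")
  }
  if (any(edges$weight < 0)) {
    stop_coexloc("edge weights must be nonnegative", "coexloc_value_error")
  }
  if (!directed && nrow(edges)) {
    swap <- edges$node_a > edges$node_b
    tmp <- edges$node_a[swap]
    edges$node_a[swap] <- edges$node_b[swap]
    edges$node_b[swap] <- tmp
  }
  key <- paste(edges$node_a, edges$node_b, sep = "\r")
  if (anyDuplicated(key)) {
    stop_coexloc("duplicate edges in network", "coexloc_format_error")
  }
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges[, c("node_a", "node_b", "weight")]
}
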