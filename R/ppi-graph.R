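# Shared protein-protein interaction topology and per-patient graphs.
#
# Edges are STRING-style scored gene pairs. The confidence filter keeps
# combined scores >= 400 (medium confidence on the 0-1000 scale). All
# patients share one topology; only node features differ.

#' Split a gene query list into API-sized batches
#'
#' Network retrieval from a STRING-style service is performed in batches of
#' 100 genes per query; this returns the batch structure without touching
#' the network.
#'
#' @param genes character vector of query genes.
#' @param batch_size genes per batch.
#' @return list of character vectors.
#' @export
string_query_batches <- function(genes, batch_size = 100L) {
  if (length(genes) == 0) stopf("gene query list must be non-empty")
  split(genes, ceiling(seq_along(genes) / batch_size))
}

#' Load scored PPI edges from a local edge file
#'
#' Reads a three-column TSV (`gene_a`, `gene_b`, `combined_score` on the
#' 0-1000 integer scale) and drops rows below `min_score`. Malformed rows
#' (missing endpoint or non-numeric score) are skipped and counted in a
#' message. Live network retrieval (human, taxon 9606, batched queries of
#' 100 genes) is not performed by this package; pointing `source` at
#' anything but a readable local file raises an error directing you to
#' offline-file mode.
#'
#' @param source path to a local TSV edge file.
#' @param min_score minimum combined score to keep (default 400).
#' @return data.frame of raw edge rows passing the score filter.
#' @export
load_string_edges <- function(source, min_score = 400) {
  if (!(is.character(source) && length(source) == 1 && file.exists(source)))
    stopf(paste("network retrieval is not available: provide a local edge file",
                "(TSV: gene_a, gene_b, combined_score). A live client would query",
                "the human (9606) network in batches of 100 genes."))
  df <- read_tsv(source)
  if (ncol(df) < 3) stopf("edge file needs 3 columns: gene_a, gene_b, combined_score")
  names(df)[1:3] <- c("gene_a", "gene_b", "combined_score")
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- is.na(score) | is.na(df$gene_a) | is.na(df$gene_b) |
    !nzchar(trimws(as.character(df$gene_a))) | !nzchar(trimws(as.character(df$gene_b)))
  if (any(bad)) message(sprintf("skipped %d malformed edge rows", sum(bad)))
  df <- df[!bad, , drop = FALSE]
  score <- score[!bad]
  keep <- score >= min_score
  data.frame(gene_a = as.character(df$gene_a[keep]),
             gene_b = as.character(df$gene_b[keep]),
             combined_score = score[keep], stringsAsFactors = FALSE)
}

#' Deduplicate edges and restrict to the annotated gene universe
#'
#' `(a,b)` and `(b,a)` collapse to one unordered edge keeping the maximum
#' score; self-loops are removed; edges with an endpoint outside
#' `annotated_genes` are dropped. Nodes are the genes left with at least
#' one edge (lexicographically ordered), plus, when `keep_isolated = TRUE`,
#' the annotated genes with no surviving edge (they still receive a
#' self-loop during attention so their own signal propagates).
#'
#' @param raw data.frame of edge rows (`gene_a`, `gene_b`, `combined_score`).
#' @param annotated_genes character vector of genes present in the
#'   annotated multi-omics data.
#' @param keep_isolated keep annotated genes without any edge as nodes.
#' @return a `ppi_network`: list(`nodes`, `edges`).
#' @export
dedupe_and_restrict <- function(raw, annotated_genes, keep_isolated = FALSE) {
  a <- toupper(trimws(raw$gene_a)); b <- toupper(trimws(raw$gene_b))
  s <- as.numeric(raw$combined_score)
  ann <- toupper(trimws(annotated_genes))
  keep <- a != b & a %in% ann & b %in% ann
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    mx <- tapply(s, key, max)
    parts <- strsplit(names(mx), "\r", fixed = TRUE)
    edges <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                        gene_b = vapply(parts, `[`, "", 2),
                        combined_score = as.numeric(mx),
                        stringsAsFactors = FALSE, row.names = NULL)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        combined_score = numeric(0), stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (keep_isolated) nodes <- sort(unique(c(nodes, ann)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Assemble per-patient graphs on the shared topology
#'
#' One graph per sample: the shared `ppi_network` plus a nodes-by-3 feature
#' matrix in channel order (mRNA, methylation, miRNA). Genes in the network
#' missing from the gene table get all-zero rows (counted in a message).
#'
#' @param network a [dedupe_and_restrict()] result.
#' @param gene_table a [build_gene_table()] result.
#' @param labels optional named factor of subtype labels; every labelled
#'   sample must be present in the gene table.
#' @return a `patient_graphs` object: list(`network`, `features`
#'   (nodes x 3 x samples array), `sample_ids`, `labels`).
#' @export
assemble_patient_graphs <- function(network, gene_table, labels = NULL) {
  stopifnot(inherits(network, "ppi_network"), inherits(gene_table, "gene_table"))
  if (!is.null(labels)) {
    missing <- setdiff(names(labels), gene_table$sample_ids)
    if (length(missing))
      stopf("labelled samples missing from the gene table: %s",
            paste(missing, collapse = ", "))
    labels <- labels[gene_table$sample_ids]
  }
  absent <- setdiff(network$nodes, gene_table$genes)
  if (length(absent))
    message(sprintf("%d network genes absent from the gene table; zero-filled", length(absent)))
  X <- flatten_gene_table(gene_table)
  feats <- flat_to_graph_features(X, network$nodes)
  structure(list(network = network, features = feats,
                 sample_ids = gene_table$sample_ids, labels = labels),
            class = "patient_graphs")
}

#' @export
print.patient_graphs <- function(x, ...) {
  cat(sprintf("<patient_graphs> %d patients on %d nodes (3 channels)\n",
              length(x$sample_ids), length(x$network$nodes)))
  invisible(x)
}

# Directed edge index with self-loops in the CSR layout the C++ forward
# pass expects (0-based, sorted by target node).
graph_edge_index <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  ia <- match(network$edges$gene_a, nodes)
  ib <- match(network$edges$gene_b, nodes)
  tgt <- c(ia, ib, seq_len(n))
  src <- c(ib, ia, seq_len(n))
  o <- order(tgt, src)
  tgt <- tgt[o]; src <- src[o]
  rowptr <- c(0L, cumsum(tabulate(tgt, nbins = n)))
  list(edge_i = as.integer(tgt - 1L), edge_j = as.integer(src - 1L),
       rowptr = as.integer(rowptr), n_nodes = n)
}
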