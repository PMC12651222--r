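# Gene-centric annotation of the three omics layers.
#
# miRNAs resolve to their most frequently reported target gene, CpG probes
# to a deduplicated gene set, and the three layers combine into one
# per-gene three-channel table (mRNA, methylation, miRNA) with zero fill
# for channels a gene does not carry.

#' Construct an omics matrix
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#' @param modality one of `"mrna"`, `"mirna"`, `"meth"`.
#' @return an `omics_matrix` object.
#' @export
omics_matrix <- function(values, modality = c("mrna", "mirna", "meth")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stopf("omics matrix needs sample ids as rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stopf("omics matrix needs feature ids as colnames")
  ids <- colnames(values) %||% character(0)
  norm_ids <- if (modality == "mirna" && length(ids)) normalize_mirna_ids(ids) else ids
  if (anyDuplicated(norm_ids))
    stopf("feature ids not unique after normalization: %s",
          paste(unique(norm_ids[duplicated(norm_ids)]), collapse = ", "))
  structure(list(values = values,
                 sample_ids = rownames(values),
                 feature_ids = ids,
                 modality = modality),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d samples x %d features\n",
              x$modality, length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' Write / read an omics matrix as TSV
#'
#' First column `sample_id`, remaining columns the feature ids.
#' @param om an [omics_matrix()].
#' @param path file path.
#' @return `path` (write) or an `omics_matrix` (read).
#' @export
write_omics_matrix <- function(om, path) {
  stopifnot(inherits(om, "omics_matrix"))
  df <- data.frame(sample_id = om$sample_ids, om$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_omics_matrix
#' @param modality modality tag for the matrix being read.
#' @export
read_omics_matrix <- function(path, modality) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  omics_matrix(m, modality)
}

#' Normalize miRNA identifiers
#'
#' Lowercases and strips trailing arm/variant suffixes (`-3p`, `-5p`,
#' `.<digit>`), repeatedly, so the result is idempotent.
#'
#' @param ids character vector of raw miRNA identifiers.
#' @return normalized identifiers.
#' @export
normalize_mirna_ids <- function(ids) {
  if (length(ids) == 0) return(character(0))
  if (any(is.na(ids)) || any(!nzchar(trimws(ids))))
    stopf("miRNA identifiers must be non-empty strings")
  out <- tolower(trimws(ids))
  repeat {
    nxt <- sub("(-3p|-5p|\\.[0-9]+)$", "", out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  out
}

#' Resolve each miRNA to its most frequently reported target gene
#'
#' Report counts are summed per (miRNA, gene) after identifier
#' normalization; the gene with the maximum total wins, ties broken by
#' lexicographically smallest gene symbol. miRNAs with no usable rows are
#' excluded with a message.
#'
#' @param mirna_map data.frame with columns `mirna_id`, `target_gene`,
#'   `report_count`.
#' @return named character vector: normalized miRNA id -> gene symbol.
#' @export
resolve_mirna_targets <- function(mirna_map) {
  need <- c("mirna_id", "target_gene", "report_count")
  if (!all(need %in% names(mirna_map)))
    stopf("mirna_map needs columns: %s", paste(need, collapse = ", "))
  if (nrow(mirna_map) == 0) return(setNames(character(0), character(0)))
  keep <- !is.na(mirna_map$target_gene) & nzchar(trimws(mirna_map$target_gene))
  if (any(!keep)) message(sprintf("dropping %d miRNA rows with empty targets", sum(!keep)))
  tab <- mirna_map[keep, , drop = FALSE]
  if (nrow(tab) == 0) return(setNames(character(0), character(0)))
  mid <- normalize_mirna_ids(tab$mirna_id)
  gene <- toupper(trimws(tab$target_gene))
  agg <- stats::aggregate(list(count = tab$report_count),
                          by = list(mirna = mid, gene = gene), FUN = sum)
  out <- vapply(split(agg, agg$mirna), function(d) {
    best <- d$gene[d$count == max(d$count)]
    sort(best)[1]
  }, character(1))
  out
}

#' Resolve each CpG probe to its deduplicated gene set
#'
#' Splits the semicolon-joined gene list, trims, uppercases, and
#' deduplicates preserving first-seen order. Probes with an empty gene
#' list are excluded with a message.
#'
#' @param cpg_map data.frame with columns `probe_id`, `gene_list`.
#' @return named list: probe id -> character vector of gene symbols.
#' @export
resolve_cpg_genes <- function(cpg_map) {
  need <- c("probe_id", "gene_list")
  if (!all(need %in% names(cpg_map)))
    stopf("cpg_map needs columns: %s", paste(need, collapse = ", "))
  if (nrow(cpg_map) == 0) return(setNames(list(), character(0)))
  sets <- lapply(cpg_map$gene_list, function(gl) {
    if (is.na(gl)) return(character(0))
    g <- toupper(trimws(strsplit(gl, ";", fixed = TRUE)[[1]]))
    unique(g[nzchar(g)])
  })
  names(sets) <- cpg_map$probe_id
  empty <- lengths(sets) == 0
  if (any(empty))
    message(sprintf("dropping %d CpG probes with empty gene lists", sum(empty)))
  sets[!empty]
}

#' Build the gene-centric three-channel table
#'
#' For every gene in the union of annotated symbols, each sample gets a
#' (mRNA, methylation, miRNA) channel triple: the gene's own expression,
#' the mean over CpG probes whose gene set contains it, and the mean over
#' miRNAs resolved to it. Channels a gene does not carry are zero-filled.
#' No scaling happens here; standardization is fold-confined and applied
#' by the cross-validation driver.
#'
#' @param mrna,mirna,meth [omics_matrix()] objects on the same sample set
#'   (`mirna`/`meth` may have zero features).
#' @param mirna_targets resolved map from [resolve_mirna_targets()].
#' @param cpg_genes resolved map from [resolve_cpg_genes()].
#' @param genes optional gene universe; default is the union of mRNA
#'   features, CpG set members and resolved miRNA targets.
#' @return a `gene_table`: list with `sample_ids`, `genes` and `channels`
#'   (list of three samples-by-genes matrices).
#' @export
build_gene_table <- function(mrna, mirna, meth, mirna_targets, cpg_genes,
                             genes = NULL) {
  stopifnot(inherits(mrna, "omics_matrix"))
  sample_ids <- mrna$sample_ids
  for (om in list(mirna, meth)) {
    if (is.null(om)) next
    if (!setequal(om$sample_ids, sample_ids)) {
      bad <- c(setdiff(om$sample_ids, sample_ids), setdiff(sample_ids, om$sample_ids))
      stopf("sample-id mismatch across omics layers: %s", paste(bad, collapse = ", "))
    }
  }
  mrna_genes <- toupper(mrna$feature_ids)
  if (is.null(genes)) {
    genes <- sort(unique(c(mrna_genes,
                           unlist(cpg_genes, use.names = FALSE),
                           unname(mirna_targets))))
  }
  n <- length(sample_ids); G <- length(genes)
  empty <- function() matrix(0, n, G, dimnames = list(sample_ids, genes))
  ch_mrna <- empty(); ch_meth <- empty(); ch_mirna <- empty()

  hit <- match(genes, mrna_genes)
  has <- !is.na(hit)
  if (any(has)) ch_mrna[, has] <- mrna$values[sample_ids, hit[has], drop = FALSE]

  if (!is.null(meth) && length(cpg_genes) > 0 && length(meth$feature_ids) > 0) {
    probe_of <- names(cpg_genes)
    gene_probe <- data.frame(
      gene = unlist(cpg_genes, use.names = FALSE),
      probe = rep(probe_of, lengths(cpg_genes)), stringsAsFactors = FALSE)
    gene_probe <- gene_probe[gene_probe$probe %in% meth$feature_ids, , drop = FALSE]
    mv <- meth$values[sample_ids, , drop = FALSE]
    for (g in intersect(genes, unique(gene_probe$gene))) {
      pr <- gene_probe$probe[gene_probe$gene == g]
      ch_meth[, g] <- rowMeans(mv[, pr, drop = FALSE])
    }
  }

  if (!is.null(mirna) && length(mirna_targets) > 0 && length(mirna$feature_ids) > 0) {
    norm_ids <- normalize_mirna_ids(mirna$feature_ids)
    tgt <- mirna_targets[norm_ids]
    mvals <- mirna$values[sample_ids, , drop = FALSE]
    for (g in intersect(genes, unique(stats::na.omit(tgt)))) {
      cols <- which(!is.na(tgt) & tgt == g)
      ch_mirna[, g] <- rowMeans(mvals[, cols, drop = FALSE])
    }
  }

  structure(list(sample_ids = sample_ids, genes = genes,
                 channels = list(mrna = ch_mrna, meth = ch_meth, mirna = ch_mirna)),
            class = "gene_table")
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("<gene_table> %d samples x %d genes x 3 channels\n",
              length(x$sample_ids), length(x$genes)))
  invisible(x)
}

#' Write a gene table as long or wide TSV
#'
#' Long form: one row per (sample, gene) with the three channel values.
#' Wide form: one TSV per channel, samples by genes.
#'
#' @param gt a [build_gene_table()] result.
#' @param path output file (long) or directory (wide).
#' @return written path(s), invisibly.
#' @export
write_gene_table_long <- function(gt, path) {
  stopifnot(inherits(gt, "gene_table"))
  df <- data.frame(
    sample_id = rep(gt$sample_ids, times = length(gt$genes)),
    gene = rep(gt$genes, each = length(gt$sample_ids)),
    mrna = as.vector(gt$channels$mrna),
    meth = as.vector(gt$channels$meth),
    mirna = as.vector(gt$channels$mirna), stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_gene_table_long
#' @export
write_gene_table_wide <- function(gt, path) {
  stopifnot(inherits(gt, "gene_table"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (ch in names(gt$channels)) {
    p <- file.path(path, sprintf("gene_table_%s.tsv", ch))
    df <- data.frame(sample_id = gt$sample_ids, gt$channels[[ch]],
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, p)
    out <- c(out, p)
  }
  invisible(out)
}

# Flatten the three channels into one samples x (genes*3) matrix with
# columns named "<gene>|<channel>". `combination` zeroes excluded layers
# (RNA = mrna, METH = meth, MIR = mirna).
flatten_gene_table <- function(gt, combination = c("RNA", "METH", "MIR")) {
  stopifnot(inherits(gt, "gene_table"))
  map <- c(RNA = "mrna", METH = "meth", MIR = "mirna")
  bad <- setdiff(combination, names(map))
  if (length(bad)) stopf("unknown omics combination element: %s", paste(bad, collapse = ", "))
  if (length(combination) == 0) stopf("omics combination must be non-empty")
  keep <- unname(map[combination])
  chans <- lapply(names(gt$channels), function(ch) {
    m <- gt$channels[[ch]]
    if (!(ch %in% keep)) m[] <- 0
    colnames(m) <- paste(gt$genes, ch, sep = "|")
    m
  })
  do.call(cbind, chans)
}

# Inverse of flatten: samples x (3G) matrix -> cube n_nodes x 3 x n_samples
# restricted and ordered to the network's node list. Genes absent from the
# table get zero rows.
flat_to_graph_features <- function(X, nodes) {
  chans <- c("mrna", "meth", "mirna")
  n <- nrow(X)
  arr <- array(0, dim = c(length(nodes), 3L, n),
               dimnames = list(nodes, chans, rownames(X)))
  for (ci in seq_along(chans)) {
    cols <- paste(nodes, chans[ci], sep = "|")
    hit <- match(cols, colnames(X))
    has <- !is.na(hit)
    if (any(has)) arr[has, ci, ] <- t(X[, hit[has], drop = FALSE])
  }
  arr
}
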