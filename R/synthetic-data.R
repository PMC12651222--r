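# Synthetic multi-omics cohort generator.
#
# Emulates a post-differential-analysis lower-grade-glioma style cohort:
# three omics layers on a shared sample set, a scored protein-protein
# interaction edge list, miRNA-target and CpG-gene annotation tables, an
# imbalanced three-class label vector, and a known set of planted
# subtype-discriminative genes so recovery can be measured exactly.

LGG_SUBTYPES <- c("IDHmut-codel", "IDHmut-non-codel", "IDHwt")

#' Simulation configuration
#'
#' Defaults describe the benchmark cohort used throughout the package: 140
#' patients split 60/60/20 across the three glioma subtypes (the third class
#' mimics the underrepresented IDH-wildtype group), 200 genes of which 20
#' carry planted class signal with a mean shift of 2 within-class standard
#' deviations, and a negative mRNA/methylation coupling that mimics
#' epigenetic silencing.
#'
#' @param n_per_class integer vector of length 3, samples per subtype.
#' @param n_genes number of genes (mRNA features).
#' @param n_mirnas number of miRNAs.
#' @param n_cpgs number of CpG probes.
#' @param n_informative_genes number of genes with planted class signal.
#' @param effect_size class-mean separation in units of within-class SD.
#' @param cross_layer_rho target correlation between a gene's mRNA value and
#'   its mapped methylation latent value, in `[-1, 1]`. Negative by default
#'   (hypermethylation goes with low expression).
#' @param ppi_attach_edges preferential-attachment edges per new node.
#' @param hub_informative if `TRUE`, informative genes are inserted first
#'   into the preferential-attachment graph and therefore become its hubs.
#' @param seed integer RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_per_class = c(60L, 60L, 20L),
                              n_genes = 200L,
                              n_mirnas = 30L,
                              n_cpgs = 300L,
                              n_informative_genes = 20L,
                              effect_size = 2,
                              cross_layer_rho = -0.6,
                              ppi_attach_edges = 2L,
                              hub_informative = TRUE,
                              seed = 1L) {
  if (length(n_per_class) != 3L) stopf("n_per_class must have length 3")
  counts <- c(n_per_class, n_genes, n_mirnas, n_cpgs, n_informative_genes)
  if (any(counts < 0)) stopf("all counts must be non-negative")
  if (n_informative_genes > n_genes)
    stopf("n_informative_genes (%d) exceeds n_genes (%d)", n_informative_genes, n_genes)
  if (abs(cross_layer_rho) > 1) stopf("cross_layer_rho must be in [-1, 1]")
  if (ppi_attach_edges < 1) stopf("ppi_attach_edges must be >= 1")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 n_cpgs = as.integer(n_cpgs),
                 n_informative_genes = as.integer(n_informative_genes),
                 effect_size = effect_size,
                 cross_layer_rho = cross_layer_rho,
                 ppi_attach_edges = as.integer(ppi_attach_edges),
                 hub_informative = isTRUE(hub_informative),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a scored protein-protein interaction edge list
#'
#' Barabasi-Albert style preferential attachment from a two-node seed
#' graph: node `t` attaches `min(attach_edges, t - 1)` distinct edges to
#' existing nodes with probability proportional to current degree. Early
#' nodes in `genes` therefore end up as hubs. Each edge carries an integer
#' confidence score drawn uniformly from 400..1000 (the medium-to-high
#' confidence range of STRING-style combined scores).
#'
#' @param genes character vector of gene symbols (insertion order).
#' @param attach_edges edges per new node, `>= 1`.
#' @param seed integer seed.
#' @return data.frame with columns `gene_a`, `gene_b`, `combined_score`;
#'   connected, no self-loops, no duplicate unordered pairs.
#' @export
generate_ppi <- function(genes, attach_edges = 2L, seed = 1L) {
  n <- length(genes)
  if (n < 2) stopf("need at least 2 genes to build a PPI graph, got %d", n)
  if (attach_edges < 1) stopf("attach_edges must be >= 1")
  with_seed(seed, {
    deg <- integer(n)
    from <- integer(0); to <- integer(0)
    from[1] <- 1L; to[1] <- 2L
    deg[1:2] <- 1L
    if (n > 2) {
      for (t in 3:n) {
        m <- min(attach_edges, t - 1L)
        tgt <- sample.int(t - 1L, m, prob = deg[seq_len(t - 1L)])
        from <- c(from, rep.int(t, m))
        to <- c(to, tgt)
        deg[t] <- deg[t] + m
        deg[tgt] <- deg[tgt] + 1L
      }
    }
    score <- sample(400:1000, length(from), replace = TRUE)
    data.frame(gene_a = genes[from], gene_b = genes[to],
               combined_score = as.integer(score), stringsAsFactors = FALSE)
  })
}

#' Generate miRNA-target and CpG-gene annotation tables
#'
#' Produces a miRTarBase-style table (`mirna_id`, `target_gene`,
#' `report_count`) and an Illumina-450k-style table (`probe_id`,
#' `gene_list` with semicolon-joined symbols). Some miRNAs deliberately
#' carry several candidate targets (including tied report counts) and some
#' CpGs deliberately name several genes (including duplicates) so the
#' downstream resolution rules are exercised.
#'
#' @param genes gene symbols to draw targets from.
#' @param mirna_ids miRNA identifiers (raw, possibly suffixed).
#' @param n_cpgs number of CpG probes.
#' @param seed integer seed.
#' @param primary_genes optional gene symbols guaranteed to receive a CpG
#'   (recycled over the first probes); used to tie planted signal genes to
#'   the methylation layer.
#' @return list with `mirna_map`, `cpg_map` (data.frames) and
#'   `cpg_primary` (the generating gene of each probe).
#' @export
generate_mappings <- function(genes, mirna_ids, n_cpgs, seed = 1L,
                              primary_genes = character(0)) {
  with_seed(seed, {
    n_mirnas <- length(mirna_ids)
    if (n_mirnas > 0) {
      rows <- lapply(seq_len(n_mirnas), function(i) {
        n_tgt <- if (i == 1L && length(genes) >= 2) 2L else sample(1:min(3L, length(genes)), 1L)
        tgt <- sample(genes, n_tgt)
        cnt <- sample(1:10, n_tgt, replace = TRUE)
        if (i == 2L && n_tgt >= 2) cnt[1:2] <- max(cnt)  # deliberate tie
        data.frame(mirna_id = mirna_ids[i], target_gene = tgt,
                   report_count = as.integer(cnt), stringsAsFactors = FALSE)
      })
      mirna_map <- do.call(rbind, rows)
    } else {
      mirna_map <- data.frame(mirna_id = character(0), target_gene = character(0),
                              report_count = integer(0), stringsAsFactors = FALSE)
    }

    if (n_cpgs > 0) {
      probes <- sprintf("cg%08d", seq_len(n_cpgs))
      primary <- character(n_cpgs)
      np <- length(primary_genes)
      if (np > 0) primary[seq_len(min(np, n_cpgs))] <- primary_genes[seq_len(min(np, n_cpgs))]
      rest <- which(primary == "")
      if (length(rest) > 0) primary[rest] <- sample(genes, length(rest), replace = TRUE)
      gene_list <- vapply(seq_len(n_cpgs), function(i) {
        gl <- primary[i]
        if (i == 1L && length(genes) >= 2) {
          # force one multi-gene probe with a duplicate entry
          extra <- sample(setdiff(genes, gl), 1L)
          gl <- c(gl, gl, extra)
        } else if (runif(1) < 0.25 && length(genes) >= 2) {
          gl <- c(gl, sample(setdiff(genes, gl), sample(1:2, 1L)))
        }
        paste(gl, collapse = ";")
      }, character(1))
      cpg_map <- data.frame(probe_id = probes, gene_list = gene_list,
                            stringsAsFactors = FALSE)
    } else {
      cpg_map <- data.frame(probe_id = character(0), gene_list = character(0),
                            stringsAsFactors = FALSE)
      primary <- character(0)
    }
    list(mirna_map = mirna_map, cpg_map = cpg_map, cpg_primary = primary)
  })
}

#' Generate a synthetic multi-omics cohort
#'
#' Within-class values are Gaussian with unit SD. Each planted informative
#' gene receives a random permutation of class means
#' `effect_size * (-1, 0, 1)` in its signal channel, which cycles over
#' mRNA-only, methylation-only and both. Methylation beta values arise by a
#' logistic squash of a latent Gaussian coupled to the primary gene's mRNA
#' value at correlation `cross_layer_rho`; miRNAs whose resolved target is
#' an informative gene inherit half the class shift.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_cohort` list: `mrna`, `mirna`, `meth`
#'   ([omics_matrix()] each), `labels` (named factor), `truth_genes`,
#'   `signal_channel`, `ppi_edges`, `mirna_map`, `cpg_map`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- sum(cfg$n_per_class)
    sample_ids <- sprintf("S%04d", seq_len(n))
    labels <- factor(rep(LGG_SUBTYPES, cfg$n_per_class), levels = LGG_SUBTYPES)
    names(labels) <- sample_ids

    genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    truth <- if (cfg$n_informative_genes > 0) sort(sample(genes, cfg$n_informative_genes)) else character(0)
    channel_cycle <- c("mrna", "meth", "both")
    signal_channel <- setNames(rep_len(channel_cycle, length(truth)), truth)

    # class-mean patterns per informative gene (rows = classes)
    mu <- matrix(0, nrow = 3, ncol = length(truth), dimnames = list(LGG_SUBTYPES, truth))
    for (g in truth) mu[, g] <- cfg$effect_size * sample(c(-1, 0, 1))

    cls_idx <- as.integer(labels)

    # mRNA layer
    mrna_vals <- matrix(rnorm(n * cfg$n_genes), n, cfg$n_genes,
                        dimnames = list(sample_ids, genes))
    for (g in truth) {
      if (signal_channel[g] %in% c("mrna", "both"))
        mrna_vals[, g] <- mrna_vals[, g] + mu[cls_idx, g]
    }

    # raw miRNA identifiers: decorate a subset with arm suffixes / case
    # variants so identifier normalization is exercised end to end
    mirna_base <- if (cfg$n_mirnas > 0) sprintf("hsa-mir-%d", 100L + seq_len(cfg$n_mirnas)) else character(0)
    mirna_ids <- mirna_base
    if (cfg$n_mirnas > 0) {
      style <- rep_len(c("plain", "5p", "3p", "dot"), cfg$n_mirnas)
      mirna_ids <- mapply(function(id, st) {
        switch(st,
               plain = id,
               `5p` = paste0(sub("mir", "miR", id), "-5p"),
               `3p` = paste0(id, "-3p"),
               dot = paste0(toupper(id), ".1"))
      }, mirna_base, style, USE.NAMES = FALSE)
    }

    maps <- generate_mappings(genes, mirna_ids, cfg$n_cpgs,
                              seed = cfg$seed + 101L, primary_genes = truth)

    # methylation layer: latent Gaussian tied to the primary gene's mRNA
    rho <- cfg$cross_layer_rho
    meth_vals <- matrix(0, n, cfg$n_cpgs,
                        dimnames = list(sample_ids, maps$cpg_map$probe_id))
    if (cfg$n_cpgs > 0) {
      for (p in seq_len(cfg$n_cpgs)) {
        g <- maps$cpg_primary[p]
        x <- mrna_vals[, g]
        xs <- (x - mean(x)) / max(sd(x), 1e-12)
        latent <- rho * xs + sqrt(max(0, 1 - rho^2)) * rnorm(n)
        if (g %in% truth && signal_channel[g] == "meth")
          latent <- latent + mu[cls_idx, g]
        meth_vals[, p] <- plogis(latent)
      }
    }

    # miRNA layer: noise plus an inherited half-shift when the resolved
    # target (max total report count, lexicographic tie-break) is planted
    mirna_vals <- matrix(rnorm(n * cfg$n_mirnas), n, cfg$n_mirnas,
                         dimnames = list(sample_ids, mirna_ids))
    if (cfg$n_mirnas > 0 && nrow(maps$mirna_map) > 0) {
      resolved <- resolve_mirna_targets(maps$mirna_map)
      norm_ids <- normalize_mirna_ids(mirna_ids)
      for (j in seq_len(cfg$n_mirnas)) {
        tg <- resolved[norm_ids[j]]
        if (!is.na(tg) && tg %in% truth)
          mirna_vals[, j] <- mirna_vals[, j] + 0.5 * mu[cls_idx, match(tg, truth)]
      }
    }

    gene_order <- if (cfg$hub_informative) c(truth, setdiff(genes, truth)) else genes
    ppi_edges <- generate_ppi(gene_order, cfg$ppi_attach_edges, seed = cfg$seed + 202L)

    structure(list(
      mrna = omics_matrix(mrna_vals, "mrna"),
      mirna = omics_matrix(mirna_vals, "mirna"),
      meth = omics_matrix(meth_vals, "meth"),
      labels = labels,
      truth_genes = truth,
      signal_channel = signal_channel,
      class_means = mu,
      ppi_edges = ppi_edges,
      mirna_map = maps$mirna_map,
      cpg_map = maps$cpg_map,
      config = cfg), class = "synthetic_cohort")
  })
}

#' Export a cohort to the delimited-text formats the pipeline consumes
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mrna = file.path(dir, "mrna.tsv"),
             mirna = file.path(dir, "mirna.tsv"),
             meth = file.path(dir, "meth.tsv"),
             labels = file.path(dir, "labels.tsv"),
             ppi = file.path(dir, "ppi_edges.tsv"),
             mirna_map = file.path(dir, "mirna_targets.tsv"),
             cpg_map = file.path(dir, "cpg_genes.tsv"))
  write_omics_matrix(cohort$mrna, paths["mrna"])
  write_omics_matrix(cohort$mirna, paths["mirna"])
  write_omics_matrix(cohort$meth, paths["meth"])
  write_tsv(data.frame(sample_id = names(cohort$labels),
                       subtype = as.character(cohort$labels)), paths["labels"])
  write_tsv(cohort$ppi_edges, paths["ppi"])
  write_tsv(cohort$mirna_map, paths["mirna_map"])
  write_tsv(cohort$cpg_map, paths["cpg_map"])
  invisible(paths)
}
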