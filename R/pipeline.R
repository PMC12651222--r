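# End-to-end pipeline: read the five delimited inputs, annotate, build
# the network, run repeated cross-validation, rank biomarkers, and write
# all artifacts plus a reproducibility manifest.

#' Parse a flat key=value run-configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys mirror the
#' arguments of [run_pipeline()]'s config list.
#'
#' @param path configuration file.
#' @param overrides named list applied on top of the file values.
#' @return a named list.
#' @export
parse_run_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- list()
  for (p in kv) {
    if (length(p) < 2) stopf("malformed config line: %s", paste(p, collapse = "="))
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

default_pipeline_config <- function() {
  list(combination = "RNA+METH+MIR", seed = 1, n_folds = 5, n_repeats = 3,
       min_score = 400, rf_trees = 500, smote_k = 5, ridge_strength = 1,
       biomarker_weight = 0.5, gat_preset = "paper", top_k = 20)
}

#' Run the full hybrid classification pipeline
#'
#' Reads the three omics matrices, label table, PPI edge list and the two
#' annotation tables; builds the gene-centric table and the shared PPI
#' topology; runs the repeated stratified cross-validation of the RF, GAT
#' and stacked models; ranks biomarkers; and writes fold results, summary
#' tables (performance, paired t-tests, per-gene ANOVA), the biomarker
#' report and a manifest naming the configuration hash. Re-running with
#' the same configuration reproduces all outputs byte-identically.
#'
#' @param config named list (or [parse_run_config()] result) with file
#'   paths `mrna_file`, `mirna_file`, `meth_file`, `labels_file`,
#'   `ppi_file`, `mirna_map_file`, `cpg_map_file`, an `out_dir`, and
#'   optional settings: `combination` (e.g. `"RNA+METH"`), `seed`,
#'   `n_folds`, `n_repeats`, `min_score`, `rf_trees`, `smote_k`,
#'   `ridge_strength`, `biomarker_weight`, `top_k`, `gat_preset`
#'   (`"paper"` or `"benchmark"`) plus `gat_*` overrides
#'   (`gat_heads`, `gat_hidden`, `gat_epochs`, `gat_dropout`,
#'   `gat_learning_rate`, `gat_patience`).
#' @return invisibly, a list with the artifact paths and the `cv_result`.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  for (key in c("mrna_file", "mirna_file", "meth_file", "labels_file",
                "ppi_file", "mirna_map_file", "cpg_map_file", "out_dir")) {
    if (is.null(cfg[[key]])) stopf("config is missing '%s'", key)
    if (key != "out_dir" && !file.exists(cfg[[key]]))
      stopf("input file not found: %s (%s)", cfg[[key]], key)
  }
  combination <- strsplit(toupper(cfg$combination), "\\+")[[1]]
  seed <- as.integer(cfg$seed)

  mrna <- read_omics_matrix(cfg$mrna_file, "mrna")
  mirna <- read_omics_matrix(cfg$mirna_file, "mirna")
  meth <- read_omics_matrix(cfg$meth_file, "meth")
  lab_df <- read_tsv(cfg$labels_file)
  labels <- factor(lab_df[[2]])
  names(labels) <- lab_df[[1]]

  mirna_targets <- resolve_mirna_targets(read_tsv(cfg$mirna_map_file))
  cpg_genes <- resolve_cpg_genes(read_tsv(cfg$cpg_map_file))
  gt <- build_gene_table(mrna, mirna, meth, mirna_targets, cpg_genes)

  raw_edges <- load_string_edges(cfg$ppi_file, min_score = cfg$min_score)
  network <- dedupe_and_restrict(raw_edges, gt$genes)

  gat_cfg <- if (identical(cfg$gat_preset, "benchmark")) gat_benchmark_config(seed)
             else gat_config(seed = seed)
  for (fld in c("heads", "hidden", "epochs", "patience")) {
    key <- paste0("gat_", fld)
    if (!is.null(cfg[[key]])) gat_cfg[[fld]] <- as.integer(cfg[[key]])
  }
  for (fld in c("dropout", "learning_rate")) {
    key <- paste0("gat_", fld)
    if (!is.null(cfg[[key]])) gat_cfg[[fld]] <- as.numeric(cfg[[key]])
  }
  hcfg <- hybrid_config(gat = gat_cfg, rf_trees = as.integer(cfg$rf_trees),
                        smote_k = as.integer(cfg$smote_k),
                        ridge_strength = cfg$ridge_strength)
  plan <- cv_plan(labels[gt$sample_ids], n_folds = as.integer(cfg$n_folds),
                  n_repeats = as.integer(cfg$n_repeats), seed = seed)

  cv <- run_cv(gt, labels, network, config = hcfg, plan = plan,
               combination = combination, seed = seed)

  agg <- aggregate_importances(cv$rf_gene_importance, cv$attention)
  ranking <- combine_and_rank(agg$rf, agg$attention, w = cfg$biomarker_weight)
  top_genes <- head(ranking$gene, as.integer(cfg$top_k))
  anova_tab <- anova_best_omic(gt, labels, genes = top_genes)
  ranking_top <- annotate_best_omic(head(ranking, as.integer(cfg$top_k)), anova_tab)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash_keys <- setdiff(sort(names(cfg)), "out_dir")  # content, not destination
  cfg_hash <- object_hash(cfg[hash_keys])
  paths <- c(fold_results = file.path(cfg$out_dir, "fold_results.tsv"),
             summary = file.path(cfg$out_dir, "summary_by_model.tsv"),
             ttests = file.path(cfg$out_dir, "ttest_table.tsv"),
             anova = file.path(cfg$out_dir, "anova_best_omic.tsv"),
             biomarkers = file.path(cfg$out_dir, "biomarkers.tsv"),
             selected = file.path(cfg$out_dir, "selected_features.tsv"),
             manifest = file.path(cfg$out_dir, "manifest.txt"))
  write_tsv(cv$fold_results, paths["fold_results"])
  write_tsv(cbind(config_hash = cfg_hash, summarize_cv(cv$fold_results)), paths["summary"])
  write_tsv(ttest_table(cv$fold_results), paths["ttests"])
  write_tsv(anova_tab, paths["anova"])
  write_tsv(cbind(ranking_top, config_hash = cfg_hash), paths["biomarkers"])
  write_selected_features(cv$selections, paths["selected"])
  writeLines(c(sprintf("config_hash\t%s", cfg_hash),
               sprintf("seed\t%d", seed),
               sprintf("package_version\t%s", as.character(utils::packageVersion("gatstack"))),
               sprintf("combination\t%s", paste(combination, collapse = "+")),
               sprintf("n_folds\t%d", plan$n_folds),
               sprintf("n_repeats\t%d", plan$n_repeats),
               vapply(hash_keys, function(k)
                 sprintf("cfg.%s\t%s", k, paste(cfg[[k]], collapse = ",")),
                 character(1))),
             paths["manifest"])
  invisible(list(paths = paths, cv = cv, ranking = ranking,
                 network = network, gene_table = gt, config_hash = cfg_hash))
}
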