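# Shared fixtures: tiny cohorts, networks and configs sized for fast tests.

tiny_cohort <- function(seed = 7, effect = 2, npc = c(16L, 16L, 8L),
                        n_genes = 40L, n_mirnas = 8L, n_cpgs = 50L,
                        n_informative = 8L) {
  generate_cohort(simulation_config(
    n_per_class = npc, n_genes = n_genes, n_mirnas = n_mirnas, n_cpgs = n_cpgs,
    n_informative_genes = n_informative, effect_size = effect, seed = seed))
}

cohort_gene_table <- function(cohort) {
  build_gene_table(cohort$mrna, cohort$mirna, cohort$meth,
                   resolve_mirna_targets(cohort$mirna_map),
                   resolve_cpg_genes(cohort$cpg_map))
}

cohort_network <- function(cohort, gene_table = cohort_gene_table(cohort)) {
  dedupe_and_restrict(cohort$ppi_edges, gene_table$genes)
}

tiny_gat_config <- function(seed = 1, epochs = 15L) {
  gat_config(heads = 2L, hidden = 6L, dropout = 0.1, learning_rate = 0.02,
             epochs = epochs, patience = 0L, val_fraction = 0, seed = seed)
}

tiny_hybrid_config <- function(seed = 1) {
  hybrid_config(gat = tiny_gat_config(seed), rf_trees = 100L)
}

# small hand-made network from an explicit undirected edge list
make_network <- function(edges_mat, n_nodes = max(edges_mat)) {
  nodes <- sprintf("G%02d", seq_len(n_nodes))
  structure(list(nodes = nodes,
                 edges = data.frame(gene_a = nodes[edges_mat[, 1]],
                                    gene_b = nodes[edges_mat[, 2]],
                                    combined_score = 500,
                                    stringsAsFactors = FALSE)),
            class = "ppi_network")
}

pipeline_fixture <- function(dir, seed = 1) {
  co <- generate_cohort(simulation_config(
    n_per_class = c(12L, 12L, 6L), n_genes = 20L, n_mirnas = 4L, n_cpgs = 25L,
    n_informative_genes = 5L, effect_size = 2, seed = 3))
  write_cohort(co, dir)
  cfg_file <- file.path(dir, "run.cfg")
  writeLines(c(
    sprintf("mrna_file = %s", file.path(dir, "mrna.tsv")),
    sprintf("mirna_file = %s", file.path(dir, "mirna.tsv")),
    sprintf("meth_file = %s", file.path(dir, "meth.tsv")),
    sprintf("labels_file = %s", file.path(dir, "labels.tsv")),
    sprintf("ppi_file = %s", file.path(dir, "ppi_edges.tsv")),
    sprintf("mirna_map_file = %s", file.path(dir, "mirna_targets.tsv")),
    sprintf("cpg_map_file = %s", file.path(dir, "cpg_genes.tsv")),
    "gat_preset = benchmark", "gat_epochs = 10", "rf_trees = 100",
    "n_folds = 3", "n_repeats = 1", sprintf("seed = %d", seed),
    "# comment line", "top_k = 10"), cfg_file)
  cfg_file
}
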