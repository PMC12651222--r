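test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_per_class = c(10, 10)), "length 3")
  expect_error(simulation_config(n_genes = -1), "non-negative")
  expect_error(simulation_config(n_genes = 10, n_informative_genes = 11), "exceeds")
  expect_error(simulation_config(cross_layer_rho = 1.2), "\\[-1, 1\\]")
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  a <- tiny_cohort(seed = 7)
  b <- tiny_cohort(seed = 7)
  c <- tiny_cohort(seed = 8)
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$meth$values, b$meth$values)
  expect_identical(a$ppi_edges, b$ppi_edges)
  expect_false(identical(a$mrna$values, c$mrna$values))
})

test_that("planted genes separate classes and noise genes do not", {
  co <- generate_cohort(simulation_config(
    n_per_class = c(60, 60, 20), n_genes = 200, n_informative_genes = 20,
    effect_size = 2, seed = 7))
  # signal lives in the mRNA or methylation channel depending on the gene;
  # test each truth gene in its assigned channel
  gt <- cohort_gene_table(co)
  p_truth <- vapply(co$truth_genes, function(g) {
    ch <- if (co$signal_channel[g] == "meth") "meth" else "mrna"
    anova(lm(gt$channels[[ch]][, g] ~ co$labels))$`Pr(>F)`[1]
  }, numeric(1))
  expect_gte(sum(p_truth < 1e-4), 18)

  null_co <- generate_cohort(simulation_config(
    n_per_class = c(30, 30, 15), n_genes = 100, n_informative_genes = 10,
    effect_size = 0, seed = 3))
  p_null <- anova_pvals(null_co$mrna$values, null_co$labels)
  expect_gte(mean(p_null > 0.01), 0.95)
})

test_that("cohort invariants hold: shared samples, truth genes, edge endpoints", {
  co <- tiny_cohort()
  expect_identical(co$mrna$sample_ids, co$meth$sample_ids)
  expect_identical(co$mrna$sample_ids, co$mirna$sample_ids)
  expect_true(all(co$truth_genes %in% co$mrna$feature_ids))
  expect_true(all(c(co$ppi_edges$gene_a, co$ppi_edges$gene_b) %in% co$mrna$feature_ids))
})

test_that("mRNA/methylation coupling approximates the target correlation", {
  co <- generate_cohort(simulation_config(
    n_per_class = c(50, 50, 40), n_genes = 80, n_cpgs = 120,
    n_informative_genes = 10, effect_size = 1, cross_layer_rho = -0.6, seed = 5))
  primary <- sub(";.*", "", co$cpg_map$gene_list)
  idx <- which(!(primary %in% co$truth_genes))[1:20]
  rhos <- vapply(idx, function(p)
    cor(co$mrna$values[, primary[p]], co$meth$values[, p]), numeric(1))
  expect_true(all(abs(rhos - (-0.6)) < 0.15))
})

test_that("preferential attachment gives the exact edge count and clean pairs", {
  genes2 <- c("A", "B")
  e2 <- generate_ppi(genes2, attach_edges = 1, seed = 1)
  expect_equal(nrow(e2), 1)
  expect_error(generate_ppi("A"), "at least 2")

  g100 <- sprintf("g%03d", 1:100)
  e <- generate_ppi(g100, attach_edges = 2, seed = 1)
  expect_equal(nrow(e), 2 * 98 + 1)
  expect_true(all(e$gene_a != e$gene_b))
  key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(e$combined_score >= 400 & e$combined_score <= 1000))
  expect_true(is_connected_graph(e, g100))
})

test_that("hub bias makes informative genes high-degree nodes", {
  co <- tiny_cohort(seed = 2)
  deg <- table(c(co$ppi_edges$gene_a, co$ppi_edges$gene_b))
  truth_deg <- as.numeric(deg[co$truth_genes])
  other_deg <- as.numeric(deg[setdiff(names(deg), co$truth_genes)])
  expect_gt(mean(truth_deg), 2 * mean(other_deg))
})

test_that("mapping tables are deterministic and exercise multi-target rules", {
  m0 <- generate_mappings(letters, character(0), 0, seed = 1)
  expect_equal(nrow(m0$mirna_map), 0)
  expect_equal(nrow(m0$cpg_map), 0)

  ids <- sprintf("hsa-mir-%d", 1:6)
  m1 <- generate_mappings(LETTERS, ids, 50, seed = 4)
  m2 <- generate_mappings(LETTERS, ids, 50, seed = 4)
  expect_identical(m1, m2)
  n_genes_per_probe <- lengths(resolve_cpg_genes(m1$cpg_map))
  expect_gte(sum(n_genes_per_probe >= 2), 1)
  per_mirna <- table(m1$mirna_map$mirna_id)
  expect_gte(sum(per_mirna >= 2), 1)
})

test_that("an empty miRNA layer flows through the pipeline", {
  co <- generate_cohort(simulation_config(
    n_per_class = c(8, 8, 4), n_genes = 20, n_mirnas = 0, n_cpgs = 25,
    n_informative_genes = 4, seed = 1))
  gt <- cohort_gene_table(co)
  expect_true(all(gt$channels$mirna == 0))
})

test_that("exported cohort files are byte-identical across runs", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(tiny_cohort(seed = 3), d1)
  write_cohort(tiny_cohort(seed = 3), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
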