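test_that("miRNA identifier normalization strips suffixes and is idempotent", {
  expect_equal(normalize_mirna_ids("hsa-miR-21-5p"), "hsa-mir-21")
  expect_equal(normalize_mirna_ids("hsa-mir-21"), "hsa-mir-21")
  expect_equal(normalize_mirna_ids("HSA-MIR-155.1"), "hsa-mir-155")
  expect_equal(normalize_mirna_ids("hsa-miR-9-3p.2"), "hsa-mir-9")
  once <- normalize_mirna_ids(c("hsa-miR-21-5p", "HSA-MIR-155.1"))
  expect_identical(normalize_mirna_ids(once), once)
  expect_error(normalize_mirna_ids(""), "non-empty")
})

test_that("miRNA targets resolve to the most frequently reported gene", {
  tab <- data.frame(mirna_id = c("m1", "m1"), target_gene = c("G1", "G2"),
                    report_count = c(5, 3))
  expect_equal(unname(resolve_mirna_targets(tab)["m1"]), "G1")
  tie <- data.frame(mirna_id = c("m1", "m1"), target_gene = c("G2", "G1"),
                    report_count = c(4, 4))
  expect_equal(unname(resolve_mirna_targets(tie)["m1"]), "G1")
  empty <- data.frame(mirna_id = character(0), target_gene = character(0),
                      report_count = integer(0))
  expect_length(resolve_mirna_targets(empty), 0)
  # counts aggregate over duplicate rows and suffixed identifier variants
  dup <- data.frame(mirna_id = c("hsa-miR-7-5p", "hsa-mir-7", "hsa-mir-7"),
                    target_gene = c("G2", "G2", "G1"),
                    report_count = c(3, 3, 5))
  expect_equal(unname(resolve_mirna_targets(dup)["hsa-mir-7"]), "G2")
})

test_that("CpG gene sets merge duplicates and drop empty probes", {
  tab <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                    gene_list = c("GENE1;GENE1;GENE2", "gene1", ""))
  expect_message(res <- resolve_cpg_genes(tab), "1 CpG probes")
  expect_equal(res[["cg1"]], c("GENE1", "GENE2"))
  expect_equal(res[["cg2"]], "GENE1")
  expect_false("cg3" %in% names(res))
})

test_that("gene table aggregates channels by the arithmetic mean with zero fill", {
  samples <- c("s1", "s2")
  mrna <- omics_matrix(matrix(c(1, 2, 3, 4), 2, 2,
                              dimnames = list(samples, c("GA", "GB"))), "mrna")
  meth <- omics_matrix(matrix(c(0.2, 0.2, 0.6, 0.6), 2, 2,
                              dimnames = list(samples, c("cg1", "cg2"))), "meth")
  mirna <- omics_matrix(matrix(c(5, 7), 2, 1,
                               dimnames = list(samples, "hsa-mir-1")), "mirna")
  cpg <- resolve_cpg_genes(data.frame(probe_id = c("cg1", "cg2"),
                                      gene_list = c("GA", "GA")))
  mir <- resolve_mirna_targets(data.frame(mirna_id = "hsa-mir-1",
                                          target_gene = "GB", report_count = 1))
  gt <- build_gene_table(mrna, mirna, meth, mir, cpg)
  expect_setequal(gt$genes, c("GA", "GB"))
  expect_equal(unname(gt$channels$meth[, "GA"]), c(0.4, 0.4))  # mean of 2 CpGs
  expect_equal(unname(gt$channels$meth[, "GB"]), c(0, 0))      # no probe
  expect_equal(unname(gt$channels$mirna[, "GB"]), c(5, 7))
  expect_equal(unname(gt$channels$mirna[, "GA"]), c(0, 0))
  expect_equal(unname(gt$channels$mrna[, "GA"]), c(1, 2))
})

test_that("gene table is invariant to input feature order", {
  co <- tiny_cohort(seed = 9)
  gt1 <- cohort_gene_table(co)
  perm <- sample(ncol(co$mrna$values))
  mrna_p <- omics_matrix(co$mrna$values[, perm], "mrna")
  permc <- sample(ncol(co$meth$values))
  meth_p <- omics_matrix(co$meth$values[, permc], "meth")
  gt2 <- build_gene_table(mrna_p, co$mirna, meth_p,
                          resolve_mirna_targets(co$mirna_map),
                          resolve_cpg_genes(co$cpg_map))
  expect_identical(gt1$genes, gt2$genes)
  expect_equal(gt1$channels, gt2$channels)
})

test_that("non-zero methylation channels match the genes with mapped probes", {
  co <- tiny_cohort(seed = 4)
  gt <- cohort_gene_table(co)
  mapped <- unique(unlist(resolve_cpg_genes(co$cpg_map)))
  nz <- colSums(gt$channels$meth != 0) > 0
  expect_setequal(gt$genes[nz], intersect(gt$genes, mapped))
})

test_that("sample-id mismatches are rejected with the offending ids", {
  samples <- c("s1", "s2")
  mrna <- omics_matrix(matrix(0, 2, 1, dimnames = list(samples, "GA")), "mrna")
  meth <- omics_matrix(matrix(0, 2, 1, dimnames = list(c("s1", "sX"), "cg1")), "meth")
  expect_error(build_gene_table(mrna, NULL, meth, character(0),
                                list(cg1 = "GA")), "sX")
})

test_that("omics matrices round-trip through TSV", {
  co <- tiny_cohort(seed = 6)
  p <- tempfile(fileext = ".tsv")
  write_omics_matrix(co$mrna, p)
  back <- read_omics_matrix(p, "mrna")
  expect_equal(back$values, co$mrna$values, tolerance = 1e-12)
  unlink(p)
})
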