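test_that("the fold plan partitions every repeat with stratification", {
  y <- factor(rep(c("a", "b", "c"), c(60, 60, 20)))
  names(y) <- sprintf("s%03d", seq_along(y))
  plan <- cv_plan(y, n_folds = 5, n_repeats = 3, seed = 1)
  expect_equal(dim(plan$assignment), c(140L, 3L))
  for (r in 1:3) {
    expect_setequal(unique(plan$assignment[, r]), 1:5)
    tab <- table(y, plan$assignment[, r])
    expect_true(all(abs(tab - as.numeric(table(y)) / 5) <= 1))
  }
})

test_that("perfect probabilities score 1 on every metric", {
  y <- factor(rep(c("a", "b", "c"), each = 4))
  probs <- gatstack:::one_hot(y) * 0.94 + 0.02
  colnames(probs) <- levels(y)
  m <- compute_metrics(y, probs / rowSums(probs))
  expect_equal(unname(m), rep(1, 6))
})

test_that("a no-skill classifier sits at chance AUC", {
  y <- factor(rep(c("a", "b", "c"), each = 10))
  probs <- matrix(1 / 3, 30, 3, dimnames = list(NULL, levels(y)))
  m <- compute_metrics(y, probs)
  expect_equal(unname(m["roc_auc"]), 0.5)
  expect_equal(unname(m["accuracy"]), 1 / 3)
})

test_that("macro-F1 matches the hand-worked six-sample confusion matrix", {
  # y:    a a b b c c     predictions: a b b c c a
  # per class: P = R = F1 = 0.5, accuracy = 0.5
  y <- factor(c("a", "a", "b", "b", "c", "c"))
  probs <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.8, 0.1),
                 c(0.1, 0.1, 0.8), c(0.1, 0.1, 0.8), c(0.8, 0.1, 0.1))
  colnames(probs) <- c("a", "b", "c")
  m <- compute_metrics(y, probs)
  expect_equal(unname(m["accuracy"]), 0.5)
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["recall"]), 0.5)
  expect_equal(unname(m["f1"]), 0.5)
})

test_that("average precision matches a brute-force PR computation", {
  set.seed(1)
  pos <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  score <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.45, 0.4, 0.1)
  # walk thresholds by hand: AP = sum over positives of precision at each
  ap_brute <- {
    o <- order(score, decreasing = TRUE)
    p <- pos[o]
    sum(cumsum(p)[p] / which(p)) / sum(p)
  }
  expect_equal(gatstack:::average_precision(pos, score), ap_brute)
})

test_that("classes absent from the fold are excluded from AUC with a warning", {
  y <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "c"))
  probs <- matrix(c(0.7, 0.2, 0.1, 0.6, 0.3, 0.1, 0.2, 0.7, 0.1, 0.1, 0.8, 0.1),
                  4, 3, byrow = TRUE, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(m <- compute_metrics(y, probs), "excluded")
  expect_false(is.na(m["roc_auc"]))
})

test_that("the paired t-test matches its closed form and degenerate branches", {
  d <- c(0.01, -0.02, 0.03, 0.00, 0.02)
  b <- c(0.70, 0.60, 0.65, 0.75, 0.70)
  a <- b + d
  res <- paired_ttest(a, b)
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$df, 4)

  same <- paired_ttest(b, b)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const <- paired_ttest(c(0.9, 0.8, 0.85, 0.95, 0.9), c(0.7, 0.6, 0.65, 0.75, 0.7))
  expect_true(is.infinite(const$t) && const$t > 0)
  expect_equal(const$p, 0)
})

test_that("per-gene ANOVA finds strong separation and skips empty channels", {
  set.seed(2)
  g <- factor(rep(c("x", "y", "z"), each = 30))
  v_sig <- c(rnorm(30, 0), rnorm(30, 0), rnorm(30, 3))
  v_null <- rnorm(90)
  res <- anova_per_gene("G", list(RNASeq = v_sig, Methylation = v_null,
                                  miRNA = rep(0, 90)), g)
  expect_lt(res$p_RNASeq, 1e-10)
  expect_true(is.na(res$p_miRNA))
  expect_equal(res$best_omic, "RNASeq")
  # equal group means: F small, p large (seeded draw)
  res0 <- anova_per_gene("G0", list(RNASeq = rnorm(90)), g)
  expect_gt(res0$p_RNASeq, 0.01)
})

test_that("min-max normalization maps to [0,1] with the constant convention", {
  expect_equal(unname(minmax_normalize(c(2, 4, 6))), c(0, 0.5, 1))
  expect_equal(unname(minmax_normalize(c(5, 5, 5))), c(0.5, 0.5, 0.5))
  set.seed(3)
  v <- rnorm(50)
  out <- minmax_normalize(v)
  expect_equal(range(out), c(0, 1))
  expect_error(minmax_normalize(numeric(0)), "empty")
})

test_that("the cross-validation driver books 15 results per model and audits folds", {
  co <- tiny_cohort(seed = 6, npc = c(12L, 12L, 6L), n_genes = 20L,
                    n_mirnas = 4L, n_cpgs = 25L, n_informative = 5L)
  gt <- cohort_gene_table(co)
  net <- cohort_network(co, gt)
  plan <- cv_plan(co$labels, n_folds = 3, n_repeats = 2, seed = 1)
  cv <- suppressMessages(run_cv(gt, co$labels, net, config = tiny_hybrid_config(),
                                plan = plan, seed = 1))
  expect_equal(nrow(cv$fold_results), 3 * 2 * 3)  # folds x repeats x models
  expect_setequal(unique(cv$fold_results$model), c("RF", "GAT", "stacked"))
  expect_true(all(cv$fold_results$accuracy >= 0 & cv$fold_results$accuracy <= 1))
  summ <- summarize_cv(cv$fold_results)
  expect_equal(nrow(summ), 3)
  tt <- ttest_table(cv$fold_results)
  expect_equal(nrow(tt), 4)
})

test_that("whole-dataset standardization is caught by the leakage audit", {
  co <- tiny_cohort(seed = 6, npc = c(10L, 10L, 5L), n_genes = 15L,
                    n_mirnas = 3L, n_cpgs = 20L, n_informative = 4L)
  gt <- cohort_gene_table(co)
  net <- cohort_network(co, gt)
  plan <- cv_plan(co$labels, n_folds = 3, n_repeats = 1, seed = 1)
  expect_error(
    suppressMessages(run_cv(gt, co$labels, net, config = tiny_hybrid_config(),
                            plan = plan, seed = 1, inject_global_scaling = TRUE)),
    "leakage audit failed")
})
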