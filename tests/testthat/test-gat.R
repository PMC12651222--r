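test_that("attention over a single neighbour is exactly 1 and rows sum to 1", {
  set.seed(1)
  h <- matrix(rnorm(8), 4, 2)
  a <- rnorm(4)
  nb <- list(2L, c(1L, 3L, 2L), c(2L, 3L), c(4L, 1L))
  al <- attention_coefficients(h, a, nb)
  expect_equal(al[[1]], 1)
  for (i in seq_along(nb)) expect_equal(sum(al[[i]]), 1, tolerance = 1e-12)
  expect_true(all(unlist(al) >= 0))
  expect_error(attention_coefficients(h, a, list(integer(0), 1L, 1L, 1L)),
               "no neighbours")
})

test_that("a zero attention vector gives uniform attention", {
  h <- matrix(rnorm(6), 3, 2)
  al <- attention_coefficients(h, rep(0, 4), list(c(1L, 2L, 3L), c(1L, 2L), 3L))
  expect_equal(al[[1]], rep(1 / 3, 3))
  expect_equal(al[[2]], rep(1 / 2, 2))
})

test_that("compiled forward pass matches the dense loop implementation", {
  set.seed(42)
  for (trial in 1:8) {
    n <- sample(3:6, 1)
    all_pairs <- t(combn(n, 2))
    keep <- runif(nrow(all_pairs)) < 0.6 | seq_len(nrow(all_pairs)) <= n - 1
    net <- make_network(all_pairs[keep, , drop = FALSE], n)
    cfg <- gat_config(heads = sample(1:3, 1), hidden = sample(2:5, 1),
                      dropout = 0, seed = trial)
    params <- gatstack:::init_gat_params(3, cfg)
    X <- matrix(rnorm(n * 3), n, 3)
    ei <- gatstack:::graph_edge_index(net)
    out <- gatstack:::gat_forward_cpp(array(X, c(n, 3, 1)), ei$edge_i, ei$edge_j,
                                      ei$rowptr, params, 0.2, TRUE)
    ref <- dense_gat_forward(X, params, network_neighbors(net))
    expect_equal(as.numeric(out$probs[1, ]), ref$probs, tolerance = 1e-6)
    for (k in seq_len(cfg$heads)) {
      sums <- tapply(out$attention1[, k], ei$edge_i, sum)
      expect_true(all(abs(sums - 1) < 1e-6))
      sums2 <- tapply(out$attention2[, k], ei$edge_i, sum)
      expect_true(all(abs(sums2 - 1) < 1e-6))
    }
  }
})

test_that("with one head, concat and average layers coincide", {
  set.seed(2)
  h <- matrix(rnorm(12), 4, 3)
  W <- list(matrix(rnorm(6), 2, 3))
  a <- list(rnorm(4))
  nb <- list(c(1L, 2L), c(1L, 2L, 3L), c(2L, 3L, 4L), c(3L, 4L))
  expect_equal(gat_layer(h, W, a, nb, "concat"), gat_layer(h, W, a, nb, "average"))
})

test_that("uniform attention on a regular graph averages neighbour features", {
  # 3-cycle with self-loops, zero attention vector, identity-like W
  h <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  W <- list(diag(2))
  a <- list(rep(0, 4))
  nb <- list(c(1L, 2L, 3L), c(1L, 2L, 3L), c(1L, 2L, 3L))
  out <- gat_layer(h, W, a, nb, "average")
  m <- colMeans(h)
  exp_row <- ifelse(m > 0, m, expm1(m))
  for (i in 1:3) expect_equal(out[i, ], exp_row)
})

test_that("layer output is equivariant to node permutation", {
  set.seed(3)
  h <- matrix(rnorm(15), 5, 3)
  W <- list(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3))
  a <- list(rnorm(6), rnorm(6))
  nb <- list(c(1L, 2L), c(1L, 2L, 3L), c(2L, 3L, 4L), c(3L, 4L, 5L), c(4L, 5L))
  out <- gat_layer(h, W, a, nb, "concat")
  perm <- c(3L, 5L, 1L, 2L, 4L)   # new index of old node i is match(i, perm)
  inv <- order(perm)
  nb_p <- lapply(perm, function(old) sort(inv[nb[[old]]]))
  out_p <- gat_layer(h[perm, ], W, a, nb_p, "concat")
  expect_equal(out_p, out[perm, ], tolerance = 1e-12)
})

test_that("graph prediction is invariant to node relabeling", {
  co <- tiny_cohort(seed = 5)
  gt <- cohort_gene_table(co)
  net <- cohort_network(co, gt)
  graphs <- assemble_patient_graphs(net, gt, co$labels)
  cfg_nodrop <- gat_config(heads = 2L, hidden = 6L, dropout = 0,
                           learning_rate = 0.02, epochs = 5L, patience = 0L,
                           val_fraction = 0, seed = 1L)
  m <- train_gat(graphs, config = cfg_nodrop)
  p1 <- predict_gat(m, graphs)
  # relabel genes (reverse alphabet) and rebuild: same patients, same graph
  relab <- setNames(rev(net$nodes), net$nodes)
  gt2 <- gt
  gt2$genes <- unname(relab[gt$genes])
  for (ch in names(gt2$channels)) colnames(gt2$channels[[ch]]) <- unname(relab[colnames(gt$channels[[ch]])])
  net2 <- dedupe_and_restrict(data.frame(gene_a = relab[net$edges$gene_a],
                                         gene_b = relab[net$edges$gene_b],
                                         combined_score = net$edges$combined_score),
                              gt2$genes)
  # reorder gene table columns to the new lexicographic order
  ord <- order(gt2$genes)
  gt2$genes <- gt2$genes[ord]
  for (ch in names(gt2$channels)) gt2$channels[[ch]] <- gt2$channels[[ch]][, ord]
  graphs2 <- assemble_patient_graphs(net2, gt2, co$labels)
  m2 <- train_gat(graphs2, config = cfg_nodrop)
  expect_equal(m2$train_loss, m$train_loss, tolerance = 1e-8)
  p2 <- predict_gat(m2, graphs2)
  expect_equal(unname(p2$probs), unname(p1$probs), tolerance = 1e-8)
})

test_that("readout behaves as an affine map followed by softmax", {
  set.seed(4)
  emb <- matrix(rnorm(12), 4, 3)
  Wout <- matrix(rnorm(9), 3, 3)
  p0 <- readout_and_classify(matrix(0, 4, 3), Wout, rep(0, 3))
  expect_equal(p0, rep(1 / 3, 3))
  pr <- readout_and_classify(emb, Wout, rnorm(3))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # doubling embeddings doubles the (bias-free) logits
  l1 <- as.numeric(Wout %*% colMeans(emb))
  l2 <- as.numeric(Wout %*% colMeans(2 * emb))
  expect_equal(l2, 2 * l1)
})

test_that("training reduces the loss and is reproducible under a seed", {
  co <- tiny_cohort(seed = 8, effect = 2)
  gt <- cohort_gene_table(co)
  net <- cohort_network(co, gt)
  graphs <- assemble_patient_graphs(net, gt, co$labels)
  # standardize channels as the CV driver would
  X <- gatstack:::flatten_gene_table(gt)
  sc <- gatstack:::fit_scaler(X)
  graphs$features <- gatstack:::flat_to_graph_features(
    gatstack:::apply_scaler(sc, X), net$nodes)
  cfg <- tiny_gat_config(seed = 2, epochs = 100L)
  m <- train_gat(graphs, config = cfg)
  expect_lte(tail(m$train_loss, 1), 0.5 * m$train_loss[1])
  m2 <- train_gat(graphs, config = cfg)
  expect_equal(tail(m2$train_loss, 1), tail(m$train_loss, 1), tolerance = 1e-6)

  pr <- predict_gat(m, graphs)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-6))
  expect_gt(mean(pr$labels == co$labels), 0.7)

  # an untrained model predicts near chance
  cfg0 <- tiny_gat_config(seed = 2, epochs = 0L)
  m0 <- train_gat(graphs, config = cfg0)
  pr0 <- predict_gat(m0, graphs)
  expect_lt(mean(abs(pr0$probs - 1 / 3)), 0.2)
})

test_that("early stopping restores the best validation checkpoint", {
  co <- tiny_cohort(seed = 10)
  gt <- cohort_gene_table(co)
  net <- cohort_network(co, gt)
  graphs <- assemble_patient_graphs(net, gt, co$labels)
  cfg <- gat_config(heads = 2, hidden = 6, dropout = 0.1, learning_rate = 0.02,
                    epochs = 40L, patience = 5L, val_fraction = 0.2, seed = 1)
  m <- train_gat(graphs, config = cfg)
  expect_gt(length(m$val_loss), 0)
  expect_lte(m$best_epoch, length(m$train_loss))
})

test_that("attention scores lie in [0,1] and are flat on uniform regular graphs", {
  # planted-hub case: the informative hubs should attract attention
  co <- tiny_cohort(seed = 12, effect = 2)
  gt <- cohort_gene_table(co)
  net <- cohort_network(co, gt)
  graphs <- assemble_patient_graphs(net, gt, co$labels)
  m <- train_gat(graphs, config = tiny_gat_config(seed = 3, epochs = 30L))
  att <- node_attention_scores(m, graphs)
  expect_equal(range(att), c(0, 1))
  top_decile <- names(sort(att, decreasing = TRUE))[seq_len(ceiling(length(att) / 10))]
  expect_gte(length(intersect(top_decile, co$truth_genes)), 1)

  # uniform features on a ring: identical incoming mass everywhere -> 0.5
  ring <- make_network(cbind(1:6, c(2:6, 1)))
  feats <- array(1, c(6, 3, 4), dimnames = list(ring$nodes, NULL, NULL))
  g_ring <- structure(list(network = ring, features = feats,
                           sample_ids = sprintf("p%d", 1:4),
                           labels = factor(c("a", "a", "b", "b"))),
                      class = "patient_graphs")
  m_ring <- train_gat(g_ring, config = tiny_gat_config(seed = 1, epochs = 2L))
  att_ring <- node_attention_scores(m_ring, g_ring)
  expect_lt(max(att_ring) - min(att_ring), 0.3)
})
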