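# Independent oracles used by the unit and acceptance tests.

# closed-form least squares / ridge on a centered response
ols_oracle <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))
ridge_oracle <- function(X, y, lambda) {
  n <- nrow(X)
  as.numeric(solve(crossprod(X) + n * lambda * diag(ncol(X)), crossprod(X, y)))
}

# dense loop-based forward pass of the two-layer GAT (via the package's
# reference R layer math), returning class probabilities and layer-1
# attention for one patient
dense_gat_forward <- function(X, params, neighbors) {
  a1 <- mapply(function(s, d) c(s, d), params$a1s, params$a1n, SIMPLIFY = FALSE)
  a2 <- mapply(function(s, d) c(s, d), params$a2s, params$a2n, SIMPLIFY = FALSE)
  h1 <- gat_layer(X, params$W1, a1, neighbors, mode = "concat")
  h2 <- gat_layer(h1, params$W2, a2, neighbors, mode = "average")
  list(probs = readout_and_classify(h2, params$Wout, params$bout),
       h1 = h1, h2 = h2)
}

# neighbourhoods (with self-loops) of a ppi_network, as node-index lists
network_neighbors <- function(network) {
  n <- length(network$nodes)
  ia <- match(network$edges$gene_a, network$nodes)
  ib <- match(network$edges$gene_b, network$nodes)
  lapply(seq_len(n), function(i) sort(unique(c(i, ib[ia == i], ia[ib == i]))))
}

# undirected connectivity check by breadth-first search
is_connected_graph <- function(edges, nodes) {
  adj <- lapply(nodes, function(g)
    unique(c(edges$gene_b[edges$gene_a == g], edges$gene_a[edges$gene_b == g])))
  names(adj) <- nodes
  seen <- nodes[1]
  frontier <- nodes[1]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  setequal(seen, nodes)
}

anova_pvals <- function(values, labels) {
  apply(values, 2, function(v) anova(lm(v ~ labels))$`Pr(>F)`[1])
}
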