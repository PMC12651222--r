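# Repeated stratified cross-validation orchestration, metrics, paired
# t-tests, per-gene ANOVA, and min-max normalization.

#' Repeated stratified fold plan
#'
#' @param labels factor of class labels.
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats (default 3).
#' @param seed integer seed.
#' @return a `cv_plan`: list with `assignment` (samples x repeats fold-id
#'   matrix), `n_folds`, `n_repeats`, `seed`.
#' @export
cv_plan <- function(labels, n_folds = 5L, n_repeats = 3L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  assignment <- vapply(seq_len(n_repeats), function(r) {
    stratified_folds_complete(labels, n_folds, seed + 131L * r)
  }, integer(length(labels)))
  rownames(assignment) <- names(labels)
  # stratification tolerance: each fold within one sample per class
  for (r in seq_len(n_repeats)) {
    tab <- table(labels, assignment[, r])
    expected <- as.numeric(table(labels)) / n_folds
    if (any(abs(sweep(tab, 1, expected, "-")) > 1 + 1e-9))
      stopf("stratification tolerance exceeded in repeat %d", r)
  }
  structure(list(assignment = assignment, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Classification metric bundle
#'
#' Accuracy plus macro-averaged precision, recall, F1, one-vs-rest
#' ROC-AUC and AUPRC (average precision). Classes absent from `y_true`
#' (or present in every row) are excluded from the AUC macro averages
#' with a warning.
#'
#' @param y_true factor of true labels.
#' @param probs class-probability matrix (named columns covering the
#'   classes; rows sum to 1).
#' @return named numeric vector: `accuracy`, `precision`, `recall`, `f1`,
#'   `roc_auc`, `auprc`.
#' @export
compute_metrics <- function(y_true, probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(y_true)) stopf("probability rows do not match labels")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stopf("probability rows must sum to 1")
  classes <- sort(colnames(probs))
  probs <- probs[, classes, drop = FALSE]
  y_true <- factor(as.character(y_true), levels = classes)
  pred <- prob_argmax(probs)

  acc <- mean(pred == y_true)
  prec <- rec <- f1 <- numeric(0)
  for (cl in classes) {
    tp <- sum(pred == cl & y_true == cl)
    fp <- sum(pred == cl & y_true != cl)
    fn <- sum(pred != cl & y_true == cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    prec <- c(prec, p); rec <- c(rec, r); f1 <- c(f1, f)
  }
  aucs <- auprcs <- numeric(0)
  skipped <- character(0)
  for (cl in classes) {
    pos <- y_true == cl
    if (!any(pos) || all(pos)) { skipped <- c(skipped, cl); next }
    roc <- pROC::roc(response = as.integer(pos), predictor = probs[, cl],
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    aucs <- c(aucs, as.numeric(roc$auc))
    auprcs <- c(auprcs, average_precision(pos, probs[, cl]))
  }
  if (length(skipped))
    warning(sprintf("AUC undefined for class(es) %s; excluded from macro average",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  c(accuracy = acc, precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    roc_auc = if (length(aucs)) mean(aucs) else NA_real_,
    auprc = if (length(auprcs)) mean(auprcs) else NA_real_)
}

# Average precision (step-interpolated area under the PR curve); ties in
# the score are handled as one block.
average_precision <- function(pos, score) {
  o <- order(score, decreasing = TRUE)
  pos <- as.logical(pos)[o]
  score <- score[o]
  n_pos <- sum(pos)
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  # collapse tied scores to the block's final confusion counts
  last_of_block <- c(score[-1] != score[-length(score)], TRUE)
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  dr <- diff(c(0, recall))
  sum(precision * dr)
}

#' Paired two-sided t-test on fold-wise metric differences
#'
#' Degenerate branches: identically zero differences give `t = 0, p = 1`;
#' constant non-zero differences give `t = +/-Inf, p = 0`.
#'
#' @param metric_a,metric_b equal-length paired metric vectors.
#' @return list with `t`, `p`, `df`.
#' @export
paired_ttest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stopf("paired vectors differ in length")
  n <- length(metric_a)
  if (n < 2) stopf("paired t-test needs at least 2 pairs")
  d <- metric_a - metric_b
  if (sd(d) < 1e-15) {
    if (all(abs(d) < 1e-15)) return(list(t = 0, p = 1, df = n - 1))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1))
  }
  ht <- t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' One-way ANOVA per gene and omic layer
#'
#' For each omic channel with a non-degenerate value vector, fits the
#' one-way ANOVA of value against subtype and reports F and p; the best
#' omic is the one with the smallest p. All-zero channels are skipped.
#'
#' @param gene gene symbol (annotation only).
#' @param channel_values named list of per-omic numeric vectors, names
#'   among `RNASeq`, `Methylation`, `miRNA`.
#' @param labels factor of subtypes aligned with the vectors.
#' @return one-row data.frame: `gene`, per-omic `F_`/`p_` columns,
#'   `best_omic`, `p_value`.
#' @export
anova_per_gene <- function(gene, channel_values, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) {
    warning(sprintf("gene %s skipped: fewer than 2 groups", gene), call. = FALSE)
    return(NULL)
  }
  out <- list(gene = gene)
  best_p <- Inf; best_omic <- NA_character_
  for (om in names(channel_values)) {
    v <- channel_values[[om]]
    if (all(v == 0) || var(v) < 1e-15) {
      out[[paste0("F_", om)]] <- NA_real_
      out[[paste0("p_", om)]] <- NA_real_
      next
    }
    a <- anova(lm(v ~ labels))
    Fv <- a$`F value`[1]; pv <- a$`Pr(>F)`[1]
    out[[paste0("F_", om)]] <- Fv
    out[[paste0("p_", om)]] <- pv
    if (!is.na(pv) && pv < best_p) { best_p <- pv; best_omic <- om }
  }
  out$best_omic <- best_omic
  out$p_value <- if (is.finite(best_p)) best_p else NA_real_
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Best-omic ANOVA table over a gene set
#'
#' @param gene_table a [build_gene_table()] result.
#' @param labels named subtype factor for the table's samples.
#' @param genes genes to test (default: all in the table).
#' @return data.frame, one row per testable gene.
#' @export
anova_best_omic <- function(gene_table, labels, genes = NULL) {
  genes <- genes %||% gene_table$genes
  labels <- labels[gene_table$sample_ids]
  rows <- lapply(genes, function(g) {
    if (!(g %in% gene_table$genes)) return(NULL)
    anova_per_gene(g, list(
      RNASeq = gene_table$channels$mrna[, g],
      Methylation = gene_table$channels$meth[, g],
      miRNA = gene_table$channels$mirna[, g]), labels)
  })
  do.call(rbind, rows)
}

#' Min-max normalization to `[0, 1]`
#'
#' Constant vectors map to 0.5 (documented convention).
#'
#' @param values numeric vector with at least one finite value.
#' @return normalized vector preserving names.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0) stopf("empty input")
  if (!any(is.finite(values))) stopf("no finite values")
  rng <- range(values)
  if (diff(rng) < 1e-15) return(setNames(rep(0.5, length(values)), names(values)))
  (values - rng[1]) / diff(rng)
}

# Leakage audit: no sample id used to fit anything may appear in the
# held-out partition.
audit_fold_confinement <- function(fit_records, test_ids, context = "") {
  seen <- unique(unlist(fit_records, use.names = FALSE))
  leak <- intersect(seen, test_ids)
  if (length(leak))
    stopf("leakage audit failed%s: test sample(s) entered a training fit: %s",
          if (nzchar(context)) paste0(" (", context, ")") else "",
          paste(head(leak, 5), collapse = ", "))
  invisible(TRUE)
}

#' Run the hybrid pipeline under repeated stratified cross-validation
#'
#' Per fold, entirely on the training partition: standardization
#' statistics, variance filter, elastic-net selection, SMOTE, the RF and
#' GAT arms, out-of-fold meta features and the stacking meta-learner. The
#' held-out partition is transformed with the frozen statistics and
#' scored for all three models. A leakage audit asserts that no held-out
#' sample id entered any fit; the internal `inject_global_scaling` switch
#' deliberately violates this (the audit's negative control) and must
#' abort the run.
#'
#' @param gene_table a [build_gene_table()] result.
#' @param labels named subtype factor.
#' @param network a `ppi_network` over the annotated genes.
#' @param config a [hybrid_config()].
#' @param plan a [cv_plan()]; default 5 folds x 3 repeats.
#' @param combination subset of `c("RNA", "METH", "MIR")`; excluded
#'   channels are zeroed and their features never reach selection.
#' @param seed integer seed for per-fold sub-seeds.
#' @param inject_global_scaling internal negative control (see above).
#' @return a `cv_result`: `fold_results` (one row per model per fold),
#'   `rf_gene_importance` and `attention` (folds x genes matrices),
#'   `selections`, `plan`, `classes`, `genes`.
#' @export
run_cv <- function(gene_table, labels, network, config = hybrid_config(),
                   plan = NULL, combination = c("RNA", "METH", "MIR"),
                   seed = 1L, inject_global_scaling = FALSE) {
  labels <- droplevels(as.factor(labels[gene_table$sample_ids]))
  plan <- plan %||% cv_plan(labels, seed = seed)
  X_raw <- flatten_gene_table(gene_table, combination)
  rownames(X_raw) <- gene_table$sample_ids
  genes <- gene_table$genes

  n_cells <- plan$n_repeats * plan$n_folds
  fold_results <- list()
  rf_imp <- matrix(0, n_cells, length(genes), dimnames = list(NULL, genes))
  att <- matrix(0, n_cells, length(genes), dimnames = list(NULL, genes))
  selections <- vector("list", n_cells)
  cell <- 0L
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      cell <- cell + 1L
      te <- plan$assignment[, r] == f
      tr_ids <- gene_table$sample_ids[!te]
      te_ids <- gene_table$sample_ids[te]
      fold_seed <- seed + 7919L * cell

      base <- fit_base_models(X_raw[tr_ids, , drop = FALSE], labels[tr_ids],
                              network, config, seed = fold_seed,
                              global_X = if (inject_global_scaling) X_raw else NULL)
      oof <- oof_meta_features(X_raw[tr_ids, , drop = FALSE], labels[tr_ids],
                               network, config, seed = fold_seed + 53L)
      meta_model <- train_meta(oof$meta, labels[tr_ids], config$ridge_strength)

      records <- c(base$fit_records,
                   lapply(oof$fit_records, `[[`, "saw"))
      audit_fold_confinement(records, te_ids,
                             context = sprintf("repeat %d fold %d", r, f))

      pr <- predict_base_models(base, X_raw[te_ids, , drop = FALSE])
      st <- predict_stacked(meta_model, pr$rf_probs, pr$gat_probs)

      y_te <- labels[te_ids]
      for (mod in c("RF", "GAT", "stacked")) {
        probs <- switch(mod, RF = pr$rf_probs, GAT = pr$gat_probs, stacked = st$probs)
        m <- suppressWarnings(compute_metrics(y_te, probs))
        fold_results[[length(fold_results) + 1L]] <-
          data.frame(model = mod, rep = r, fold = f, t(m), stringsAsFactors = FALSE)
      }

      imp <- rf_importance(base$rf)
      g_of <- sub("\\|.*$", "", names(imp))
      per_gene <- tapply(imp, g_of, sum)
      rf_imp[cell, names(per_gene)] <- per_gene

      a <- node_attention_scores(base$gat, base$graphs_train)
      att[cell, intersect(names(a), genes)] <- a[intersect(names(a), genes)]

      selections[[cell]] <- base$selection
    }
  }
  structure(list(fold_results = do.call(rbind, fold_results),
                 rf_gene_importance = rf_imp, attention = att,
                 selections = selections, plan = plan,
                 classes = sort(levels(labels)), genes = genes,
                 combination = combination),
            class = "cv_result")
}

#' Summarize fold results as mean +/- SD per model
#'
#' @param fold_results the `fold_results` data.frame of a [run_cv()].
#' @return data.frame with one row per model.
#' @export
summarize_cv <- function(fold_results) {
  metrics <- c("accuracy", "precision", "recall", "f1", "roc_auc", "auprc")
  out <- lapply(split(fold_results, fold_results$model), function(d) {
    row <- list(model = d$model[1])
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- sd(d[[m]], na.rm = TRUE)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired t-test table: stacked model versus each baseline
#'
#' @param fold_results the `fold_results` of a [run_cv()].
#' @param metrics metric columns to compare.
#' @return data.frame: metric, comparison, t, p.
#' @export
ttest_table <- function(fold_results, metrics = c("roc_auc", "auprc")) {
  wide <- function(mod, m) {
    d <- fold_results[fold_results$model == mod, ]
    d <- d[order(d$rep, d$fold), ]
    d[[m]]
  }
  rows <- list()
  for (m in metrics) {
    for (base in c("RF", "GAT")) {
      ht <- paired_ttest(wide("stacked", m), wide(base, m))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, comparison = paste0("Hybrid vs. ", base),
        t_statistic = ht$t, p_value = ht$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
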