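# Biomarker ranking: fold-aggregated RF importance and GAT attention,
# min-max scaled, combined by a weighted mean, and annotated with the
# most discriminative omic layer per gene.

#' Aggregate per-fold importance and attention scores
#'
#' Per-gene mean across folds and repeats (genes missing from a fold
#' contribute 0 through the fold matrices), each component then min-max
#' scaled to `[0, 1]`.
#'
#' @param rf_fold_importance folds x genes matrix of per-gene RF
#'   importances.
#' @param attention_fold_scores folds x genes matrix of attention scores.
#' @return list: `rf` and `attention`, named scaled vectors on the same
#'   gene universe.
#' @export
aggregate_importances <- function(rf_fold_importance, attention_fold_scores) {
  if (nrow(rf_fold_importance) == 0 || nrow(attention_fold_scores) == 0)
    stopf("need at least one fold of scores")
  if (!identical(colnames(rf_fold_importance), colnames(attention_fold_scores)))
    stopf("gene universes differ between components")
  list(rf = minmax_normalize(colMeans(rf_fold_importance)),
       attention = minmax_normalize(colMeans(attention_fold_scores)))
}

#' Combine RF and attention scores into the hybrid biomarker ranking
#'
#' `combined = w * rf + (1 - w) * attention`, sorted descending with ties
#' broken by lexicographic gene symbol.
#'
#' @param rf_scores,attention_scores named score vectors on the same gene
#'   universe (misalignment is an error naming the symmetric difference).
#' @param w RF weight in `[0, 1]`; `w = 1` is the RF-only view, `w = 0`
#'   the attention-only view.
#' @return data.frame: `rank`, `gene`, `rf_importance`,
#'   `attention_score`, `combined`.
#' @export
combine_and_rank <- function(rf_scores, attention_scores, w = 0.5) {
  if (w < 0 || w > 1) stopf("w must be in [0, 1]")
  if (!setequal(names(rf_scores), names(attention_scores))) {
    d <- c(setdiff(names(rf_scores), names(attention_scores)),
           setdiff(names(attention_scores), names(rf_scores)))
    stopf("gene universes differ: %s", paste(d, collapse = ", "))
  }
  genes <- sort(names(rf_scores))
  rf <- rf_scores[genes]; at <- attention_scores[genes]
  combined <- w * rf + (1 - w) * at
  o <- order(-combined, genes)
  data.frame(rank = seq_along(genes), gene = genes[o],
             rf_importance = as.numeric(rf[o]),
             attention_score = as.numeric(at[o]),
             combined = as.numeric(combined[o]),
             stringsAsFactors = FALSE)
}

#' Annotate a ranking with each gene's most discriminative omic
#'
#' @param ranking a [combine_and_rank()] result.
#' @param anova_results an [anova_best_omic()] table.
#' @return the ranking with `best_omic` and `p_value` columns; genes
#'   without an ANOVA row are flagged (`anova_missing = TRUE`), never
#'   dropped.
#' @export
annotate_best_omic <- function(ranking, anova_results) {
  hit <- match(ranking$gene, anova_results$gene)
  ranking$best_omic <- ifelse(is.na(hit), NA_character_, anova_results$best_omic[hit])
  ranking$p_value <- ifelse(is.na(hit), NA_real_, anova_results$p_value[hit])
  ranking$anova_missing <- is.na(hit)
  ranking
}

#' Precision of the top-k ranking against a known truth set
#'
#' @param ranking a [combine_and_rank()] result.
#' @param truth_genes character vector of planted informative genes.
#' @param k ranking depth.
#' @return fraction of the top `k` genes that are true positives.
#' @export
precision_at_k <- function(ranking, truth_genes, k = 20L) {
  top <- head(ranking$gene, k)
  mean(top %in% truth_genes)
}
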