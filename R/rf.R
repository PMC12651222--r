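# Random-forest arm: bagged CART trees with per-node random feature
# subsets, majority-vote prediction (lexicographic tie-break) and
# normalized Gini impurity importance.

#' Train the random-forest arm
#'
#' `T` trees on bootstrap samples of size `n`, with `ceil(sqrt(F))`
#' candidate features per split and the Gini criterion, grown to purity.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y factor of class labels (at least two classes present).
#' @param n_trees number of trees `T` (default 500).
#' @param mtry features tried per split; default `ceil(sqrt(F))`.
#' @param seed integer seed.
#' @return a `forest_model` wrapping the fitted ensemble.
#' @export
train_forest <- function(X, y, n_trees = 500L, mtry = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stopf("random forest needs at least 2 classes, got %d", nlevels(y))
  mtry <- mtry %||% ceiling(sqrt(ncol(X)))
  fit <- with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = n_trees, mtry = min(mtry, ncol(X))))
  structure(list(fit = fit, classes = sort(levels(y)),
                 feature_ids = colnames(X), n_trees = n_trees,
                 fit_rows = rownames(X)),
            class = "forest_model")
}

#' Majority-vote prediction with vote-fraction probabilities
#'
#' The label is the modal tree vote; ties break to the lexicographically
#' smallest class. Probabilities are the per-class vote fractions (rows
#' sum to 1), which is what the stacking meta-learner consumes.
#'
#' @param model a [train_forest()] result.
#' @param X feature matrix with the training columns.
#' @return list: `labels` (factor) and `probs` (samples x classes).
#' @export
predict_vote <- function(model, X) {
  stopifnot(inherits(model, "forest_model"))
  X <- as.matrix(X)
  if (!identical(colnames(X), model$feature_ids))
    stopf("feature columns do not match the trained forest")
  votes <- predict(model$fit, X, type = "vote", norm.votes = TRUE)
  votes <- votes[, model$classes, drop = FALSE]
  votes <- votes / rowSums(votes)
  if (is.null(rownames(votes))) rownames(votes) <- rownames(X)
  list(labels = prob_argmax(votes), probs = votes)
}

#' Normalized impurity importance
#'
#' Mean decrease in Gini impurity per feature, normalized to sum to 1;
#' features never used in any split score 0.
#'
#' @param model a [train_forest()] result.
#' @return named numeric vector over features.
#' @export
rf_importance <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  imp <- model$fit$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  if (tot <= 0) return(setNames(rep(0, length(imp)), model$feature_ids))
  setNames(as.numeric(imp / tot), model$feature_ids)
}

#' Export importances as TSV
#'
#' @param importance named importance vector (feature ids of the form
#'   `gene|channel` get a modality column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_importances <- function(importance, path) {
  ids <- names(importance)
  write_tsv(data.frame(feature_id = ids,
                       modality = sub("^.*\\|", "", ids),
                       importance = as.numeric(importance),
                       stringsAsFactors = FALSE), path)
}
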