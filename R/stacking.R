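# Base-model fitting (fold-confined preprocessing + RF + GAT) and the
# ridge-logistic stacking meta-learner with out-of-fold meta features.
#
# Every fitted object records the sample ids it was fit on (`fit_rows`),
# which the cross-validation driver audits against the held-out partition.

#' Hybrid pipeline configuration
#'
#' Bundles the per-arm settings used inside every training fold.
#'
#' @param enet an [enet_params()].
#' @param gat a [gat_config()].
#' @param rf_trees trees in the random-forest arm.
#' @param smote_k SMOTE nearest-neighbour count.
#' @param ridge_strength L2 weight of the stacking meta-learner, on the
#'   summed log-likelihood scale of standardized meta features.
#' @param inner_folds stratified inner folds for out-of-fold meta features
#'   (and the elastic-net penalty search).
#' @return a `hybrid_config` list.
#' @export
hybrid_config <- function(enet = enet_params(), gat = gat_config(),
                          rf_trees = 500L, smote_k = 5L,
                          ridge_strength = 1, inner_folds = 5L) {
  structure(list(enet = enet, gat = gat, rf_trees = as.integer(rf_trees),
                 smote_k = as.integer(smote_k), ridge_strength = ridge_strength,
                 inner_folds = as.integer(inner_folds)),
            class = "hybrid_config")
}

# Fold-confined training core: variance filter, standardization, elastic
# net selection, SMOTE (selected space, with the full standardized matrix
# as companion for the graph arm), then RF on the selected features and
# GAT on the shared topology. `global_X`, when supplied, deliberately fits
# the scaler on the whole dataset -- the negative control for the leakage
# audit.
fit_base_models <- function(X_raw, y, network, config, seed,
                            global_X = NULL) {
  y <- droplevels(as.factor(y))
  if (is.null(global_X)) {
    scaler <- fit_scaler(X_raw)
  } else {
    scaler <- fit_scaler(global_X)  # leakage by construction
  }
  X_std <- apply_scaler(scaler, X_raw)

  v <- apply(X_raw, 2, var)
  keep <- which(v >= 1e-12)
  if (!length(keep)) stopf("variance filter removed every feature")

  sel <- select_features(X_raw[, keep, drop = FALSE], y,
                         params = config$enet, seed = seed + 1L)
  sel_cols <- colnames(X_raw)[keep][match(sel$feature_ids, colnames(X_raw)[keep])]

  bal <- smote_balance(X_std[, sel_cols, drop = FALSE], y,
                       k = config$smote_k, seed = seed + 2L,
                       companions = list(full = X_std))

  rf <- train_forest(bal$X, bal$y, n_trees = config$rf_trees, seed = seed + 3L)

  gat_cfg <- config$gat
  gat_cfg$seed <- seed + 4L
  feats <- flat_to_graph_features(bal$companions$full, network$nodes)
  graphs <- structure(list(network = network, features = feats,
                           sample_ids = rownames(bal$X), labels = bal$y),
                      class = "patient_graphs")
  gat <- train_gat(graphs, config = gat_cfg)

  fit_records <- list(scaler = scaler$fit_rows, selection = sel$fit_rows,
                      smote = bal$fit_rows, rf = rownames(X_raw),
                      gat = rownames(X_raw))
  list(scaler = scaler, keep = keep, selection = sel, sel_cols = sel_cols,
       smote = bal, rf = rf, gat = gat, graphs_train = graphs,
       classes = sort(levels(y)), network = network,
       fit_records = fit_records)
}

# Probabilities of both arms on new raw rows, using frozen fold statistics.
predict_base_models <- function(base, X_raw_new) {
  X_std <- apply_scaler(base$scaler, X_raw_new)
  rf_out <- predict_vote(base$rf, X_std[, base$sel_cols, drop = FALSE])
  feats <- flat_to_graph_features(X_std, base$network$nodes)
  graphs <- structure(list(network = base$network, features = feats,
                           sample_ids = rownames(X_raw_new), labels = NULL),
                      class = "patient_graphs")
  gat_out <- predict_gat(base$gat, graphs)
  list(rf_probs = rf_out$probs, gat_probs = gat_out$probs)
}

#' Out-of-fold meta features for stacking
#'
#' Splits the training rows into stratified inner folds; for each fold the
#' full fold-confined pipeline (selection, SMOTE, RF, GAT) is retrained on
#' the complement and predicts the held rows, so no meta feature was
#' produced by a fit that saw its own row. Columns are the three RF vote
#' fractions followed by the three GAT probabilities.
#'
#' @param X_raw raw flattened gene-channel matrix of the training rows.
#' @param y factor labels aligned with `X_raw`.
#' @param network the shared `ppi_network`.
#' @param config a [hybrid_config()].
#' @param seed integer seed.
#' @return list: `meta` (rows x 6), `assignment` (inner fold per row),
#'   `fit_records` (per inner fold: ids each fit saw, plus held ids).
#' @export
oof_meta_features <- function(X_raw, y, network, config = hybrid_config(),
                              seed = 1L) {
  y <- droplevels(as.factor(y))
  classes <- sort(levels(y))
  folds <- stratified_folds_complete(y, config$inner_folds, seed)
  meta <- matrix(NA_real_, nrow(X_raw), 2 * length(classes),
                 dimnames = list(rownames(X_raw),
                                 c(paste0("rf_", classes), paste0("gat_", classes))))
  fit_records <- vector("list", config$inner_folds)
  for (f in seq_len(config$inner_folds)) {
    tr <- folds != f
    base <- fit_base_models(X_raw[tr, , drop = FALSE], y[tr], network,
                            config, seed = seed + 10L * f)
    pr <- predict_base_models(base, X_raw[!tr, , drop = FALSE])
    meta[!tr, ] <- cbind(pr$rf_probs[, classes, drop = FALSE],
                         pr$gat_probs[, classes, drop = FALSE])
    fit_records[[f]] <- list(saw = unique(unlist(base$fit_records)),
                             held = rownames(X_raw)[!tr])
  }
  stopifnot(!anyNA(meta))
  list(meta = meta, assignment = folds, fit_records = fit_records)
}

#' Train the ridge-logistic stacking meta-learner
#'
#' Multinomial (softmax) extension of the binary sigmoid model, fit on
#' standardized meta features with an L2 penalty on the slopes (intercepts
#' unpenalized). When every meta feature is constant the model degenerates
#' to the intercept-only fit reproducing the class priors.
#'
#' @param meta meta-feature matrix (rows x 6).
#' @param labels factor labels.
#' @param ridge_strength L2 weight against the summed log-likelihood.
#' @return a `meta_model`.
#' @export
train_meta <- function(meta, labels, ridge_strength = 1) {
  meta <- as.matrix(meta)
  if (!all(is.finite(meta))) stopf("meta features contain non-finite values")
  labels <- droplevels(as.factor(labels))
  classes <- sort(levels(labels))
  v <- apply(meta, 2, var)
  if (all(v < 1e-12)) {
    priors <- as.numeric(table(factor(labels, classes)) / length(labels))
    return(structure(list(type = "prior", classes = classes, priors = priors,
                          ridge_strength = ridge_strength),
                     class = "meta_model"))
  }
  scaler <- fit_scaler(meta)
  Xs <- apply_scaler(scaler, meta)
  if (ncol(Xs) < 2) Xs <- cbind(Xs, .pad = 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(Xs, factor(labels, classes), family = "multinomial",
                        alpha = 0, lambda = ridge_strength / nrow(Xs),
                        standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  structure(list(type = "glmnet", fit = fit, scaler = scaler,
                 classes = classes, ridge_strength = ridge_strength),
            class = "meta_model")
}

#' Predict from the stacking meta-learner
#'
#' @param model a [train_meta()] result.
#' @param meta meta-feature matrix with the training columns.
#' @return list: `probs` (rows sum to 1) and `labels` (argmax,
#'   lexicographic tie-break).
#' @export
predict_meta <- function(model, meta) {
  stopifnot(inherits(model, "meta_model"))
  meta <- as.matrix(meta)
  if (model$type == "prior") {
    probs <- matrix(model$priors, nrow(meta), length(model$classes), byrow = TRUE,
                    dimnames = list(rownames(meta), model$classes))
  } else {
    Xs <- apply_scaler(model$scaler, meta)
    if (ncol(Xs) < 2) Xs <- cbind(Xs, .pad = 0)
    probs <- predict(model$fit, Xs, type = "response")[, , 1]
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                             dimnames = list(rownames(meta), model$classes))
    probs <- probs[, model$classes, drop = FALSE]
    rownames(probs) <- rownames(meta)
  }
  probs <- probs / rowSums(probs)
  list(probs = probs, labels = prob_argmax(probs))
}

#' Stacked prediction from base-model probabilities
#'
#' @param model a [train_meta()] result.
#' @param rf_probs,gat_probs base-model class-probability matrices with
#'   identically ordered rows.
#' @return list: `probs` and `labels`.
#' @export
predict_stacked <- function(model, rf_probs, gat_probs) {
  classes <- model$classes
  meta <- cbind(rf_probs[, classes, drop = FALSE], gat_probs[, classes, drop = FALSE])
  colnames(meta) <- c(paste0("rf_", classes), paste0("gat_", classes))
  predict_meta(model, meta)
}
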