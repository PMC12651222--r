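# ElasticNet feature selection by cyclic coordinate descent.
#
# The selector fits one-hot multi-response penalized least squares: the
# penalty is elementwise, so the three response columns decouple into
# independent elastic nets whose supports are unioned. The penalty grid is
# 50 logarithmically spaced strengths in [1e-5, 1] with the mixing
# parameter fixed at 0.1, and the working strength is picked by stratified
# inner cross-validation on mean squared error.

#' ElasticNet parameters
#'
#' @param alpha L1/L2 mixing parameter in `[0, 1]` (default 0.1).
#' @param lambda optional explicit penalty grid (strictly increasing);
#'   default 50 log-spaced values in `[lambda_min, lambda_max]`.
#' @param n_lambda grid size when `lambda` is `NULL`.
#' @param lambda_min,lambda_max grid endpoints.
#' @param inner_folds folds of the penalty-selection cross-validation.
#' @param tol coordinate-descent tolerance on the maximum coefficient
#'   change per sweep.
#' @param max_sweeps sweep cap per penalty value.
#' @param nonzero_tol coefficient magnitude treated as non-zero.
#' @return an `enet_params` list.
#' @export
enet_params <- function(alpha = 0.1, lambda = NULL, n_lambda = 50L,
                        lambda_min = 1e-5, lambda_max = 1,
                        inner_folds = 5L, tol = 1e-6, max_sweeps = 2000L,
                        nonzero_tol = 1e-8) {
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  if (is.null(lambda))
    lambda <- 10^seq(log10(lambda_min), log10(lambda_max), length.out = n_lambda)
  if (is.unsorted(lambda, strictly = TRUE)) stopf("lambda grid must be strictly increasing")
  structure(list(alpha = alpha, lambda = lambda, inner_folds = as.integer(inner_folds),
                 tol = tol, max_sweeps = as.integer(max_sweeps),
                 nonzero_tol = nonzero_tol),
            class = "enet_params")
}

#' Fit the elastic-net coefficient path
#'
#' Minimizes `1/(2n) ||y - X b||^2 + lambda (alpha ||b||_1 +
#' (1-alpha)/2 ||b||_2^2)` per response column by cyclic coordinate
#' descent, warm-started down the penalty path. `X` is used as supplied
#' (callers standardize); response columns are centered internally, so
#' coefficients exclude the intercept.
#'
#' @param X numeric feature matrix.
#' @param Y numeric response matrix (e.g. one-hot labels), one column per
#'   response.
#' @param params an [enet_params()].
#' @return list: `beta` (features x responses x lambdas array),
#'   `objective` (per response, per lambda: objective after every sweep),
#'   `lambda`, `y_center`.
#' @export
fit_enet_path <- function(X, Y, params = enet_params()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(is.finite(X))) stopf("X contains non-finite entries")
  if (!all(is.finite(Y))) stopf("Y contains non-finite entries")
  if (nrow(X) != nrow(Y)) stopf("X and Y row counts differ")
  lam_desc <- rev(params$lambda)
  L <- length(params$lambda); R <- ncol(Y); p <- ncol(X)
  beta <- array(0, dim = c(p, R, L),
                dimnames = list(colnames(X), colnames(Y), NULL))
  objective <- vector("list", R)
  y_center <- colMeans(Y)
  for (r in seq_len(R)) {
    fit <- enet_path_cpp(X, Y[, r] - y_center[r], lam_desc, params$alpha,
                         params$tol, params$max_sweeps)
    # reorder from descending fit order back to the increasing grid
    beta[, r, ] <- fit$beta[, L:1, drop = FALSE]
    objective[[r]] <- rev(fit$objective)
  }
  list(beta = beta, objective = objective, lambda = params$lambda,
       y_center = y_center)
}

#' Choose the penalty strength by inner cross-validation
#'
#' Stratified `inner_folds`-fold cross-validation; each fold standardizes
#' on its own training rows, fits the path, and scores held-out mean
#' squared error summed over response columns. The winner is the grid
#' value with minimum mean error; ties go to the larger (sparser) penalty.
#'
#' @param X raw feature matrix (standardized per inner fold internally).
#' @param Y one-hot response matrix.
#' @param params an [enet_params()].
#' @param seed integer seed for the fold draw.
#' @param y_labels optional factor used for stratification; defaults to
#'   the argmax of `Y`.
#' @return list: `lambda` (the chosen value), `cv_mse` (per grid value).
#' @export
choose_lambda <- function(X, Y, params = enet_params(), seed = 1L,
                          y_labels = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(y_labels)) y_labels <- factor(max.col(Y, ties.method = "first"))
  folds <- stratified_folds_complete(y_labels, params$inner_folds, seed)
  L <- length(params$lambda)
  err <- matrix(NA_real_, params$inner_folds, L)
  for (f in seq_len(params$inner_folds)) {
    tr <- folds != f; te <- !tr
    sc <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(sc, X[tr, , drop = FALSE])
    Xte <- apply_scaler(sc, X[te, , drop = FALSE])
    path <- fit_enet_path(Xtr, Y[tr, , drop = FALSE], params)
    se <- numeric(L)
    for (l in seq_len(L)) {
      pred <- Xte %*% path$beta[, , l] +
        matrix(path$y_center, sum(te), ncol(Y), byrow = TRUE)
      se[l] <- mean(rowSums((Y[te, , drop = FALSE] - pred)^2))
    }
    err[f, ] <- se
  }
  cv <- colMeans(err)
  best <- max(which(cv <= min(cv) + 1e-12))  # ties -> larger lambda
  list(lambda = params$lambda[best], cv_mse = cv, index = best)
}

#' Select features with the elastic net
#'
#' Standardizes columns with training statistics, drops (and logs)
#' zero-variance columns, one-hot encodes the three class labels, picks
#' the penalty by [choose_lambda()], refits on all rows and returns the
#' union of non-zero supports across the response columns. If the support
#' at the chosen penalty is empty, the largest grid penalty with at least
#' one non-zero coefficient is used instead, so the selection is never
#' empty.
#'
#' @param X raw feature matrix (samples x features, named columns).
#' @param y_labels factor of class labels.
#' @param params an [enet_params()].
#' @param seed integer seed.
#' @return list: `indices` (into `X` columns), `feature_ids`, `lambda`,
#'   `coefficients` (selected features x classes, standardized scale),
#'   `scaler`, `dropped` (zero-variance columns), `fit_rows`.
#' @export
select_features <- function(X, y_labels, params = enet_params(), seed = 1L) {
  X <- as.matrix(X)
  y_labels <- droplevels(as.factor(y_labels))
  v <- apply(X, 2, var)
  dropped <- which(v < 1e-12)
  if (length(dropped))
    message(sprintf("dropping %d zero-variance columns before selection", length(dropped)))
  keep <- setdiff(seq_len(ncol(X)), dropped)
  if (!length(keep)) stopf("no non-constant feature columns to select from")
  Xk <- X[, keep, drop = FALSE]
  Y <- one_hot(y_labels)

  cl <- choose_lambda(Xk, Y, params, seed, y_labels)
  sc <- fit_scaler(Xk)
  Xs <- apply_scaler(sc, Xk)
  path <- fit_enet_path(Xs, Y, params)

  support_at <- function(l) which(apply(abs(path$beta[, , l, drop = FALSE]) >
                                          params$nonzero_tol, 1, any))
  sel <- support_at(cl$index)
  lam <- cl$lambda
  if (!length(sel)) {
    for (l in rev(seq_along(params$lambda))) {
      sel <- support_at(l)
      if (length(sel)) { lam <- params$lambda[l]; cl$index <- l; break }
    }
  }
  if (!length(sel)) stopf("elastic net produced an empty model at every penalty")
  list(indices = keep[sel],
       feature_ids = colnames(X)[keep[sel]],
       lambda = lam,
       coefficients = path$beta[sel, , cl$index, drop = TRUE],
       scaler = sc,
       dropped = dropped,
       cv_mse = cl$cv_mse,
       fit_rows = rownames(X))
}

one_hot <- function(y) {
  y <- as.factor(y)
  Y <- matrix(0, length(y), nlevels(y), dimnames = list(names(y), levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# Column scaler fit on training rows only; zero-spread columns scale by 1.
fit_scaler <- function(X, rows = rownames(X)) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  structure(list(center = mu, scale = s, fit_rows = rows), class = "gatstack_scaler")
}

apply_scaler <- function(sc, X) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

#' Export per-fold selected features as TSV
#'
#' @param selections list of [select_features()] results (one per fold).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_selected_features <- function(selections, path) {
  rows <- lapply(seq_along(selections), function(f) {
    s <- selections[[f]]
    ids <- s$feature_ids
    modality <- sub("^.*\\|", "", ids)
    coef_max <- apply(abs(as.matrix(s$coefficients)), 1, max)
    data.frame(fold = f, feature_id = ids, modality = modality,
               coefficient = as.numeric(coef_max), stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
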