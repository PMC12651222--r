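# SMOTE minority oversampling: x_new = x_i + delta * (x_j - x_i) with
# x_j one of the k nearest same-class neighbours and delta ~ U(0, 1).
# Applied only inside training folds, after feature selection, with full
# parent-pair bookkeeping for auditability.

#' SMOTE class balancing
#'
#' Oversamples every minority class up to the majority count by convex
#' interpolation between a minority sample and one of its `k` nearest
#' minority neighbours (Euclidean metric on the supplied feature space).
#' Original rows are preserved verbatim and come first in the output.
#' `companions` are parallel matrices (same rows as `X`, e.g. the full
#' gene-channel matrix feeding the graph arm) interpolated with the exact
#' same parent pairs and deltas, so both classifier arms train on the same
#' augmented cohort.
#'
#' @param X numeric matrix, samples in rows.
#' @param y factor of class labels aligned with `X` rows.
#' @param k nearest-neighbour count (default 5); silently reduced (with a
#'   message) to `minority size - 1` when the class is smaller than `k+1`.
#' @param seed integer seed.
#' @param delta optional fixed interpolation weight in `[0, 1]` replacing
#'   the uniform draw (used to exercise the interpolation endpoints).
#' @param companions named list of matrices to augment identically.
#' @return list: `X`, `y`, `companions`, `audit` (data.frame
#'   `synthetic_row_id`, `parent_i`, `parent_j`, `delta`, `class`),
#'   `fit_rows`.
#' @export
smote_balance <- function(X, y, k = 5L, seed = 1L, delta = NULL,
                          companions = list()) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (is.null(rownames(X))) rownames(X) <- sprintf("row%04d", seq_len(nrow(X)))
  for (nm in names(companions)) {
    companions[[nm]] <- as.matrix(companions[[nm]])
    if (nrow(companions[[nm]]) != nrow(X))
      stopf("companion '%s' row count differs from X", nm)
  }
  counts <- table(y)
  maj <- max(counts)
  audit <- data.frame(synthetic_row_id = character(0), parent_i = character(0),
                      parent_j = character(0), delta = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (all(counts == maj)) {
    return(list(X = X, y = y, companions = companions, audit = audit,
                fit_rows = rownames(X)))
  }
  new_X <- list(); new_comp <- lapply(companions, function(z) list())
  new_y <- character(0)
  with_seed(seed, {
    for (cl in names(counts)[counts < maj]) {
      idx <- which(y == cl)
      m <- length(idx)
      if (m < 2)
        stopf("class '%s' has %d sample(s); SMOTE needs at least 2", cl, m)
      k_eff <- k
      if (m - 1L < k_eff) {
        k_eff <- m - 1L
        message(sprintf("SMOTE: k reduced to %d for class '%s' (size %d)", k_eff, cl, m))
      }
      D <- as.matrix(dist(X[idx, , drop = FALSE]))
      diag(D) <- Inf
      nn <- do.call(rbind, lapply(seq_len(m), function(r)
        order(D[r, ])[seq_len(k_eff)]))
      n_new <- maj - m
      seeds_i <- idx[sample.int(m, n_new, replace = TRUE)]
      for (t in seq_len(n_new)) {
        i <- seeds_i[t]
        local_i <- match(i, idx)
        j <- idx[nn[local_i, sample.int(k_eff, 1L)]]
        d <- if (is.null(delta)) runif(1) else delta
        # the d = 0 / d = 1 endpoints reproduce the parents exactly
        interp <- function(M) if (d == 0) M[i, ] else if (d == 1) M[j, ]
                              else M[i, ] + d * (M[j, ] - M[i, ])
        new_X[[length(new_X) + 1L]] <- interp(X)
        for (nm in names(companions))
          new_comp[[nm]][[length(new_comp[[nm]]) + 1L]] <- interp(companions[[nm]])
        new_y <- c(new_y, cl)
        audit[nrow(audit) + 1L, ] <- list(
          sprintf("syn_%s_%03d", gsub("[^A-Za-z0-9]", "", cl), t),
          rownames(X)[i], rownames(X)[j], d, cl)
      }
    }
  })
  X_aug <- rbind(X, do.call(rbind, new_X))
  rownames(X_aug) <- c(rownames(X), audit$synthetic_row_id)
  comp_aug <- companions
  for (nm in names(companions)) {
    comp_aug[[nm]] <- rbind(companions[[nm]], do.call(rbind, new_comp[[nm]]))
    rownames(comp_aug[[nm]]) <- rownames(X_aug)
  }
  y_aug <- factor(c(as.character(y), new_y), levels = levels(y))
  names(y_aug) <- rownames(X_aug)
  list(X = X_aug, y = y_aug, companions = comp_aug, audit = audit,
       fit_rows = rownames(X))
}

#' Write the SMOTE parent-pair audit table
#'
#' @param balanced a [smote_balance()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_smote_audit <- function(balanced, path) {
  write_tsv(balanced$audit, path)
}
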