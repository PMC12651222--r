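make_toy <- function(seed = 1, n = 10, p = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(2, -1, 0.5, 0, 0)[1:p]
  y <- as.numeric(X %*% beta + 0.1 * rnorm(n))
  list(X = X, y = y - mean(y))
}

test_that("the unpenalized limit matches ordinary least squares", {
  toy <- make_toy()
  params <- enet_params(lambda = c(0, 0.5), tol = 1e-10, max_sweeps = 50000)
  fit <- fit_enet_path(toy$X, cbind(toy$y), params)
  expect_equal(as.numeric(fit$beta[, 1, 1]), ols_oracle(toy$X, toy$y),
               tolerance = 1e-6)
})

test_that("the pure-L2 path matches the ridge closed form", {
  toy <- make_toy(2)
  for (lam in c(0.01, 0.1, 1)) {
    params <- enet_params(alpha = 0, lambda = c(lam, lam * 10),
                          tol = 1e-10, max_sweeps = 50000)
    fit <- fit_enet_path(toy$X, cbind(toy$y), params)
    expect_equal(as.numeric(fit$beta[, 1, 1]), ridge_oracle(toy$X, toy$y, lam),
                 tolerance = 1e-6, info = sprintf("lambda=%g", lam))
  }
})

test_that("a large enough penalty shrinks every coefficient to zero", {
  toy <- make_toy(3)
  lam_max <- max(abs(crossprod(toy$X, toy$y))) / (nrow(toy$X) * 0.1)
  params <- enet_params(alpha = 0.1, lambda = c(lam_max * 1.01, lam_max * 2))
  fit <- fit_enet_path(toy$X, cbind(toy$y), params)
  expect_true(all(fit$beta == 0))
})

test_that("the objective is non-increasing across coordinate-descent sweeps", {
  set.seed(4)
  X <- matrix(rnorm(40 * 25), 40, 25)
  y <- rnorm(40)
  fit <- fit_enet_path(X, cbind(y - mean(y)), enet_params())
  for (objs in fit$objective[[1]]) {
    if (length(objs) > 1) expect_true(all(diff(objs) <= 1e-12))
  }
})

test_that("support at the largest grid penalty is no bigger than at the smallest", {
  set.seed(5)
  X <- scale(matrix(rnorm(60 * 30), 60, 30))
  y <- as.numeric(X[, 1:3] %*% c(1, -1, 0.5) + rnorm(60))
  fit <- fit_enet_path(X, cbind(y - mean(y)), enet_params())
  L <- length(fit$lambda)
  expect_lte(sum(abs(fit$beta[, 1, L]) > 1e-8), sum(abs(fit$beta[, 1, 1]) > 1e-8))
})

test_that("coefficients agree with glmnet at matched parameterization", {
  set.seed(6)
  X <- scale(matrix(rnorm(80 * 12), 80, 12))
  y <- as.numeric(X[, 1:2] %*% c(1.5, -1) + rnorm(80))
  yc <- y - mean(y)
  yc <- yc / sqrt(mean(yc^2))  # unit variance: glmnet's internal response
                               # standardization becomes a no-op
  lam <- 0.05
  ours <- fit_enet_path(X, cbind(yc), enet_params(lambda = c(lam, 1),
                                                  tol = 1e-10, max_sweeps = 50000))
  ref <- glmnet::glmnet(X, yc, alpha = 0.1, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
  expect_equal(as.numeric(ours$beta[, 1, 1]), as.numeric(ref$beta),
               tolerance = 1e-5)
})

test_that("the penalty search is seeded and favors heavy shrinkage on noise", {
  set.seed(7)
  upper_half <- 0L
  for (r in 1:20) {
    set.seed(100 + r)
    X <- matrix(rnorm(60 * 30), 60, 30)
    y <- factor(rep(c("a", "b", "c"), each = 20))
    Y <- gatstack:::one_hot(y)
    cl <- choose_lambda(X, Y, enet_params(), seed = r, y_labels = y)
    if (cl$index > 25) upper_half <- upper_half + 1L
  }
  expect_gte(upper_half, 16)

  set.seed(8)
  X <- matrix(rnorm(45 * 10), 45, 10)
  y <- factor(rep(c("a", "b", "c"), each = 15))
  Y <- gatstack:::one_hot(y)
  c1 <- choose_lambda(X, Y, enet_params(), seed = 3, y_labels = y)
  c2 <- choose_lambda(X, Y, enet_params(), seed = 3, y_labels = y)
  expect_identical(c1, c2)
})

test_that("planted features are recovered and the selection is never empty", {
  set.seed(9)
  hits <- vapply(1:5, function(r) {
    set.seed(200 + r)
    n <- 120
    y <- factor(rep(c("a", "b", "c"), length.out = n))
    X <- matrix(rnorm(n * 40), n, 40,
                dimnames = list(NULL, sprintf("f%02d", 1:40)))
    shift <- cbind(a = c(2, 0, -2, 1, -1), b = c(0, 2, 2, -1, 0),
                   c = c(-2, -2, 0, 0, 1))
    for (j in 1:5) X[, j] <- X[, j] + shift[j, as.character(y)]
    sel <- select_features(X, y, enet_params(), seed = r)
    sum(sprintf("f%02d", 1:5) %in% sel$feature_ids)
  }, numeric(1))
  expect_gte(median(hits), 5)

  # all-noise data: selections stay non-empty and typically tiny (the
  # inner-CV minimum is itself noisy, so the typical -- median -- support
  # is the stable quantity)
  set.seed(10)
  sizes <- vapply(1:10, function(r) {
    set.seed(300 + r)
    X <- matrix(rnorm(210 * 50), 210, 50, dimnames = list(NULL, sprintf("n%02d", 1:50)))
    y <- factor(rep(c("a", "b", "c"), each = 70))
    sel <- select_features(X, y, enet_params(), seed = r)
    expect_gte(length(sel$indices), 1)
    length(sel$indices)
  }, numeric(1))
  expect_lt(median(sizes), 0.1 * 50)
})

test_that("duplicated informative columns are grouped, not both dropped", {
  set.seed(11)
  n <- 90
  y <- factor(rep(c("a", "b", "c"), each = 30))
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, sprintf("f%02d", 1:20)))
  X[, 1] <- X[, 1] + c(2, 0, -2)[as.integer(y)]
  X[, 2] <- X[, 1] + rnorm(n, sd = 1e-3)  # near-duplicate of the signal
  sel <- select_features(X, y, enet_params(), seed = 1)
  expect_true(any(c("f01", "f02") %in% sel$feature_ids))
})

test_that("zero-variance columns are dropped with a message", {
  set.seed(12)
  X <- cbind(const = 1, matrix(rnorm(60 * 5), 60, 5,
                               dimnames = list(NULL, paste0("f", 1:5))))
  y <- factor(rep(c("a", "b", "c"), each = 20))
  X[, "f1"] <- X[, "f1"] + c(3, 0, -3)[as.integer(y)]
  expect_message(sel <- select_features(X, y, enet_params(), seed = 1),
                 "zero-variance")
  expect_false("const" %in% sel$feature_ids)
})
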