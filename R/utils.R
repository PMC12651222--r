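# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded package
#' internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Stratified fold assignment
#'
#' Deals the (shuffled) members of every class round-robin across folds so
#' per-fold class proportions stay within one sample of the global ones.
#'
#' @param y factor of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`, aligned with `y`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  k <- as.integer(k)
  if (k < 2) stopf("need at least 2 folds, got %d", k)
  folds <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      # stagger classes so small classes do not all pile into fold 1
      offset <- offset + length(idx)
    }
  })
  folds
}

# Stratified folds whose training complements are guaranteed to contain
# every class; redraws with a perturbed seed when a class is so small that
# one fold swallowed it entirely.
stratified_folds_complete <- function(y, k, seed = 1L, max_tries = 20L) {
  y <- as.factor(y)
  for (t in seq_len(max_tries)) {
    f <- stratified_folds(y, k, seed + (t - 1L) * 1000L)
    ok <- all(vapply(seq_len(k), function(i) {
      length(unique(y[f != i])) == nlevels(droplevels(y))
    }, logical(1)))
    if (ok) return(f)
  }
  stopf("could not build %d stratified folds with every class in every training complement", k)
}

# Deterministic hash of an R object (via its canonical deparse).
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x, control = c("all", "digits17")), tf)
  unname(tools::md5sum(tf))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
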