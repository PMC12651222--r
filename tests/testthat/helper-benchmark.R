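# Benchmark cohort runs shared by several acceptance checks, computed
# lazily and cached for the session.

.benchmark_cache <- new.env(parent = emptyenv())

benchmark_cv_run <- function(effect, seed, n_repeats = 3L) {
  key <- sprintf("cv_e%s_s%d_r%d", effect, seed, n_repeats)
  if (!is.null(.benchmark_cache[[key]])) return(.benchmark_cache[[key]])
  co <- generate_cohort(simulation_config(effect_size = effect, seed = seed))
  gt <- cohort_gene_table(co)
  net <- cohort_network(co, gt)
  plan <- cv_plan(co$labels, n_folds = 5L, n_repeats = n_repeats, seed = seed)
  cv <- suppressWarnings(suppressMessages(
    run_cv(gt, co$labels, net, config = hybrid_config(gat = gat_benchmark_config(1L)),
           plan = plan, seed = seed)))
  res <- list(cv = cv, truth = co$truth_genes, labels = co$labels,
              summary = summarize_cv(cv$fold_results))
  .benchmark_cache[[key]] <- res
  res
}

benchmark_ranking <- function(run) {
  agg <- aggregate_importances(run$cv$rf_gene_importance, run$cv$attention)
  list(ranking = combine_and_rank(agg$rf, agg$attention, w = 0.5), agg = agg)
}
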