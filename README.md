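# gatstack

Hybrid classification of lower-grade-glioma (LGG) molecular subtypes from
multi-omics data, combining a graph attention network (GAT) over a shared
protein–protein interaction (PPI) topology with a random forest (RF),
stacked by ridge-penalized multinomial logistic regression.

## Who this is for

Computational biologists who want a fully reproducible, leakage-safe
implementation of the PPI-informed hybrid subtype classifier: gene-centric
integration of mRNA, miRNA and DNA-methylation layers; per-patient graphs
on one shared STRING-style network; ElasticNet feature selection and SMOTE
balancing confined to training folds; and an interpretable biomarker
ranking built from attention mass and impurity importance. A synthetic
cohort generator with planted ground truth makes every stage testable
offline.

## The model

Patients are graphs `G = (V, E)`: nodes are genes, edges are PPI
associations with STRING combined score ≥ 400, identical for all patients;
node features are the patient's three omics channels per gene. One
attention head computes

    h'_i   = W h_i
    e_ij   = LeakyReLU(a^T [h'_i || h'_j])          (slope 0.2)
    α_ij   = softmax_{j ∈ N_i}(e_ij)
    h_i^+  = ELU( Σ_{j ∈ N_i} α_ij h'_j )

with K heads concatenated in the hidden layer and averaged in the output
layer; mean-pooled node embeddings map to three subtype logits
(IDHmut-codel, IDHmut-non-codel, IDHwt). The RF arm votes T = 500 trees on
ElasticNet-selected features (objective
`1/(2n)·||y − Xβ||² + λ(α||β||₁ + (1−α)/2·||β||₂²)`, α = 0.1, 50
log-spaced λ in [1e-5, 1]); SMOTE (`x_new = x_i + δ(x_j − x_i)`, k = 5)
equalizes classes inside each training fold. A multinomial
ridge-logistic meta-learner stacks the six out-of-fold base probabilities.
Biomarkers are ranked by the equal-weight mean of min–max-scaled RF
importance and incoming attention mass, annotated per gene with the omic
layer whose one-way ANOVA against subtype has the smallest p-value.

## Worked example

```r
library(gatstack)

co  <- generate_cohort(simulation_config(seed = 11))   # 140 patients, 60/60/20
gt  <- build_gene_table(co$mrna, co$mirna, co$meth,
                        resolve_mirna_targets(co$mirna_map),
                        resolve_cpg_genes(co$cpg_map))
net <- dedupe_and_restrict(co$ppi_edges, gt$genes)

cv <- run_cv(gt, co$labels, net,
             config = hybrid_config(gat = gat_benchmark_config(1)),
             plan = cv_plan(co$labels, n_folds = 5, n_repeats = 3, seed = 11),
             seed = 11)
summarize_cv(cv$fold_results)[, c("model", "accuracy_mean", "f1_mean", "roc_auc_mean")]
#>     model accuracy_mean   f1_mean roc_auc_mean
#> 1     GAT     0.5595238 0.5467583    0.7846065
#> 2      RF     1.0000000 1.0000000    1.0000000
#> 3 stacked     1.0000000 1.0000000    1.0000000

agg <- aggregate_importances(cv$rf_gene_importance, cv$attention)
rk  <- combine_and_rank(agg$rf, agg$attention, w = 0.5)
precision_at_k(rk, co$truth_genes, 20)
#> [1] 1
```

With the default planted effect size (2 within-class SDs on 20 of 200
genes) the stacked model recovers the subtypes essentially perfectly
(mean accuracy 1.0 over 15 folds) and all of the top-20 ranked biomarkers
are planted truth genes; the weaker GAT arm contributes the attention
signal that places the planted hub genes near the top of the ranking.
With `effect_size = 0` the same pipeline sits at chance, which is the
package's null calibration check.

A thin command-line surface wraps the same functions:

```sh
Rscript inst/cli/gatstack.R simulate --out data/ --seed 11
Rscript inst/cli/gatstack.R run --config run.cfg --out results/
```

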