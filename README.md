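# mmpscore

Gene-set consensus subtyping and PC1-difference prognostic scoring for
tumor expression cohorts.

## The problem

A recurring design in cancer transcriptomics takes a curated gene family —
matrix metalloproteinase (MMP) genes in the motivating gastric cancer
setting — and asks whether its expression pattern stratifies patients into
molecular subtypes with different outcomes, and whether those subtypes can
be distilled into a single per-patient risk score that transfers to
independent cohorts. `mmpscore` is a tested, reusable implementation of
that whole chain for anyone who wants to run it on their own cohort or
probe its statistical behaviour on synthetic data:

1. **Consensus clustering** of the cohort over the gene set
   (resampling-based; agglomerative base clusterer on
   1 − Pearson correlation), with the cluster number *K* selected from the
   consensus CDF: with areas *A(K)* under the CDF, the relative gain
   Δ(2) = *A*(2), Δ(K) = (*A(K)* − *A(K−1)*)/*A(K−1)*, and the selected *K*
   is the largest candidate with Δ(K) ≥ 0.1 (the elbow rule).
2. **One-vs-rest moderated-t differential expression** between clusters,
   empirical-Bayes variance shrinkage, BH adjustment; DEGs pass at
   adjusted *p* < 0.05 and |log2FC| > 1.
3. **Signatures A and B**: DEGs positively / negatively Spearman-correlated
   with the prognosis-ordered cluster ordinal (A = up in poor prognosis).
4. **Boruta reduction** of the signatures (shadow features + random forest
   + binomial hit tests) against the cluster label.
5. **Scoring**: per sample, `score = PC1A − PC1B`, the difference of the
   first principal-component scores of the two signatures (PC1 oriented to
   track each signature's mean expression), then a **median split** into
   high/low groups — low score ⇒ better prognosis.
6. **Downstream analysis**: Kaplan–Meier / log-rank / univariate Cox
   survival comparison of the groups, time-dependent IPCW AUC at 12–60
   months, clinicopathological (T/N/M/G/TNM) rank tests, per-gene mutation
   logistic regression and burden comparison, and ridge-regression
   drug-sensitivity (log-IC50) imputation from a reference panel.

External cohorts are scored by **projection with frozen loadings**, never
refit. A synthetic cohort generator with planted subtypes, a latent
prognostic factor, proportional-hazards survival and a mutation layer
provides ground truth for every recovery claim the package makes about
itself.

## Worked example

Generate a planted cohort, write it to disk in the pipeline's input formats
(expression TSV, clinical TSV, MAF, GMT), and run everything end to end:

```r
library(mmpscore)

co <- generate_cohort(cohort_spec(n_samples = 300, seed = 1))
paths <- write_cohort(co, tempfile())

report <- run_pipeline(list(
  expression = paths[["expression"]],
  clinical   = paths[["clinical"]],
  gene_sets  = paths[["gmt"]],
  maf        = paths[["maf"]],
  seed       = 1,
  consensus  = list(k_range = 2:6),
  boruta     = list(max_iter = 40, num_trees = 300)))

report$consensus
#> Consensus clustering over K = 2..6
#>   selected K: 3
#>   cluster sizes: 100/100/100
#>   CDF areas: 2:0.446 3:0.669 4:0.672 5:0.675 6:0.679
report$score_fit
#> PC1-difference score over 30 A + 23 B genes; 300 samples ( 150 high / 150 low )
```

The CDF area jumps from 0.446 to 0.669 going from *K* = 2 to 3 (Δ = 0.50)
and is nearly flat afterwards (Δ ≈ 0.005), so the delta-area rule selects
*K* = 3 — the planted cluster number. Of 105 DEGs between the clusters, 54
land in signature A and 51 in B; Boruta keeps 30 + 23. The score split then
recovers the planted prognostic structure:

```r
signif(report$survival$OS$logrank_p, 3)
#> [1] 3.89e-16                       # low-score group has better OS
unlist(report$survival$OS$auc)
#>   m12   m24   m36   m48   m60
#> 0.781 0.745 0.774 0.786 0.748     # time-dependent IPCW AUC
signif(report$associations$TNM$p, 3)
#> [1] 1.43e-41                       # score rises with TNM stage
signif(report$mutation$burden_p, 3)
#> [1] 1.86e-15                       # burden differs between score groups
```

Project the frozen score onto a second cohort drawn from the same
population:

```r
co2 <- generate_cohort(cohort_spec(n_samples = 300, seed = 2))
proj <- project_scores(co2$expression, report$score_fit)
table(proj$table$group)
```

All module-level functions (`run_consensus()`, `moderated_deg_table()`,
`assign_signatures()`, `boruta_select()`, `fit_scores()`, `km_estimate()`,
`logrank_test()`, `cox_univariate()`, `time_dependent_auc()`,
`rank_test()`, `per_gene_mutation_assoc()`, `ridge_drug_response()`, …)
are exported and documented individually; `vignettes/mmp-scoring-methods.Rmd`
describes the model, conventions and numerical choices in detail.

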