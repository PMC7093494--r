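# lamod — liquid association-based detection of ceRNA modules

Competing endogenous RNAs (ceRNAs) — mRNAs, lncRNAs, pseudogene and
circular transcripts carrying response elements for the same microRNAs —
regulate one another by competing for the microRNAs they share.  Most
computational screens rank candidate pairs by static co-expression (the
Pearson correlation ρ, or the sensitivity correlation
SI = ρ − ρ<sub>partial</sub>) plus a hypergeometric test on the number of
shared microRNAs.  ceRNA kinetics, however, predicts that the *strength*
of the coupling tracks the abundance of the shared microRNAs — a signal
the static correlation ignores.

`lamod` scores that signal with **liquid association** (LA), the mean
derivative of the pairwise correlation with respect to a conditioning
variable.  For standardized expression vectors *X*, *Y* and the
normal-scores transform *W* of the pair's summed shared-microRNA
expression, Stein's lemma gives

LA(X, Y | W) = E[g′(W)] = E[X · Y · W] ≈ (1/N) Σᵢ xᵢ yᵢ wᵢ ,

where g(w) = E[XY | W = w].  The package then detects **ceRNA modules**
by joint factorization of the PCC and LA similarity matrices
(multi-view NMF with a shared consensus factor V*, multiplicative
updates, ℓ₁-normalized basis columns), selects the module count K with
four internal cluster-validity indices (C-index, McClain–Rao,
point-biserial, silhouette) over a K grid, and stabilizes the partition
by CSPA consensus over repeated factorizations with spectral
clustering.  It is intended for systems-biology users working from
RNA-seq + microRNA-seq expression tables and an RNA–microRNA
interaction catalogue.

The package covers, end to end:

* ingestion and filtering of expression TSVs (abundance filters per RNA
  class, log transform, CPM, restriction to interaction-covered
  candidates) — `load_expression()`, `filter_by_abundance()`,
  `restrict_to_candidates()`;
* pair statistics: `pearson()`, `liquid_association()`,
  `sensitivity_correlation()`, `msp_hypergeometric()`,
  `score_all_pairs()`;
* view construction with the joint zeroing rules — `build_views()`;
* factorization and module detection — `mvnmf_factorize()`,
  `select_k()`, `run_pipeline()`;
* module-level evaluation (AUC, fold-change and dysregulation
  entropies, shared validated microRNAs, one-sided KS/Wilcoxon with BH
  correction, CNV/methylation gene filters, hypergeometric module
  enrichment);
* seeded synthetic-data generators with planted ground truth —
  `simulate_cerna_triples()`, `simulate_block_views()`,
  `simulate_dataset()`.

A thin command-line front-end (`inst/cli/lamod`) exposes the pipeline
stages (`simulate`, `score-pairs`, `build-views`, `select-k`,
`factorize`, `run`) for shell use.

## Worked example

Simulate a small dataset with 8 planted ceRNA modules among 80 genes
(300 samples, 40 microRNAs), score all candidate pairs, build the views,
pick K, and detect modules:

```r
library(lamod)

cfg <- simulation_config(n_samples = 300, n_genes = 80, n_mirnas = 40,
                         n_modules = 8, seed = 42)
ds    <- simulate_dataset(cfg)
stats <- score_all_pairs(ds$gene_expr, ds$mic_expr, ds$map)
head(round(stats[, c("pcc", "la", "si", "msp", "q_shared")], 4), 4)
#>      pcc     la si msp q_shared
#> 1 0.9977 0.9590  0   0        6
#> 2 0.9972 0.9592  0   0        6
#> 4 0.9977 0.9621  0   0        6
#> 7 0.9980 0.9594  0   0        6

vs <- build_views(stats, rownames(ds$gene_expr))   # zeroing rules + joint support
k  <- select_k(vs, k_grid = seq(4, 12, 2), seed = 1)
k
#> [1] 8

part <- run_pipeline(vs, k = k, n_repeats = 10, base_seed = 1)
table(part$labels)
#>  1  2  3  4  5  6  7  8
#>  5  7  5  5  7 41  5  5

planted <- names(ds$truth$labels)[ds$truth$labels > 0]
mclust::adjustedRandIndex(part$labels[planted], ds$truth$labels[planted])
#> [1] 1
```

Reading the output: planted pairs are strongly co-expressed
(`pcc ≈ 1`), their coupling strengthens with shared-microRNA abundance
(`la ≈ 0.96`), and their shared-microRNA counts are far beyond chance
(`msp ≈ 0`).  Model selection recovers the planted K = 8, and the
pipeline reconstructs every planted module exactly (adjusted Rand index
1 on the planted genes); the 41-gene cluster collects the background
genes, which have no surviving similarity after the zeroing rules and
are lumped together by design.

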