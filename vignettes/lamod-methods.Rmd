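---
title: "Detecting ceRNA modules with liquid association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ceRNA modules with liquid association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamod)
```

## The biological problem

Competing endogenous RNAs (ceRNAs) are transcripts -- mRNAs, lncRNAs,
pseudogene transcripts, circRNAs -- that carry response elements for the
same microRNAs and therefore titrate each other's effective microRNA
pressure: when one partner is abundant it soaks up shared microRNAs and
de-represses the other.  Classical computational screens score candidate
pairs on two axes: a statistically surprising number of shared microRNAs,
and positive co-expression (Pearson correlation, or the sensitivity
correlation that measures how much of that correlation is mediated by the
shared microRNAs).  Both axes ignore a structural prediction of ceRNA
kinetics: the *strength* of the coupling depends on the abundance of the
shared microRNAs.  Near the optimal microRNA concentration the coupling is
strong; far from it, weak.  A statistic that asks *"does the pairwise
correlation change with the microRNA level?"* therefore carries
information the static correlation cannot.

## Liquid association and its estimator

For standardized expression vectors $X, Y$ of a candidate pair and a
conditioning variable $W$ (here: the summed expression of the pair's
shared microRNAs), write $g(w) = E[XY \mid W = w]$ -- the conditional
co-expression profile.  Liquid association is the mean slope of that
profile,

$$\mathrm{LA}(X, Y \mid W) = E\left[g'(W)\right].$$

When $W \sim N(0, 1)$, Stein's lemma turns the derivative into a plain
moment, $E[g'(W)] = E[XYW]$, estimated by the sample mean of the triple
product,

$$\widehat{\mathrm{LA}} = \frac{1}{N}\sum_{i=1}^N x_i\, y_i\, w_i ,$$

with $x, y$ z-scored and $w$ forced to standard normality by the Van der
Waerden normal-scores transform $w_i \mapsto
\Phi^{-1}\!\left(r_i/(N+1)\right)$, $r_i$ the rank of the raw summed
profile.  Three numerical conventions matter:

* **Population (divisor-$N$) variance** in `zscore()`, so the
  expectation-style identities above hold exactly on the sample; the
  unbiased divisor is available via `sample_var = TRUE`.
* **Midranks for ties** in `van_der_waerden()`.  Counts produce ties; the
  midrank convention keeps the transform mean-zero and is the standard
  normal-scores choice.
* **Conditioning profiles**: LA conditions on the *transformed* profile
  (Stein's lemma demands normality), while the sensitivity correlation
  `si = pcc - partial_correlation` conditions on the *raw* summed
  profile, since the transform is needed only for the Stein identity.
  Both conventions are fixed in `score_pair()`.

The hypergeometric shared-microRNA test (`msp_hypergeometric()`) is the
upper-tail probability of sharing at least $q$ microRNAs given target-set
sizes $T$ and $b$ in a universe of $Q$, delegated to `stats::phyper`; the
test suite certifies it against exhaustive enumeration of all draws for
every feasible configuration with $Q \le 12$.

`simulate_cerna_triples()` provides the calibration instrument: with
$W, S \sim N(0,1)$ and $X = Y = S(1 + \beta W)/\sqrt{1+\beta^2}$ (plus
noise), the pair is co-expressed at every effect size $\beta$, has unit
variance analytically (that is what the $\sqrt{1+\beta^2}$ buys), and has
expected LA $2\beta/(1+\beta^2)$ -- zero exactly when $\beta = 0$.  This
is a test instrument for the estimator, not a kinetic model of microRNA
competition.

## From pair statistics to views

`build_views()` turns scored pairs into the two $G \times G$ similarity
matrices the factorization consumes, applying three rules in order:

1. pairs with shared-microRNA significance `msp >= alpha` (default 0.05)
   have both PCC and LA zeroed;
2. negative PCC or LA values are zeroed (the factorization requires
   non-negative input);
3. entries where *either* value is zero are zeroed in *both* matrices --
   a ceRNA pair must be jointly co-expressed and microRNA-sensitive, so
   the two views share a common support.

Unscored pairs and the diagonal are structural zeros; a gene is not its
own ceRNA partner, and a free diagonal would only reward trivial
self-similarity in the factorization.  The comparison in rule 1 is
`>=` exactly: significant pairs sit strictly below the threshold.

## Multi-view non-negative matrix factorization

With views $M^{pcc}, M^{la}$, per-view factors $U^v, V^v \ge 0$ and a
consensus factor $V^*$, the objective is

$$\sum_{v} \left\|M^v - U^v (V^v)^T\right\|_F^2
  + \sum_v \lambda_v \left\|V^v - V^*\right\|_F^2,
  \qquad \|U^v_{\cdot,k}\|_1 = 1 \;\forall k,$$

minimized by cyclic multiplicative updates: U updates (both views), the
normalization $U \leftarrow U Q^{-1}$, $V \leftarrow V Q$ with
$Q = \mathrm{Diag}(\text{colSums}\, U)$, V updates, and the closed-form
consensus update $V^* = (\lambda_{pcc} V^{pcc} Q^{pcc} + \lambda_{la}
V^{la} Q^{la}) / (\lambda_{pcc} + \lambda_{la})$.  The unit-column
constraint is folded into the coupling terms through $Q$, which makes
every sub-step non-increasing; because each outer iteration ends with
column sums equal to one, the plain objective recorded in
`objective_trace` coincides with the constraint-folded one, and the trace
is monotone.  Numerical choices:

* **Initialization**: factors drawn uniformly from $(0, 1]$ and scaled by
  $\sqrt{\overline{M}/K}$ so the initial reconstruction has the right
  magnitude; $U$ is column-normalized immediately (compensated in $V$) so
  the recorded objective is on the constraint surface from iteration 0.
  Repeat $r$ of the pipeline uses seed `base_seed + r`.
* **Epsilon guard** of $10^{-10}$ in every multiplicative denominator.
* **Convergence** on the relative objective decrease (default
  `tol = 1e-6`, `max_iter = 500`).  Multiplicative updates have a slow
  tail; runs that must drive an exactly low-rank input to near-zero
  residual need a few thousand iterations, which is why `select_k()`
  defaults to a larger budget (`max_iter = 1000`, `tol = 1e-7`) -- an
  under-converged factorization at the true $K$ is the main failure mode
  of model selection.
* **Degenerate rows**: genes isolated in both views keep all-zero factor
  rows; `assign_modules()` sends them to module 1 with a warning naming
  them, and breaks argmax ties toward the lowest module index.

`factorize_single()` provides the standard one-matrix NMF used as the
PCC-only / SI-only baseline.

## Choosing K and stabilizing modules

`select_k()` runs one factorization per candidate $K$, assigns modules
from $V^*$, and scores the partition against each view with four internal
validity indices (C-index, McClain-Rao, point-biserial, silhouette).  Two
conventions are deliberate, since "evaluate the clustering on both
matrices" admits several readings:

* the views are similarities, so indices are computed on the
  dissimilarity $d = 1 - m/\max(m)$ (a Euclidean row-distance alternative
  sits behind the `dissimilarity` argument);
* "simultaneously considering" the $4 \times 2$ index series is
  formalized as mean-rank aggregation -- each series ranks the candidate
  Ks (lower-better for C-index and McClain-Rao, higher-better for the
  other two, degenerate evaluations ranked last), and the best mean rank
  wins, ties toward smaller $K$.  One partition (from $V^*$) is
  evaluated against both matrices.

The final partition comes from consensus: `run_pipeline()` repeats the
factorization (default 10 times, distinct seeds), sums the binary
co-membership matrices (CSPA, `cspa_consensus()`), and re-clusters the
consensus with normalized spectral clustering
(`spectral_partition()`): symmetric normalized Laplacian, top-$K$
eigenvector embedding, row normalization, k-means.  The k-means centers
are seeded with a deterministic farthest-point (maximin) sweep in
addition to seeded random restarts, the lower within-SS solution
winning.  This is a deliberate design choice: with many tight,
near-orthogonal clusters in the embedding, a random draw of $K$ rows
almost never covers every cluster (for $K = 20$ equal blocks the
covering probability is $20!/20^{20} \approx 2\times10^{-8}$), and the
consensus stage would otherwise be *less* accurate than the single runs
it aggregates.

## Module-level evaluation

The evaluation helpers quantify the biological coherence a ceRNA module
should show: homogeneous disease response and heavy microRNA sharing.

* `module_fold_change_entropy()` bins per-gene log fold changes into
  $\lceil\sqrt{n}\rceil$ equal-width bins over their observed range and
  returns the entropy of the bin frequencies (bits).  The binning rule is
  a documented package choice; any fixed rule comparable across methods
  serves.
* `module_dysregulation_entropies()` returns the binary entropy of the
  dysregulated fraction and the entropy of the up/down/none fractions.
* `avg_shared_validated_mirnas()` averages validated shared-microRNA
  counts over within-module pairs (singleton modules yield `NA`).
* `compare_module_metrics()` wraps the one-sided two-sample KS and
  Wilcoxon (normal approximation) tests.  The direction is a required
  argument phrased in terms of the first sample's values ("less" = the
  first method yields smaller values); internally the KS alternative is
  flipped to match R's convention.  `bh_fdr()` applies Benjamini-
  Hochberg.
* Gene filters for disease association: DE flags from supplied per-gene
  logFC/FDR tables at the standard FDR < 0.05, |logFC| > 1 thresholds
  (the DE fit itself -- edgeR/limma territory -- is out of scope and
  ingested as a table); CNV genes off-diploid in strictly more than 5%
  of samples; differentially methylated genes with at least two
  significant sites (FDR < 0.05, |mean difference| > 0.2) within 2 kb of
  the gene start, strictly more than three quarters sharing a direction,
  hypermethylation meaning positive disease-minus-normal difference.
  Coordinates are 1-based, the window symmetric and strand-agnostic.
  `module_enrichment()` reuses the hypergeometric tail.

AUC comparisons (`auc_rank()`) use the Mann-Whitney formulation with
ties counted one half; rankings use *signed* LA by default -- the
absolute value is a caller-side transform -- since a ceRNA pair is
expected to strengthen, not merely change, with microRNA abundance.

## What the synthetic benchmarks do and do not show

`simulate_block_views()` plants equal-size modules in both views
(within-module similarity 0.8, background 0.05, truncated Gaussian noise
of sd 0.05 by default) and `simulate_dataset()` generates a full input
set -- module-mates share a drawn microRNA set and follow the triple
model against its summed expression; background genes get independent
expression and sparse random targets.  These defaults are the study
conditions for all recovery and discrimination tests; the suite runs
them at $G = 200$ genes, $K = 20$ modules, 500 samples (10 000 samples
and 20 replicates for the Stein calibration; a $G = 100$, $K = 5$ grid
for model selection).

What passing these benchmarks shows: the estimator is consistent and
null-calibrated, the updates are monotone, planted structure at
realistic contrast is recovered exactly, and model selection finds a
well-separated true $K$.  What it does not show: performance on real
tumor expression, where modules are unequal, overlapping and weaker,
library-size and batch effects distort correlations (not simulated), the
microRNA-dependence of coupling is not linear, and the microRNA universe
is orders of magnitude larger.  A near-optimal microRNA regime can also
produce coupling that *peaks* rather than grows in $W$, making expected
LA near zero by symmetry -- a known limitation of the signed mean-slope
statistic.

## Other fixed conventions

* Abundance filters keep a row when its abundance exceeds the class
  threshold (mRNA 1, lncRNA 0.8 in FPKM; microRNA 100 in CPM) in
  strictly more than the class fraction (80% / 50% / 50%) of disease
  *or* normal samples; both inequalities strict, groups supplied as a
  two-column annotation table.  Logs are natural (`log(x + 1)`), base
  configurable.
* Disease and normal samples are not pooled or split implicitly:
  correlations are computed on whatever sample set the caller passes,
  so state-specific module sets come from state-specific inputs.
* All generators, factorizations and the pipeline are deterministic
  given their seed arguments.
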