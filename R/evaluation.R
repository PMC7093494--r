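#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen positive pair outscores a randomly
#' chosen negative pair, with ties counted one half.  Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) class labels, parallel to `scores`.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Shannon entropy of a discrete distribution (bits)
#'
#' `-sum(p * log2(p))` with the convention `0 * log(0) = 0`.
#'
#' @param proportions Non-negative vector summing to 1 (tolerance 1e-9).
#' @return Entropy in bits.
#' @export
categorical_entropy <- function(proportions) {
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be non-negative and sum to 1")
  p <- proportions[proportions > 0]
  -sum(p * log2(p))
}

#' Fold-change entropy of a module
#'
#' Tight ceRNA modules should have homogeneous disease-vs-normal fold
#' changes, hence low entropy.  Per-gene log fold changes are discretized
#' into `ceiling(sqrt(n))` equal-width bins over their observed range and
#' the entropy of the bin frequencies is returned.  A module whose genes
#' all share one value has entropy 0.
#'
#' @param log_fold_change Numeric vector of per-gene log fold changes
#'   (one module).
#' @param n_bins Optional bin-count override.
#' @return Entropy in bits.
#' @export
module_fold_change_entropy <- function(log_fold_change, n_bins = NULL) {
  n <- length(log_fold_change)
  if (n == 0L) stop("module is empty")
  rng <- range(log_fold_change)
  if (diff(rng) == 0) return(0)
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(n))
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- table(cut(log_fold_change, breaks, include.lowest = TRUE))
  categorical_entropy(as.numeric(counts) / n)
}

#' Dysregulation entropies of a module
#'
#' Two measures of how uniformly a module responds to disease: the binary
#' entropy of the dysregulated-gene fraction (direction ignored) and the
#' entropy of the up/down/none direction fractions.
#'
#' @param de_flag Logical vector: is each gene differentially expressed.
#' @param de_direction Character vector in `{"up", "down", "none"}`,
#'   consistent with `de_flag` (`none` iff not flagged).
#' @return Named numeric vector `c(dysregulated = ..., direction = ...)`,
#'   both in bits.
#' @export
module_dysregulation_entropies <- function(de_flag, de_direction) {
  if (length(de_flag) == 0L) stop("module is empty")
  if (length(de_flag) != length(de_direction))
    stop("de_flag and de_direction must have equal length")
  if (!all(de_direction %in% c("up", "down", "none")))
    stop("de_direction values must be 'up', 'down' or 'none'")
  if (any(de_flag != (de_direction != "none")))
    stop("de_flag must be TRUE exactly when de_direction is not 'none'")
  p <- mean(de_flag)
  e1 <- categorical_entropy(c(p, 1 - p))
  frac <- as.numeric(table(factor(de_direction,
                                  levels = c("up", "down", "none"))))
  e2 <- categorical_entropy(frac / length(de_direction))
  c(dysregulated = e1, direction = e2)
}

#' Derive differential-expression annotations from summary statistics
#'
#' Applies the standard calling thresholds (FDR < 0.05 and |logFC| > 1 by
#' default) to a table of per-gene fold changes and adjusted p-values, as
#' produced by count-based DE tools.
#'
#' @param tbl data.frame with columns `gene_id`, `log_fold_change`,
#'   `fdr`.
#' @param fdr_cut,lfc_cut Calling thresholds.
#' @return data.frame with columns `gene_id`, `log_fold_change`,
#'   `de_flag`, `de_direction`.
#' @export
derive_de_annotation <- function(tbl, fdr_cut = 0.05, lfc_cut = 1) {
  stopifnot(all(c("gene_id", "log_fold_change", "fdr") %in% colnames(tbl)))
  flag <- tbl$fdr < fdr_cut & abs(tbl$log_fold_change) > lfc_cut
  dir <- ifelse(!flag, "none", ifelse(tbl$log_fold_change > 0, "up", "down"))
  data.frame(gene_id = tbl$gene_id,
             log_fold_change = tbl$log_fold_change,
             de_flag = flag, de_direction = dir,
             stringsAsFactors = FALSE)
}

#' Average shared validated microRNAs per within-module pair
#'
#' Mean, over all unordered pairs of module genes, of the number of
#' validated microRNA interactors the pair shares.  Genes without
#' validated targets contribute empty sets.
#'
#' @param genes Character vector of module gene ids (length >= 2 for a
#'   defined value).
#' @param validated_map A `target_map` of validated interactions.
#' @return Mean shared count, or `NA_real_` for a singleton module.
#' @export
avg_shared_validated_mirnas <- function(genes, validated_map) {
  stopifnot(inherits(validated_map, "target_map"))
  if (length(genes) < 2L) return(NA_real_)
  sets <- lapply(genes, function(g) {
    s <- validated_map$targets[[g]]
    if (is.null(s)) character(0) else s
  })
  pr <- utils::combn(length(genes), 2L)
  mean(vapply(seq_len(ncol(pr)), function(j)
    length(intersect(sets[[pr[1L, j]]], sets[[pr[2L, j]]])),
    numeric(1)))
}

#' One-sided two-sample comparison of module metrics
#'
#' Compares two vectors of per-module metric values with a one-tailed
#' two-sample Kolmogorov-Smirnov test or Wilcoxon rank-sum test (normal
#' approximation).  `alternative = "less"` tests whether the values in
#' `values_a` tend to be smaller than those in `values_b` (the usual
#' "method A yields lower entropies" hypothesis); `"greater"` the
#' reverse.  The direction must be stated explicitly.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param test `"ks"` or `"wilcoxon"`.
#' @param alternative `"less"` or `"greater"`, phrased in terms of the
#'   values of `values_a`.
#' @return The p-value.
#' @export
compare_module_metrics <- function(values_a, values_b,
                                   test = c("ks", "wilcoxon"),
                                   alternative) {
  test <- match.arg(test)
  alternative <- match.arg(alternative, c("less", "greater"))
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("empty sample")
  if (test == "ks") {
    # ks.test's "greater" alternative corresponds to x stochastically
    # smaller than y, so the direction flips
    alt <- if (alternative == "less") "greater" else "less"
    suppressWarnings(stats::ks.test(values_a, values_b,
                                    alternative = alt)$p.value)
  } else {
    suppressWarnings(stats::wilcox.test(values_a, values_b,
                                        alternative = alternative,
                                        exact = FALSE)$p.value)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, preserving input order.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Flag copy-number-variable genes
#'
#' A gene is flagged when its copy level differs from the diploid 2 in
#' strictly more than `fraction` of samples.
#'
#' @param cnv Integer gene x sample matrix of copy levels.
#' @param fraction Sample-fraction threshold (default 0.05).
#' @return Character vector of flagged gene ids.
#' @export
cnv_gene_filter <- function(cnv, fraction = 0.05) {
  stopifnot(is.matrix(cnv))
  rownames(cnv)[rowMeans(cnv != 2) > fraction]
}

#' Flag differentially methylated genes from site-level statistics
#'
#' Sites with `fdr < fdr_cut` and `|mean_diff| > diff_cut` are
#' differentially methylated sites (DMS); each DMS is mapped to every
#' gene whose annotated start lies within `window` bp (symmetric,
#' 1-based inclusive).  A gene is flagged when it has at least two mapped
#' DMS and strictly more than `frac_same` of them share the direction of
#' change (hypermethylation = positive `mean_diff`, disease minus
#' normal).
#'
#' @param sites data.frame with columns `position`, `fdr`, `mean_diff`.
#' @param genes data.frame with columns `gene_id`, `start`.
#' @param window Half-width of the mapping window in bp (default 2000).
#' @param frac_same Same-direction fraction threshold (default 0.75).
#' @param fdr_cut,diff_cut DMS calling thresholds (defaults 0.05, 0.2).
#' @return Character vector of flagged gene ids.
#' @export
dms_gene_filter <- function(sites, genes, window = 2000,
                            frac_same = 0.75, fdr_cut = 0.05,
                            diff_cut = 0.2) {
  stopifnot(all(c("position", "fdr", "mean_diff") %in% colnames(sites)),
            all(c("gene_id", "start") %in% colnames(genes)))
  dms <- sites[sites$fdr < fdr_cut & abs(sites$mean_diff) > diff_cut, ,
               drop = FALSE]
  flagged <- character(0)
  for (i in seq_len(nrow(genes))) {
    near <- dms[abs(dms$position - genes$start[i]) <= window, ,
                drop = FALSE]
    if (nrow(near) < 2L) next
    up <- mean(near$mean_diff > 0)
    if (max(up, 1 - up) > frac_same)
      flagged <- c(flagged, genes$gene_id[i])
  }
  flagged
}

#' Hypergeometric enrichment of a module in a flagged gene set
#'
#' Upper-tail probability of observing at least the module's overlap with
#' the flagged set under random draws from the universe; the same
#' statistic as the shared-microRNA MS-P.
#'
#' @param module_genes Character vector, a subset of `universe`.
#' @param flagged Character vector of flagged genes (intersected with the
#'   universe).
#' @param universe Character vector of all genes under consideration.
#' @return Enrichment p-value in (0, 1\].
#' @export
module_enrichment <- function(module_genes, flagged, universe) {
  if (!all(module_genes %in% universe))
    stop("module genes outside the universe: ",
         paste(setdiff(module_genes, universe), collapse = ", "))
  flagged <- intersect(flagged, universe)
  msp_hypergeometric(T = length(flagged),
                     b = length(module_genes),
                     q = length(intersect(module_genes, flagged)),
                     Q = length(universe))
}
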