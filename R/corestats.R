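#' Z-score a vector
#'
#' Centers to mean zero and scales to unit variance.  The default divisor is
#' N (population variance), so that expectation-style estimators such as the
#' simplified liquid-association formula are exact sample identities.
#'
#' @param x Numeric vector, length >= 2, not constant.
#' @param sample_var Use the unbiased N-1 divisor instead.
#' @return Standardized vector of the same length.
#' @export
zscore <- function(x, sample_var = FALSE) {
  if (length(x) < 2L) stop("zscore requires length >= 2")
  m <- mean(x)
  v <- if (sample_var) sum((x - m)^2) / (length(x) - 1L)
       else mean((x - m)^2)
  if (v == 0) stop("zscore undefined for a constant vector")
  (x - m) / sqrt(v)
}

#' Pearson correlation via standardized products
#'
#' Computed as the mean of the elementwise product of the population
#' z-scores of `x` and `y`, the estimator form used throughout the pair
#' scoring.  Equal to the textbook covariance formula.
#'
#' @param x,y Numeric vectors of equal length >= 2, neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  mean(zscore(x) * zscore(y))
}

#' Van der Waerden normal-scores transform
#'
#' Replaces each value by the standard-normal quantile of its rank:
#' element i becomes `qnorm(r_i / (N + 1))`.  Ties receive midranks, which
#' preserves the mean-zero rank symmetry.  The output of this transform is
#' approximately standard normal whatever the input distribution, which is
#' the condition under which Stein's lemma reduces liquid association to a
#' mean triple product.
#'
#' @param w Numeric vector, length >= 2.
#' @return Transformed vector.
#' @export
van_der_waerden <- function(w) {
  n <- length(w)
  if (n < 2L) stop("van_der_waerden requires length >= 2")
  stats::qnorm(rank(w, ties.method = "average") / (n + 1))
}

#' Shared-microRNA expression profile of a candidate pair
#'
#' For a candidate ceRNA pair the conditioning variable is the per-sample
#' sum of the expression of all microRNAs the two RNAs share.  The raw sum
#' is kept (used by the sensitivity correlation) together with its Van der
#' Waerden transform (used by liquid association).
#'
#' @param rna1,rna2 RNA identifiers present in `map`.
#' @param map A `target_map`.
#' @param mic_expr MicroRNA expression matrix (rows = microRNAs), normally
#'   log-transformed.
#' @return Object of class `shared_profile` with fields `pair`,
#'   `shared_mirnas`, `raw_sum`, `transformed`.
#' @export
shared_profile <- function(rna1, rna2, map, mic_expr) {
  stopifnot(inherits(map, "target_map"))
  for (r in c(rna1, rna2))
    if (is.null(map$targets[[r]]))
      stop("RNA '", r, "' has no entry in the target map")
  shared <- intersect(map$targets[[rna1]], map$targets[[rna2]])
  if (length(shared) == 0L)
    stop("not a candidate pair: '", rna1, "' and '", rna2,
         "' share no microRNA")
  missing <- setdiff(shared, rownames(mic_expr))
  if (length(missing) > 0L)
    stop("shared microRNA(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  raw_sum <- colSums(mic_expr[shared, , drop = FALSE])
  structure(list(pair = sort(c(rna1, rna2)),
                 shared_mirnas = shared,
                 raw_sum = raw_sum,
                 transformed = van_der_waerden(raw_sum)),
            class = "shared_profile")
}

#' Liquid association of two expression vectors
#'
#' Liquid association (LA) measures how the correlation of `x` and `y`
#' changes with a third variable `w`: LA = E\[g'(W)\] where g(w) =
#' E\[XY | W = w\].  When W is standard normal, Stein's lemma gives
#' LA = E\[X Y W\], estimated here as the mean of the elementwise triple
#' product of the z-scores of `x` and `y` with the normal-scores transform
#' of `w`.
#'
#' @param x,y Numeric vectors of equal length, neither constant.
#' @param w Either a [shared_profile()] (its `transformed` field is used)
#'   or a numeric vector.
#' @param transform When `w` is a numeric vector, apply
#'   [van_der_waerden()] first (default `TRUE`).  Ignored for
#'   `shared_profile` input.
#' @return The LA estimate (unbounded real; positive when the pair's
#'   co-expression strengthens with `w`).
#' @export
liquid_association <- function(x, y, w, transform = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  wt <- if (inherits(w, "shared_profile")) w$transformed
        else if (transform) van_der_waerden(w)
        else w
  if (length(wt) != length(x))
    stop("conditioning profile length does not match x and y")
  mean(zscore(x) * zscore(y) * wt)
}

#' Partial correlation given a conditioning vector
#'
#' First-order partial correlation of `x` and `y` given `w`:
#' (rho_xy - rho_xw rho_yw) / sqrt((1 - rho_xw^2)(1 - rho_yw^2)).
#'
#' @param x,y,w Numeric vectors of equal length.
#' @return Partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, w) {
  rxy <- pearson(x, y)
  rxw <- pearson(x, w)
  ryw <- pearson(y, w)
  den <- sqrt(1 - rxw^2) * sqrt(1 - ryw^2)
  if (den == 0)
    stop("partial correlation undefined: |cor(x,w)| or |cor(y,w)| is 1")
  (rxy - rxw * ryw) / den
}

#' Sensitivity correlation (SI)
#'
#' SI = rho(x, y) - rho(x, y | w): the drop in correlation after
#' conditioning on the shared-microRNA profile.  Large SI means the
#' co-expression is largely mediated by the conditioning variable.
#'
#' @inheritParams partial_correlation
#' @return SI value.
#' @export
sensitivity_correlation <- function(x, y, w) {
  pearson(x, y) - partial_correlation(x, y, w)
}

#' Hypergeometric significance of shared microRNAs (MS-P)
#'
#' Upper-tail probability that two RNAs targeting `T` and `b` microRNAs out
#' of a universe of `Q` share at least `q` of them by chance:
#' p = 1 - sum_(i=0)^(q-1) C(T,i) C(Q-T,b-i) / C(Q,b).
#'
#' @param T,b Target-set sizes of the two RNAs.
#' @param q Observed shared count.
#' @param Q Universe size.
#' @return p-value in (0, 1\]; `q = 0` gives exactly 1.
#' @export
msp_hypergeometric <- function(T, b, q, Q) {
  if (any(c(T, b, q, Q) < 0) || T > Q || b > Q || q > min(T, b))
    stop("infeasible hypergeometric arguments: need 0 <= q <= min(T,b) <= Q")
  stats::phyper(q - 1, m = T, n = Q - T, k = b, lower.tail = FALSE)
}

#' Score a single candidate ceRNA pair
#'
#' Computes all pair statistics: Pearson correlation of the two expression
#' rows, liquid association with respect to the transformed shared-microRNA
#' sum, sensitivity correlation with respect to the raw sum, the
#' hypergeometric MS-P, and the shared-microRNA count.
#'
#' @param rna1,rna2 Gene identifiers (rows of `gene_expr`, entries of
#'   `map`).
#' @param gene_expr Gene expression matrix (log scale).
#' @param mic_expr MicroRNA expression matrix (log scale).
#' @param map A `target_map`.
#' @param profile Optionally a precomputed [shared_profile()] for the pair.
#' @return One-row data.frame with columns `rna1`, `rna2`, `pcc`, `la`,
#'   `si`, `msp`, `q_shared` (pair in lexicographic order).
#' @export
score_pair <- function(rna1, rna2, gene_expr, mic_expr, map,
                       profile = NULL) {
  for (r in c(rna1, rna2))
    if (!r %in% rownames(gene_expr))
      stop("gene '", r, "' absent from expression matrix")
  if (is.null(profile))
    profile <- shared_profile(rna1, rna2, map, mic_expr)
  x <- gene_expr[rna1, ]
  y <- gene_expr[rna2, ]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant expression row for '",
         if (stats::var(x) == 0) rna1 else rna2, "'")
  uni <- map$universe
  pair <- sort(c(rna1, rna2))
  data.frame(
    rna1 = pair[1L], rna2 = pair[2L],
    pcc = pearson(x, y),
    la = liquid_association(x, y, profile),
    si = sensitivity_correlation(x, y, profile$raw_sum),
    msp = msp_hypergeometric(T = length(map$targets[[rna1]]),
                             b = length(map$targets[[rna2]]),
                             q = length(profile$shared_mirnas),
                             Q = length(uni)),
    q_shared = length(profile$shared_mirnas),
    stringsAsFactors = FALSE)
}

#' Score all candidate pairs
#'
#' Candidate pairs are unordered pairs of genes present in both the
#' expression matrix and the target map that share at least one microRNA.
#' Shared-profile transforms are cached per distinct shared-microRNA set,
#' which collapses the dominant cost when many pairs share the same
#' conditioning set.
#'
#' @inheritParams score_pair
#' @param pairs Optional two-column matrix/data.frame of pairs to score;
#'   default is all candidate pairs.
#' @return data.frame of [score_pair()] rows, sorted lexicographically by
#'   (`rna1`, `rna2`).
#' @export
score_all_pairs <- function(gene_expr, mic_expr, map, pairs = NULL) {
  genes <- intersect(rownames(gene_expr), names(map$targets))
  if (length(genes) < 2L)
    stop("fewer than two genes shared between expression and target map")
  if (is.null(pairs)) {
    genes <- sort(genes)
    # incidence screen for q_shared >= 1
    inc <- vapply(map$targets[genes],
                  function(s) map$universe %in% s,
                  logical(length(map$universe)))
    share <- crossprod(inc * 1)
    idx <- which(upper.tri(share) & share >= 1, arr.ind = TRUE)
    pairs <- cbind(genes[idx[, 1L]], genes[idx[, 2L]])
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no candidate pairs (no shared microRNAs)")
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r1 <- pairs[i, 1L]; r2 <- pairs[i, 2L]
    shared <- intersect(map$targets[[r1]], map$targets[[r2]])
    key <- paste(sort(shared), collapse = "\r")
    prof <- cache[[key]]
    if (is.null(prof)) {
      prof <- shared_profile(r1, r2, map, mic_expr)
      cache[[key]] <- prof
    }
    rows[[i]] <- score_pair(r1, r2, gene_expr, mic_expr, map,
                            profile = prof)
  }
  out <- do.call(rbind, rows)
  out[order(out$rna1, out$rna2), , drop = FALSE]
}
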