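#' Internal cluster-validity indices of a partition on a similarity matrix
#'
#' Evaluates a gene partition against one view matrix using four internal
#' indices.  The view is a similarity, so pairwise dissimilarities are
#' taken as `d = 1 - m / max(m)` (a row-vector Euclidean alternative is
#' available).  With `S_w` the sum of within-cluster pair distances over
#' `n_w` pairs and `S_min`/`S_max` the sums of the `n_w` smallest/largest
#' distances overall:
#' \itemize{
#'   \item C-index `(S_w - S_min) / (S_max - S_min)` (lower is better);
#'   \item McClain-Rao: mean within-pair distance / mean between-pair
#'     distance (lower is better);
#'   \item point-biserial: Pearson correlation between the pair distance
#'     and the within(0)/between(1) indicator (higher is better);
#'   \item silhouette: mean over genes of `(b - a) / max(a, b)` (higher is
#'     better; singletons contribute 0).
#' }
#'
#' @param m Symmetric non-negative similarity matrix.
#' @param partition A `module_partition` or a label vector over the rows
#'   of `m`.
#' @param dissimilarity `"similarity"` (default, `1 - m/max(m)`) or
#'   `"euclidean"` (distances between the rows of `m`).
#' @return List with `c_index`, `mcclain_rao`, `point_biserial`,
#'   `silhouette`.
#' @export
validity_indices <- function(m, partition,
                             dissimilarity = c("similarity", "euclidean")) {
  dissimilarity <- match.arg(dissimilarity)
  labels <- if (inherits(partition, "module_partition"))
    partition$labels else partition
  g <- nrow(m)
  if (length(labels) != g)
    stop("partition must label every row of m")
  if (length(unique(labels)) < 2L)
    stop("validity indices require at least two clusters")
  d <- if (dissimilarity == "similarity") {
    mx <- max(m)
    if (mx <= 0) stop("similarity matrix has no positive entries")
    1 - m / mx
  } else {
    as.matrix(stats::dist(m))
  }
  diag(d) <- 0
  ut <- upper.tri(d)
  dv <- d[ut]
  same <- outer(labels, labels, "==")[ut]
  n_w <- sum(same)
  n_b <- sum(!same)
  if (n_w == 0L || n_b == 0L)
    stop("partition yields no within- or no between-cluster pairs")
  s_w <- sum(dv[same])
  s_b <- sum(dv[!same])
  sorted <- sort(dv)
  s_min <- sum(sorted[seq_len(n_w)])
  s_max <- sum(sorted[seq.int(length(sorted) - n_w + 1L, length(sorted))])
  c_index <- if (s_max > s_min) (s_w - s_min) / (s_max - s_min) else 0
  mcclain <- (s_w / n_w) / (s_b / n_b)
  pb <- stats::cor(dv, as.numeric(!same))
  list(c_index = c_index,
       mcclain_rao = mcclain,
       point_biserial = pb,
       silhouette = .mean_silhouette(d, labels))
}

.mean_silhouette <- function(d, labels) {
  cl <- sort(unique(labels))
  sizes <- as.numeric(table(factor(labels, levels = cl)))
  ind <- outer(labels, cl, "==") * 1            # G x C membership
  sums <- d %*% ind                             # total distance to cluster
  own <- match(labels, cl)
  g <- length(labels)
  s <- numeric(g)
  for (i in seq_len(g)) {
    ni <- sizes[own[i]]
    if (ni <= 1) { s[i] <- 0; next }            # singleton convention
    a <- sums[i, own[i]] / (ni - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    mx <- max(a, b)
    s[i] <- if (mx > 0) (b - a) / mx else 0
  }
  mean(s)
}

#' Select the number of modules K over a grid
#'
#' For each candidate K a single multi-view factorization is run, modules
#' are assigned from its consensus factor, and the four validity indices
#' are computed against each of the two view matrices (8 series).  Each
#' series ranks the candidate Ks (lower-better for C-index and
#' McClain-Rao, higher-better for point-biserial and silhouette; failed or
#' degenerate evaluations rank last), and the K with the best mean rank
#' wins; ties go to the smaller K.
#'
#' @param views A `view_set`.
#' @param k_grid Integer vector of candidate K values (default
#'   `seq(10, 400, by = 10)`).
#' @param seed Integer seed; the run for the i-th grid value uses
#'   `seed + i`.
#' @param lambda_pcc,lambda_la,max_iter,tol Passed to
#'   [mvnmf_factorize()].
#' @param report Return the per-K index table alongside the choice.
#' @return The selected K (integer), or when `report = TRUE` a list with
#'   `k` and a data.frame `report` of the 8 index values and the mean rank
#'   per candidate.
#' @export
select_k <- function(views, k_grid = seq(10, 400, by = 10), seed = 1,
                     lambda_pcc = 1, lambda_la = 1, max_iter = 1000,
                     tol = 1e-7, report = FALSE) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0L) stop("k_grid is empty")
  if (any(k_grid > length(views$gene_ids)))
    stop("k_grid contains values larger than the number of genes")
  idx_names <- c("c_index", "mcclain_rao", "point_biserial", "silhouette")
  lower_better <- c(TRUE, TRUE, FALSE, FALSE)
  tab <- matrix(NA_real_, length(k_grid), 8L,
                dimnames = list(NULL, paste(rep(idx_names, 2L),
                                            rep(c("pcc", "la"), each = 4L),
                                            sep = ".")))
  for (i in seq_along(k_grid)) {
    fit <- mvnmf_factorize(views, k_grid[i], lambda_pcc, lambda_la,
                           seed = seed + i, max_iter = max_iter, tol = tol)
    part <- suppressWarnings(assign_modules(fit))
    for (v in 1:2) {
      m <- if (v == 1L) views$m_pcc else views$m_la
      vals <- tryCatch(validity_indices(m, part),
                       error = function(e) NULL)
      if (!is.null(vals))
        tab[i, (v - 1L) * 4L + 1:4] <- unlist(vals)[idx_names]
    }
  }
  ranks <- vapply(seq_len(8L), function(col) {
    x <- tab[, col]
    if (!lower_better[(col - 1L) %% 4L + 1L]) x <- -x
    x[!is.finite(x)] <- Inf
    rank(x, ties.method = "average")
  }, numeric(length(k_grid)))
  mean_rank <- rowMeans(matrix(ranks, nrow = length(k_grid)))
  best <- min(k_grid[mean_rank == min(mean_rank)])
  if (!report) return(best)
  list(k = best,
       report = data.frame(k = k_grid, tab, mean_rank = mean_rank))
}

#' CSPA consensus matrix over repeated partitions
#'
#' Cluster-based similarity partitioning: each run contributes a binary
#' co-membership matrix (1 when two genes share a module); the consensus
#' matrix is their sum.
#'
#' @param runs List of `module_partition` objects (or named label
#'   vectors) over an identical gene set.
#' @return Object of class `consensus_matrix`: list with `gene_ids`,
#'   `counts` (G x G integer matrix), `n_runs`.
#' @export
cspa_consensus <- function(runs) {
  if (length(runs) < 1L) stop("need at least one partition")
  labs <- lapply(runs, function(r)
    if (inherits(r, "module_partition")) r$labels else r)
  ids <- names(labs[[1L]])
  if (is.null(ids)) stop("partitions must carry gene names")
  for (l in labs)
    if (!identical(sort(names(l)), sort(ids)))
      stop("partitions are over different gene sets")
  counts <- Reduce(`+`, lapply(labs, function(l) {
    l <- l[ids]
    outer(l, l, "==") * 1L
  }))
  cm <- structure(list(gene_ids = ids, counts = counts,
                       n_runs = length(runs)),
                  class = "consensus_matrix")
  validate_consensus(cm)
  cm
}

#' Assert the consensus-matrix invariants
#'
#' Symmetry, counts within \[0, n_runs\], and a diagonal equal to
#' `n_runs`.
#'
#' @param cm A `consensus_matrix`.
#' @return `cm`, invisibly; errors on violation.
#' @export
validate_consensus <- function(cm) {
  stopifnot(inherits(cm, "consensus_matrix"))
  if (!isSymmetric(unname(cm$counts))) stop("consensus counts not symmetric")
  if (any(cm$counts < 0) || any(cm$counts > cm$n_runs))
    stop("consensus counts outside [0, n_runs]")
  if (any(diag(cm$counts) != cm$n_runs))
    stop("consensus diagonal must equal n_runs")
  invisible(cm)
}

#' Spectral partitioning of a consensus matrix
#'
#' Uses `counts / n_runs` as the affinity, forms the symmetric normalized
#' Laplacian, embeds the genes in the top-k eigenvectors, row-normalizes
#' the embedding, and clusters the embedded points with k-means.  The
#' centers are seeded deterministically by a farthest-point (maximin)
#' sweep -- with many tight, near-orthogonal clusters a random draw of k
#' rows almost never covers every cluster, whereas maximin seeding does --
#' and `nstart` seeded random restarts are run as well, the solution with
#' the lowest within-cluster sum of squares winning.  If the affinity
#' graph has more than `k` connected components a warning is emitted and
#' clustering proceeds.
#'
#' @param cm A `consensus_matrix`.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart k-means restarts (default 50).
#' @return A `module_partition`.
#' @export
spectral_partition <- function(cm, k, seed = 1, nstart = 50) {
  validate_consensus(cm)
  if (k < 2) stop("spectral partitioning requires k >= 2")
  g <- length(cm$gene_ids)
  if (k > g) stop("k cannot exceed the number of genes")
  if (k == g)   # every gene its own module; k-means needs k < n
    return(structure(list(labels = setNames(seq_len(g), cm$gene_ids),
                          k = k), class = "module_partition"))
  a <- cm$counts / cm$n_runs
  n_comp <- .n_components(a > 0)
  if (n_comp > k)
    warning("affinity graph has ", n_comp,
            " connected components but k = ", k, "; proceeding")
  deg <- rowSums(a)
  dis <- 1 / sqrt(pmax(deg, 1e-12))
  s <- a * outer(dis, dis)
  ev <- eigen(s, symmetric = TRUE)
  emb <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(emb^2))
  emb <- emb / pmax(nrm, 1e-12)
  set.seed(seed)
  km <- tryCatch(
    suppressWarnings(
      stats::kmeans(emb, centers = .maximin_centers(emb, k),
                    iter.max = 200)),
    error = function(e) NULL)
  km2 <- tryCatch(
    suppressWarnings(stats::kmeans(emb, centers = k, nstart = nstart,
                                   iter.max = 200)),
    error = function(e) NULL)
  if (is.null(km) && is.null(km2))
    stop("k-means failed on the spectral embedding")
  if (is.null(km) ||
      (!is.null(km2) && km2$tot.withinss < km$tot.withinss)) km <- km2
  labels <- as.integer(km$cluster)
  names(labels) <- cm$gene_ids
  structure(list(labels = labels, k = k), class = "module_partition")
}

# deterministic maximin center seeding: start at the point farthest from
# the centroid, then repeatedly add the point farthest from all chosen
# centers
.maximin_centers <- function(e, k) {
  ctr <- colMeans(e)
  sel <- which.max(colSums((t(e) - ctr)^2))
  d2 <- colSums((t(e) - e[sel, ])^2)
  d2[sel] <- -Inf                       # never reselect the same point
  while (length(sel) < k) {
    nxt <- which.max(d2)
    sel <- c(sel, nxt)
    d2 <- pmin(d2, colSums((t(e) - e[nxt, ])^2))
    d2[sel] <- -Inf
  }
  ctrs <- e[sel, , drop = FALSE]
  # duplicate embedding rows would make identical centers; jitter them
  # minutely so k-means accepts the seeding
  dup <- duplicated(round(ctrs, 12))
  if (any(dup))
    ctrs[dup, ] <- ctrs[dup, , drop = FALSE] +
      1e-9 * seq_len(sum(dup))
  ctrs
}

.n_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0L) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nb] <- TRUE
      frontier <- nb
    }
  }
  comp
}

#' Full module-detection pipeline at a fixed K
#'
#' Runs `n_repeats` multi-view factorizations with distinct seeds
#' (`base_seed + 1 .. base_seed + n_repeats`), assigns modules from each
#' consensus factor, sums their co-memberships with [cspa_consensus()],
#' and extracts the final stabilized partition by
#' [spectral_partition()] at the same K.
#'
#' @param views A `view_set`.
#' @param k Number of modules.
#' @param n_repeats Number of factorization repeats (default 10).
#' @param base_seed Integer base seed.
#' @param lambda_pcc,lambda_la,max_iter,tol Passed to
#'   [mvnmf_factorize()].
#' @return A `module_partition`.
#' @export
run_pipeline <- function(views, k, n_repeats = 10, base_seed = 1,
                         lambda_pcc = 1, lambda_la = 1, max_iter = 300,
                         tol = 1e-6) {
  parts <- lapply(seq_len(n_repeats), function(r) {
    fit <- mvnmf_factorize(views, k, lambda_pcc, lambda_la,
                           seed = base_seed + r, max_iter = max_iter,
                           tol = tol)
    suppressWarnings(assign_modules(fit))
  })
  cm <- cspa_consensus(parts)
  spectral_partition(cm, k, seed = base_seed)
}
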