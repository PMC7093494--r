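# Independent oracles and small fixture builders shared across test files.
# Everything here is deliberately naive (pair loops, exhaustive
# enumeration) so it cannot share a bug with the vectorized package code.

# exhaustive hypergeometric upper tail: enumerate every b-subset of
# {1..Q}, count overlaps with {1..T}, and take the fraction with
# overlap >= q
enum_shared_tail <- function(T, b, q, Q) {
  if (b == 0) return(if (q == 0) 1 else 0)
  subsets <- utils::combn(Q, b)
  overlaps <- colSums(subsets <= T)
  mean(overlaps >= q)
}

# naive O(G^2) validity indices on a precomputed dissimilarity matrix
naive_validity <- function(m, labels) {
  mx <- max(m)
  d <- 1 - m / mx
  diag(d) <- 0
  g <- nrow(d)
  within <- c(); between <- c()
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (labels[i] == labels[j]) within <- c(within, d[i, j])
    else between <- c(between, d[i, j])
  }
  n_w <- length(within)
  all_d <- sort(c(within, between))
  s_w <- sum(within)
  s_min <- sum(all_d[seq_len(n_w)])
  s_max <- sum(rev(all_d)[seq_len(n_w)])
  sil <- numeric(g)
  for (i in seq_len(g)) {
    own <- which(labels == labels[i] & seq_len(g) != i)
    if (length(own) == 0) { sil[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(sapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl])))
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(c_index = (s_w - s_min) / (s_max - s_min),
       mcclain_rao = (s_w / n_w) / (sum(between) / length(between)),
       point_biserial = stats::cor(c(within, between),
                                   rep(c(0, 1), c(n_w, length(between)))),
       silhouette = mean(sil))
}

# random symmetric non-negative matrix with zero diagonal
rand_sym <- function(g, seed) {
  set.seed(seed)
  m <- matrix(runif(g * g), g, g)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  ids <- sprintf("g%03d", seq_len(g))
  dimnames(m) <- list(ids, ids)
  m
}

rand_view_set <- function(g, seed) {
  view_set(rand_sym(g, seed), rand_sym(g, seed + 1000))
}

# tiny expression fixture: genes x samples with known values
toy_expression <- function() {
  matrix(c(1, 2, 3, 4,
           0, 0, 0, 0,
           5, 1, 2, 8),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("gA", "gB", "gC"),
                         c("s1", "s2", "s3", "s4")))
}
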