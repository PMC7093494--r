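#' Build the PCC and LA view matrices
#'
#' Assembles the two symmetric non-negative G x G similarity matrices used
#' by the multi-view factorization.  For each scored pair the (PCC, LA)
#' values are placed at the pair's entry, then three zeroing rules are
#' applied in order:
#' \enumerate{
#'   \item pairs whose shared-microRNA significance is weak
#'     (`msp >= alpha`) have both values set to zero;
#'   \item negative PCC or LA values are set to zero (non-negativity of the
#'     factorization input);
#'   \item if either value of a pair is zero, both are set to zero -- a
#'     ceRNA pair must be both co-expressed and microRNA-sensitive.
#' }
#' Unlisted pairs and the diagonal are structural zeros.
#'
#' @param stats data.frame of pair statistics as from [score_all_pairs()]
#'   (columns `rna1`, `rna2`, `pcc`, `la`, `msp`).
#' @param gene_ids Character vector of the G genes indexing the matrices.
#' @param alpha MS-P significance threshold (default 0.05).
#' @return Object of class `view_set`: list with `gene_ids`, `m_pcc`,
#'   `m_la`, `alpha`.  Invariants (symmetry, non-negativity, zero diagonal,
#'   equal support of the two views) are asserted on construction.
#' @export
build_views <- function(stats, gene_ids, alpha = 0.05) {
  vals <- .zeroed_pair_values(stats, gene_ids, alpha)
  pcc <- vals$pcc
  la <- vals$la
  drop <- pcc <= 0 | la <= 0          # rules 2 + 3: joint support
  pcc[drop] <- 0
  la[drop] <- 0
  vs <- structure(list(gene_ids = gene_ids,
                       m_pcc = .pair_matrix(vals$i, vals$j, pcc, gene_ids),
                       m_la = .pair_matrix(vals$i, vals$j, la, gene_ids),
                       alpha = alpha),
                  class = "view_set")
  validate_view_set(vs)
  vs
}

#' Build the single-view SI matrix
#'
#' Baseline similarity matrix of sensitivity-correlation values with the
#' same significance and negativity zeroing (no joint-support rule, there
#' being a single view).
#'
#' @inheritParams build_views
#' @return Symmetric non-negative G x G matrix with zero diagonal.
#' @export
build_si_view <- function(stats, gene_ids, alpha = 0.05) {
  if (!"si" %in% colnames(stats)) stop("stats must have an 'si' column")
  vals <- .zeroed_pair_values(stats, gene_ids, alpha, value_cols = "si")
  si <- pmax(vals$si, 0)
  .pair_matrix(vals$i, vals$j, si, gene_ids)
}

# shared zeroing front-end: index pairs, apply the MS-P rule, clamp
# negatives per column
.zeroed_pair_values <- function(stats, gene_ids, alpha,
                                value_cols = c("pcc", "la")) {
  stopifnot(is.data.frame(stats),
            all(c("rna1", "rna2", "msp") %in% colnames(stats)),
            all(value_cols %in% colnames(stats)))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  i <- match(stats$rna1, gene_ids)
  j <- match(stats$rna2, gene_ids)
  if (anyNA(i) || anyNA(j)) {
    unknown <- unique(c(stats$rna1[is.na(i)], stats$rna2[is.na(j)]))
    stop("pair references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(i == j)) stop("self-pairs are not allowed")
  weak <- stats$msp >= alpha
  out <- list(i = i, j = j)
  for (v in value_cols) {
    x <- stats[[v]]
    x[weak] <- 0
    x <- pmax(x, 0)
    out[[v]] <- x
  }
  out
}

.pair_matrix <- function(i, j, values, gene_ids) {
  g <- length(gene_ids)
  m <- matrix(0, g, g, dimnames = list(gene_ids, gene_ids))
  m[cbind(i, j)] <- values
  m[cbind(j, i)] <- values
  m
}

#' Construct a view set from two similarity matrices
#'
#' Low-level constructor for callers that already hold the two symmetric
#' non-negative matrices (e.g. simulated benchmarks).  Joint support is
#' enforced by zeroing entries that are zero in either matrix; all
#' `view_set` invariants are then asserted.
#'
#' @param m_pcc,m_la Symmetric non-negative matrices with zero diagonal
#'   and matching dimnames.
#' @param alpha The MS-P threshold to record (default 0.05).
#' @return A `view_set`.
#' @export
view_set <- function(m_pcc, m_la, alpha = 0.05) {
  stopifnot(is.matrix(m_pcc), is.matrix(m_la),
            identical(dim(m_pcc), dim(m_la)))
  ids <- rownames(m_pcc)
  if (is.null(ids)) {
    ids <- sprintf("G%04d", seq_len(nrow(m_pcc)))
    dimnames(m_pcc) <- dimnames(m_la) <- list(ids, ids)
  }
  support <- m_pcc > 0 & m_la > 0
  m_pcc[!support] <- 0
  m_la[!support] <- 0
  vs <- structure(list(gene_ids = ids, m_pcc = m_pcc, m_la = m_la,
                       alpha = alpha),
                  class = "view_set")
  validate_view_set(vs)
  vs
}

#' Assert the view-set invariants
#'
#' Checks symmetry, non-negativity, zero diagonal, and equality of the
#' non-zero supports of the two view matrices.
#'
#' @param vs A `view_set`.
#' @return `vs`, invisibly; errors on violation.
#' @export
validate_view_set <- function(vs) {
  stopifnot(inherits(vs, "view_set"))
  for (nm in c("m_pcc", "m_la")) {
    m <- vs[[nm]]
    if (!isSymmetric(unname(m))) stop(nm, " is not symmetric")
    if (any(m < 0)) stop(nm, " has negative entries")
    if (any(diag(m) != 0)) stop(nm, " has a non-zero diagonal")
  }
  if (!identical(vs$m_pcc > 0, vs$m_la > 0))
    stop("support of m_pcc and m_la differ")
  invisible(vs)
}
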