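#' Multi-view NMF objective
#'
#' The joint factorization objective
#' \deqn{\|M^{PCC} - U^{PCC}(V^{PCC})^T\|_F^2 + \|M^{LA} - U^{LA}(V^{LA})^T\|_F^2
#'   + \lambda_{PCC}\|V^{PCC} - V^*\|_F^2 + \lambda_{LA}\|V^{LA} - V^*\|_F^2}
#' subject to non-negativity of all factors and unit column sums of each
#' U.  The two reconstruction terms tie each view to its own factors; the
#' two coupling terms pull both coefficient matrices toward the shared
#' consensus factor `v_star`, whose rows are the joint low-rank embedding
#' used for module assignment.
#'
#' @param views A `view_set`.
#' @param fit A factorization state as produced by [mvnmf_init()] or
#'   [mvnmf_factorize()].
#' @return Non-negative scalar.
#' @export
mvnmf_objective <- function(views, fit) {
  .check_shapes(views, fit)
  sum((views$m_pcc - fit$u_pcc %*% t(fit$v_pcc))^2) +
    sum((views$m_la - fit$u_la %*% t(fit$v_la))^2) +
    fit$lambda_pcc * sum((fit$v_pcc - fit$v_star)^2) +
    fit$lambda_la * sum((fit$v_la - fit$v_star)^2)
}

.check_shapes <- function(views, fit) {
  g <- length(views$gene_ids)
  k <- ncol(fit$v_star)
  for (nm in c("u_pcc", "u_la", "v_pcc", "v_la", "v_star")) {
    m <- fit[[nm]]
    if (!is.matrix(m) || nrow(m) != g || ncol(m) != k)
      stop("factor ", nm, " has wrong shape; expected ", g, " x ", k)
  }
  invisible(TRUE)
}

#' Initialize a multi-view factorization
#'
#' Factors are drawn uniformly from (0, 1\] and scaled by
#' `sqrt(mean(M)/k)` per view, so the initial reconstruction has roughly
#' the right magnitude.  The U factors are immediately column-normalized
#' (compensated in V, leaving the reconstruction unchanged) so that the
#' unit-column-sum constraint -- and hence the equality between the plain
#' objective and its constraint-folded form -- holds from the first
#' recorded objective value onward.  The consensus factor starts at the
#' lambda-weighted average of the two coefficient factors.
#'
#' @param views A `view_set`.
#' @param k Number of modules (factor rank).
#' @param lambda_pcc,lambda_la Non-negative coupling weights.
#' @param seed Integer RNG seed.
#' @return Factorization state (list), not yet iterated.
#' @export
mvnmf_init <- function(views, k, lambda_pcc = 1, lambda_la = 1, seed = 1) {
  g <- length(views$gene_ids)
  if (k < 1 || k > g) stop("k must lie in [1, G]")
  set.seed(seed)
  rmat <- function(m) {
    sc <- sqrt(max(mean(m), 1e-10) / k)
    matrix((1 - stats::runif(g * k)) * sc, g, k,
           dimnames = list(views$gene_ids, NULL))
  }
  u_pcc <- rmat(views$m_pcc); v_pcc <- rmat(views$m_pcc)
  u_la <- rmat(views$m_la); v_la <- rmat(views$m_la)
  q <- colSums(u_pcc); u_pcc <- sweep(u_pcc, 2L, q, "/")
  v_pcc <- sweep(v_pcc, 2L, q, "*")
  q <- colSums(u_la); u_la <- sweep(u_la, 2L, q, "/")
  v_la <- sweep(v_la, 2L, q, "*")
  v_star <- (lambda_pcc * v_pcc + lambda_la * v_la) /
    (lambda_pcc + lambda_la)
  list(u_pcc = u_pcc, u_la = u_la, v_pcc = v_pcc, v_la = v_la,
       v_star = v_star, lambda_pcc = lambda_pcc, lambda_la = lambda_la,
       seed = seed, objective_trace = numeric(0))
}

# one multiplicative update of U for one view, with the consensus coupling
# folded in through Q = diag(colSums(U))
.update_u <- function(m, u, v, v_star, lambda, eps) {
  num <- m %*% v
  num <- sweep(num, 2L, lambda * colSums(v * v_star), "+")
  den <- u %*% crossprod(v)
  den <- den + outer(rep(1, nrow(u)),
                     lambda * colSums(u) * colSums(v * v)) + eps
  u * num / den
}

.update_v <- function(m, u, v, v_star, lambda, eps) {
  num <- crossprod(m, u) + lambda * v_star
  den <- v %*% crossprod(u) + lambda * v + eps
  v * num / den
}

#' One outer iteration of the multi-view NMF updates
#'
#' Applies, in order: the multiplicative U updates for both views, the
#' column normalization `U <- U Q^{-1}`, `V <- V Q` with
#' `Q = diag(colSums(U))` (which enforces the unit-column-sum constraint
#' without changing the reconstruction), the multiplicative V updates, and
#' the closed-form consensus update
#' `V* = (lambda_pcc V^pcc Q^pcc + lambda_la V^la Q^la) / (lambda_pcc +
#' lambda_la)`.  Every step is non-increasing in the objective, so the
#' per-iteration trace is monotone.
#'
#' @param views A `view_set`.
#' @param fit Factorization state.
#' @param eps Denominator guard (default 1e-10).
#' @param iter Iteration index, used only in error messages.
#' @return Updated factorization state.
#' @export
mvnmf_update_step <- function(views, fit, eps = 1e-10, iter = NA_integer_) {
  fit$u_pcc <- .update_u(views$m_pcc, fit$u_pcc, fit$v_pcc, fit$v_star,
                         fit$lambda_pcc, eps)
  fit$u_la <- .update_u(views$m_la, fit$u_la, fit$v_la, fit$v_star,
                        fit$lambda_la, eps)
  # normalization: unit column sums of U, compensated in V
  for (v in c("pcc", "la")) {
    un <- paste0("u_", v); vn <- paste0("v_", v)
    q <- pmax(colSums(fit[[un]]), eps)
    fit[[un]] <- sweep(fit[[un]], 2L, q, "/")
    fit[[vn]] <- sweep(fit[[vn]], 2L, q, "*")
  }
  fit$v_pcc <- .update_v(views$m_pcc, fit$u_pcc, fit$v_pcc, fit$v_star,
                         fit$lambda_pcc, eps)
  fit$v_la <- .update_v(views$m_la, fit$u_la, fit$v_la, fit$v_star,
                        fit$lambda_la, eps)
  q_pcc <- colSums(fit$u_pcc)
  q_la <- colSums(fit$u_la)
  fit$v_star <- (fit$lambda_pcc * sweep(fit$v_pcc, 2L, q_pcc, "*") +
                 fit$lambda_la * sweep(fit$v_la, 2L, q_la, "*")) /
    (fit$lambda_pcc + fit$lambda_la)
  for (nm in c("u_pcc", "u_la", "v_pcc", "v_la", "v_star"))
    if (!all(is.finite(fit[[nm]])))
      stop("non-finite values in ", nm, " at iteration ", iter)
  fit
}

#' Fit the multi-view NMF
#'
#' Iterates [mvnmf_update_step()] from a seeded random initialization until
#' the relative objective decrease falls below `tol` or `max_iter` is
#' reached.  The full objective trace (initial value plus one value per
#' outer iteration) is retained.
#'
#' @inheritParams mvnmf_init
#' @param max_iter Maximum outer iterations (default 500).
#' @param tol Relative objective-change convergence threshold
#'   (default 1e-6).
#' @param eps Denominator guard for the multiplicative rules.
#' @return Object of class `mvnmf_fit`: the factorization state with
#'   `objective_trace`, `k`, and `seed`.
#' @export
mvnmf_factorize <- function(views, k, lambda_pcc = 1, lambda_la = 1,
                            seed = 1, max_iter = 500, tol = 1e-6,
                            eps = 1e-10) {
  fit <- mvnmf_init(views, k, lambda_pcc, lambda_la, seed)
  obj <- mvnmf_objective(views, fit)
  trace <- obj
  for (it in seq_len(max_iter)) {
    fit <- mvnmf_update_step(views, fit, eps = eps, iter = it)
    prev <- obj
    obj <- mvnmf_objective(views, fit)
    trace <- c(trace, obj)
    if (prev <= 0 || (prev - obj) / prev < tol) break
  }
  fit$objective_trace <- trace
  fit$k <- k
  class(fit) <- "mvnmf_fit"
  fit
}

#' Single-view NMF baseline
#'
#' Standard multiplicative-update NMF minimizing `||M - U V^T||_F^2`, used
#' as the single-matrix baseline (e.g. factorizing the PCC or SI matrix
#' alone).
#'
#' @param m Non-negative matrix.
#' @param k Factor rank.
#' @param seed Integer RNG seed.
#' @param max_iter,tol,eps As in [mvnmf_factorize()].
#' @return List with `u`, `v`, `objective_trace`, `k`, `seed`.
#' @export
factorize_single <- function(m, k, seed = 1, max_iter = 500, tol = 1e-6,
                             eps = 1e-10) {
  if (any(m < 0)) stop("input matrix must be non-negative")
  g <- nrow(m)
  if (k < 1 || k > g) stop("k must lie in [1, nrow(m)]")
  set.seed(seed)
  sc <- sqrt(max(mean(m), 1e-10) / k)
  u <- matrix((1 - stats::runif(g * k)) * sc, g, k,
              dimnames = list(rownames(m), NULL))
  v <- matrix((1 - stats::runif(ncol(m) * k)) * sc, ncol(m), k,
              dimnames = list(colnames(m), NULL))
  obj <- sum((m - u %*% t(v))^2)
  trace <- obj
  for (it in seq_len(max_iter)) {
    u <- u * (m %*% v) / (u %*% crossprod(v) + eps)
    v <- v * (crossprod(m, u)) / (v %*% crossprod(u) + eps)
    prev <- obj
    obj <- sum((m - u %*% t(v))^2)
    trace <- c(trace, obj)
    if (prev <= 0 || (prev - obj) / prev < tol) break
  }
  list(u = u, v = v, objective_trace = trace, k = k, seed = seed)
}

#' Assign module labels from a consensus factor
#'
#' Gene i is assigned to the module with the largest coefficient in row i
#' of `v_star`; ties go to the lowest index.  All-zero rows (isolated
#' genes) fall back to module 1 with a warning naming the genes.
#'
#' @param v_star Non-negative G x K matrix, or an `mvnmf_fit` (its
#'   `v_star` is used), or a single-view fit from [factorize_single()]
#'   (its `v`).
#' @return Object of class `module_partition`: list with `labels` (named
#'   integer vector) and `k`.
#' @export
assign_modules <- function(v_star) {
  if (inherits(v_star, "mvnmf_fit")) v_star <- v_star$v_star
  else if (is.list(v_star) && !is.null(v_star$v)) v_star <- v_star$v
  if (!is.matrix(v_star) || nrow(v_star) == 0L || ncol(v_star) == 0L)
    stop("v_star must be a non-empty matrix")
  zero_rows <- rowSums(v_star != 0) == 0L
  if (any(zero_rows)) {
    who <- rownames(v_star)[zero_rows]
    if (is.null(who)) who <- which(zero_rows)
    warning("all-zero factor row(s) assigned to module 1: ",
            paste(who, collapse = ", "))
  }
  labels <- max.col(v_star, ties.method = "first")
  names(labels) <- rownames(v_star)
  structure(list(labels = labels, k = ncol(v_star)),
            class = "module_partition")
}
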