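#' Configuration for the synthetic-data generators
#'
#' One configuration object drives all three generators.  Defaults encode
#' the benchmark regime used throughout the package's tests: 500 samples,
#' 200 genes in 20 modules for the block-view benchmark, a ceRNA effect of
#' 1 (co-expression scaling linearly with the shared-microRNA level),
#' block similarities 0.8 within / 0.05 between with additive noise of
#' sd 0.05.
#'
#' @param n_samples Number of samples (>= 10).
#' @param n_genes Number of genes.
#' @param n_mirnas Number of microRNAs in the universe.
#' @param n_modules Number of planted modules (<= n_genes).
#' @param cerna_effect Non-negative strength of the microRNA-dependent
#'   co-expression; 0 yields plain co-expression with zero expected
#'   liquid association.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param within_sim,between_sim Block-view similarity inside/outside
#'   modules; `0 <= between_sim < within_sim <= 1`.
#' @param seed Integer RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 500, n_genes = 200,
                              n_mirnas = 60, n_modules = 20,
                              cerna_effect = 1, noise_sd = 0.05,
                              within_sim = 0.8, between_sim = 0.05,
                              seed = 1) {
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (n_modules > n_genes) stop("n_modules must be <= n_genes")
  if (cerna_effect < 0) stop("cerna_effect must be >= 0")
  if (!(between_sim >= 0 && between_sim < within_sim && within_sim <= 1))
    stop("need 0 <= between_sim < within_sim <= 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 n_modules = as.integer(n_modules),
                 cerna_effect = cerna_effect, noise_sd = noise_sd,
                 within_sim = within_sim, between_sim = between_sim,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a ceRNA triple (two genes and their shared-microRNA level)
#'
#' Generative model for a single candidate pair: a microRNA level
#' `w ~ N(0,1)`, a shared signal `s ~ N(0,1)`, and
#' `x = s (1 + effect * w) / sqrt(1 + effect^2) + noise`,
#' `y` likewise with independent noise.  The `sqrt(1 + effect^2)`
#' normalization keeps x and y at unit variance analytically for any
#' effect, so liquid-association estimates are comparable across effect
#' sizes; the expected LA of the noiseless pair is
#' `2 * effect / (1 + effect^2)`.  With `effect = 0` the pair is plainly
#' co-expressed and has zero expected LA.
#'
#' @param cfg A [simulation_config()]; uses `n_samples`, `cerna_effect`,
#'   `noise_sd`, `seed`.
#' @return List with vectors `x`, `y`, `w` and a `truth` list recording
#'   the generating parameters.
#' @export
simulate_cerna_triples <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  e <- cfg$cerna_effect
  w <- stats::rnorm(n)
  s <- stats::rnorm(n)
  base <- s * (1 + e * w) / sqrt(1 + e^2)
  x <- base + stats::rnorm(n, sd = cfg$noise_sd)
  y <- base + stats::rnorm(n, sd = cfg$noise_sd)
  list(x = x, y = y, w = w,
       truth = list(effect = e, noise_sd = cfg$noise_sd,
                    expected_la = 2 * e / (1 + e^2)))
}

.even_partition <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

#' Simulate two-view block-modular similarity matrices
#'
#' Genes are partitioned evenly into `n_modules`; both views take the
#' value `within_sim` on within-module entries and `between_sim`
#' elsewhere, plus independent symmetric Gaussian noise truncated at
#' zero.  The diagonal is zero and joint support is enforced, so the
#' output satisfies every `view_set` invariant.
#'
#' @param cfg A [simulation_config()]; uses `n_genes`, `n_modules`,
#'   `within_sim`, `between_sim`, `noise_sd`, `seed`.
#' @return List with `views` (a `view_set`) and `truth` (a
#'   `module_partition`).
#' @export
simulate_block_views <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  g <- cfg$n_genes
  ids <- sprintf("G%04d", seq_len(g))
  labels <- .even_partition(g, cfg$n_modules)
  names(labels) <- ids
  base <- matrix(cfg$between_sim, g, g)
  same <- outer(labels, labels, "==")
  base[same] <- cfg$within_sim
  one_view <- function() {
    noise <- matrix(0, g, g)
    ut <- upper.tri(noise)
    noise[ut] <- stats::rnorm(sum(ut), sd = cfg$noise_sd)
    noise <- noise + t(noise)
    m <- pmax(base + noise, 0)
    diag(m) <- 0
    dimnames(m) <- list(ids, ids)
    m
  }
  vs <- view_set(one_view(), one_view())
  list(views = vs,
       truth = structure(list(labels = labels, k = cfg$n_modules),
                         class = "module_partition"))
}

#' Simulate a full synthetic input set with planted ceRNA modules
#'
#' Produces gene and microRNA expression matrices and a target map in the
#' exact in-memory model the scoring pipeline consumes.  Half of the
#' genes (rounded to `n_modules` equal modules of at least two genes)
#' are planted ceRNA genes: each module draws a set of microRNAs from the
#' universe, all its genes target exactly that set (so within-module
#' pairs share many microRNAs and have small MS-P), and their expression
#' follows the triple model of [simulate_cerna_triples()] against the
#' Van der Waerden transform of the module's summed microRNA expression.
#' The remaining background genes get independent expression and a few
#' random targets each.  Expression values are shifted to a positive
#' log-abundance scale.
#'
#' @param cfg A [simulation_config()].
#' @param mirnas_per_module MicroRNAs drawn per module (default 6).
#' @param background_targets Random targets per background gene
#'   (default 3).
#' @return List with `gene_expr`, `mic_expr` (log-scale matrices),
#'   `map` (a `target_map`), `truth_pairs` (data.frame `rna1`, `rna2`,
#'   `module`), and `truth` (a `module_partition` over the planted genes;
#'   background genes are labeled 0).
#' @export
simulate_dataset <- function(cfg, mirnas_per_module = 6,
                             background_targets = 3) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (mirnas_per_module > cfg$n_mirnas)
    stop("mirnas_per_module exceeds the universe size")
  set.seed(cfg$seed)
  n <- cfg$n_samples
  mir_ids <- sprintf("MIR%03d", seq_len(cfg$n_mirnas))
  mic_expr <- matrix(pmax(stats::rnorm(cfg$n_mirnas * n, mean = 5), 0),
                     cfg$n_mirnas, n,
                     dimnames = list(mir_ids, sprintf("S%04d", seq_len(n))))
  module_size <- max(2L, floor(cfg$n_genes / (2L * cfg$n_modules)))
  n_planted <- module_size * cfg$n_modules
  if (n_planted > cfg$n_genes)
    stop("n_genes too small for n_modules planted modules of size 2")
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  planted <- gene_ids[seq_len(n_planted)]
  background <- setdiff(gene_ids, planted)
  labels <- c(rep(seq_len(cfg$n_modules), each = module_size),
              rep(0L, length(background)))
  names(labels) <- gene_ids
  e <- cfg$cerna_effect
  gene_expr <- matrix(0, cfg$n_genes, n,
                      dimnames = list(gene_ids, colnames(mic_expr)))
  rna_id <- character(0); tgt_id <- character(0)
  truth_pairs <- NULL
  for (m in seq_len(cfg$n_modules)) {
    mirs <- sample(mir_ids, mirnas_per_module)
    members <- planted[labels[planted] == m]
    w <- van_der_waerden(colSums(mic_expr[mirs, , drop = FALSE]))
    s <- stats::rnorm(n)
    for (gene in members) {
      sig <- s * (1 + e * w) / sqrt(1 + e^2) +
        stats::rnorm(n, sd = cfg$noise_sd)
      gene_expr[gene, ] <- pmax(6 + sig, 0)
    }
    rna_id <- c(rna_id, rep(members, each = length(mirs)))
    tgt_id <- c(tgt_id, rep(mirs, length(members)))
    pr <- t(utils::combn(sort(members), 2L))
    truth_pairs <- rbind(truth_pairs,
                         data.frame(rna1 = pr[, 1L], rna2 = pr[, 2L],
                                    module = m,
                                    stringsAsFactors = FALSE))
  }
  for (gene in background) {
    gene_expr[gene, ] <- pmax(6 + stats::rnorm(n), 0)
    mirs <- sample(mir_ids, background_targets)
    rna_id <- c(rna_id, rep(gene, length(mirs)))
    tgt_id <- c(tgt_id, mirs)
  }
  list(gene_expr = gene_expr,
       mic_expr = mic_expr,
       map = target_map(rna_id, tgt_id, universe = mir_ids),
       truth_pairs = truth_pairs,
       truth = structure(list(labels = labels, k = cfg$n_modules),
                         class = "module_partition"))
}
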