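#' Read an expression matrix from a tab-delimited file
#'
#' Expression tables are TSV with a header row of sample identifiers and the
#' row identifier (gene or microRNA) in the first column.  Values are read
#' raw, i.e. untransformed; see [log_transform()].
#'
#' @param path Path to a tab-delimited text file.
#' @param kind Either `"gene"` or `"microRNA"`; recorded as an attribute
#'   only, the parsing is identical.
#' @return A numeric matrix (rows = RNAs, columns = samples) with unique
#'   `rownames` and `colnames`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), tf)
#' load_expression(tf)
#' @export
load_expression <- function(path, kind = c("gene", "microRNA")) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression file must have an id column and at least one sample")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  chr <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 chr[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], samples[bad[1L, 2L]]))
  dimnames(vals) <- list(ids, samples)
  attr(vals, "kind") <- kind
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression()]: first column `id`, remaining columns the
#' samples, tab-delimited.
#'
#' @param expr Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Abundance filter policies
#'
#' Default low-abundance filters by RNA class: mRNAs are kept when their
#' abundance exceeds 1 (FPKM) in more than 80% of disease or normal samples,
#' lncRNAs when it exceeds 0.8 in more than 50%, and microRNAs when it
#' exceeds 100 (CPM) in more than 50%.  Both comparisons are strict.
#'
#' @param rna_class One of `"mRNA"`, `"lncRNA"`, `"microRNA"`.
#' @param abundance_threshold,sample_fraction Override the class default.
#' @return A list with elements `rna_class`, `abundance_threshold`,
#'   `sample_fraction`.
#' @export
filter_policy <- function(rna_class = c("mRNA", "lncRNA", "microRNA"),
                          abundance_threshold = NULL,
                          sample_fraction = NULL) {
  rna_class <- match.arg(rna_class)
  defaults <- switch(rna_class,
    mRNA     = c(1, 0.8),
    lncRNA   = c(0.8, 0.5),
    microRNA = c(100, 0.5))
  thr <- if (is.null(abundance_threshold)) defaults[1L] else abundance_threshold
  frac <- if (is.null(sample_fraction)) defaults[2L] else sample_fraction
  if (!is.numeric(thr) || length(thr) != 1L || thr <= 0)
    stop("abundance_threshold must be a single positive number")
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1)
    stop("sample_fraction must lie in (0, 1]")
  list(rna_class = rna_class, abundance_threshold = thr,
       sample_fraction = frac)
}

#' Filter expression rows by abundance
#'
#' A row is retained when the fraction of samples whose value strictly
#' exceeds the policy threshold is strictly greater than the policy sample
#' fraction, in the disease group *or* in the normal group.  The sample set
#' is unchanged.
#'
#' @param expr Numeric expression matrix (raw abundances).
#' @param policy A policy from [filter_policy()].
#' @param groups Named character vector mapping every sample id to
#'   `"disease"` or `"normal"` (see [read_sample_groups()]).
#' @return The filtered expression matrix.  Emits a warning (not an error)
#'   if no row survives.
#' @export
filter_by_abundance <- function(expr, policy, groups) {
  stopifnot(is.matrix(expr))
  samples <- colnames(expr)
  if (!all(samples %in% names(groups)))
    stop("groups must cover all samples; missing: ",
         paste(setdiff(samples, names(groups)), collapse = ", "))
  groups <- groups[samples]
  if (!all(groups %in% c("disease", "normal")))
    stop("group labels must be 'disease' or 'normal'")
  keep <- rep(FALSE, nrow(expr))
  for (g in c("disease", "normal")) {
    idx <- which(groups == g)
    if (length(idx) == 0L) next
    frac <- rowMeans(expr[, idx, drop = FALSE] > policy$abundance_threshold)
    keep <- keep | (frac > policy$sample_fraction)
  }
  if (!any(keep))
    warning("no rows pass the abundance filter")
  expr[keep, , drop = FALSE]
}

#' Log-transform abundances
#'
#' Applies `log(x + pseudo)` elementwise (natural logarithm by default,
#' matching log(FPKM + 1) / log(CPM + 1) preprocessing).
#'
#' @param expr Non-negative numeric matrix.
#' @param pseudo Pseudocount added before taking logs (default 1).
#' @param base Logarithm base (default `exp(1)`).
#' @return Transformed matrix of the same shape.
#' @export
log_transform <- function(expr, pseudo = 1, base = exp(1)) {
  if (any(expr < 0))
    stop("log_transform requires non-negative input")
  log(expr + pseudo, base = base)
}

#' Counts per million
#'
#' Library-size normalization for microRNA read counts: each column is
#' scaled to sum to one million.
#'
#' @param counts Non-negative count matrix (rows = microRNAs).
#' @return CPM matrix of the same shape.
#' @export
cpm <- function(counts) {
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("column(s) with zero total counts: ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(counts, 2L, cs, "/") * 1e6
}

#' Construct an RNA -> microRNA target map
#'
#' @param rna_id,mirna_id Parallel character vectors, one interaction per
#'   element; duplicates are collapsed.
#' @param universe Optional character vector of all considered microRNAs;
#'   defaults to the union of `mirna_id`.  Every target must lie in the
#'   universe.
#' @return An object of class `target_map`: a list with `targets` (named
#'   list of character vectors) and `universe`.
#' @export
target_map <- function(rna_id, mirna_id, universe = NULL) {
  stopifnot(length(rna_id) == length(mirna_id))
  if (is.null(universe)) universe <- sort(unique(mirna_id))
  if (!all(mirna_id %in% universe))
    stop("microRNA(s) outside the universe: ",
         paste(unique(setdiff(mirna_id, universe)), collapse = ", "))
  targets <- lapply(split(mirna_id, rna_id), function(x) sort(unique(x)))
  structure(list(targets = targets, universe = universe),
            class = "target_map")
}

#' Read an interaction table into a target map
#'
#' Two-column TSV with header `rna_id`, `mirna_id`, one interaction per
#' line.
#'
#' @param path Path to the TSV.
#' @param universe Optional microRNA universe, as in [target_map()].
#' @return A `target_map`.
#' @export
read_target_map <- function(path, universe = NULL) {
  tbl <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tbl) < 2L)
    stop("interaction table must have two columns (rna_id, mirna_id)")
  target_map(tbl[[1L]], tbl[[2L]], universe = universe)
}

#' Read sample group annotations
#'
#' TSV with columns `sample_id` and `group` (values `disease` / `normal`).
#'
#' @param path Path to the TSV.
#' @return Named character vector sample id -> group.
#' @export
read_sample_groups <- function(path) {
  tbl <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(tbl)))
    stop("annotation must have columns 'sample_id' and 'group'")
  if (!all(tbl$group %in% c("disease", "normal")))
    stop("group values must be 'disease' or 'normal'")
  stats::setNames(tbl$group, tbl$sample_id)
}

#' Restrict expression and target map to their common RNAs
#'
#' Drops expression rows without interactions and map entries without
#' expression, so both outputs refer to the same RNA set (candidate
#' ceRNAs).  Idempotent.
#'
#' @param expr Expression matrix.
#' @param map A `target_map`.
#' @return List with elements `expression` and `map`.
#' @export
restrict_to_candidates <- function(expr, map) {
  stopifnot(inherits(map, "target_map"))
  common <- intersect(rownames(expr), names(map$targets))
  if (length(common) == 0L)
    stop("no RNA shared between expression matrix and target map")
  expr2 <- expr[rownames(expr) %in% common, , drop = FALSE]
  map2 <- structure(list(targets = map$targets[common],
                         universe = map$universe),
                    class = "target_map")
  stopifnot(setequal(rownames(expr2), names(map2$targets)))
  list(expression = expr2, map = map2)
}
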