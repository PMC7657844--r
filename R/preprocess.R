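# Minimal single-cell preprocessing: cell/gene filtering, log-normalization,
# variable-gene selection by variance ranking, PCA.

#' Construct a cells-by-genes count matrix
#'
#' @param counts non-negative integer matrix (dense, or a sparse
#'   \code{Matrix} which is densified), cells in rows.
#' @param cell_ids,gene_ids optional names; default to existing dimnames or
#'   generated ids.
#' @return object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort_ee("`counts` must be a numeric matrix", "ee_invalid_input")
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort_ee("`counts` must be non-negative integers", "ee_invalid_input")
  }
  cell_ids <- cell_ids %||% rownames(counts) %||%
    paste0("cell", seq_len(nrow(counts)))
  gene_ids <- gene_ids %||% colnames(counts) %||%
    paste0("gene", seq_len(ncol(counts)))
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts)) {
    abort_ee("id lengths must match matrix dimensions", "ee_invalid_input")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "count_matrix")
}

#' Filter cells then genes by detection counts
#'
#' Single pass, cells first: drop cells in which fewer than
#' \code{min_features_per_cell} genes are detected (count > 0); then drop
#' genes detected in fewer than \code{min_cells_per_gene} of the surviving
#' cells. The conventional thresholds for the reference pipeline are 200
#' features per cell and 50 cells per gene.
#'
#' @param M \code{count_matrix}.
#' @param min_features_per_cell,min_cells_per_gene non-negative thresholds.
#' @return filtered \code{count_matrix}.
#' @export
filter_cells_genes <- function(M, min_features_per_cell = 200L,
                               min_cells_per_gene = 50L) {
  if (min_features_per_cell < 0 || min_cells_per_gene < 0) {
    abort_ee("thresholds must be >= 0", "ee_invalid_parameter")
  }
  detected <- M$counts > 0
  keep_cells <- rowSums(detected) >= min_features_per_cell
  keep_genes <- colSums(detected[keep_cells, , drop = FALSE]) >= min_cells_per_gene
  if (!any(keep_cells) || !any(keep_genes)) {
    abort_ee("no cells or genes survive the filters", "ee_empty_after_filter")
  }
  count_matrix(M$counts[keep_cells, keep_genes, drop = FALSE],
               M$cell_ids[keep_cells], M$gene_ids[keep_genes])
}

#' Log-normalize counts
#'
#' Per cell: divide each count by the cell total, multiply by
#' \code{scale} (default \eqn{10^4}), add 1, take the natural logarithm
#' (configurable base).
#'
#' @param M \code{count_matrix} with no zero-total cells (filter first).
#' @param scale scale factor (default 1e4).
#' @param base logarithm base (default \code{exp(1)}).
#' @return numeric matrix of normalized expression (cells x genes).
#' @export
lognormalize <- function(M, scale = 1e4, base = exp(1)) {
  totals <- rowSums(M$counts)
  if (any(totals == 0)) {
    abort_ee("some cells have zero total counts; run filter_cells_genes() first",
             "ee_divide_by_zero")
  }
  X <- log1p(M$counts / totals * scale)
  if (base != exp(1)) X <- X / log(base)
  X
}

#' Select the most variable genes
#'
#' Keeps the \code{n_top} genes of highest variance of the (log-normalized)
#' expression values, a plain variance-ranking stand-in for variance-
#' stabilizing selection. Ties break deterministically toward the lower gene
#' index.
#'
#' @param X numeric cells-by-genes matrix.
#' @param n_top number of genes to keep (default 2000).
#' @return matrix restricted to the selected genes, in variance order.
#' @export
select_variable_genes <- function(X, n_top = 2000L) {
  X <- as_data_matrix(X, "X")
  if (n_top > ncol(X)) {
    abort_ee("n_top exceeds the number of genes", "ee_invalid_parameter")
  }
  n <- nrow(X)
  mu <- colMeans(X)
  v <- (colSums(X * X) - n * mu^2) / max(1, n - 1)
  ord <- order(-v, seq_along(v))
  X[, ord[seq_len(n_top)], drop = FALSE]
}

#' PCA projection
#'
#' Column-centers the matrix and projects onto the top right singular
#' vectors. Sign convention: each component's largest-magnitude loading is
#' positive. If the matrix rank falls below \code{n_components} the
#' available components are returned with a warning.
#'
#' @param X numeric matrix (samples x features).
#' @param n_components number of components (default 50), at most
#'   \eqn{\min(N - 1, D)}.
#' @return samples-by-components score matrix with attribute
#'   \code{"explained_variance"}.
#' @export
pca_reduce <- function(X, n_components = 50L) {
  X <- as_data_matrix(X, "X")
  n <- nrow(X)
  if (n_components > min(n - 1L, ncol(X))) {
    abort_ee("n_components must be <= min(N - 1, D)", "ee_invalid_parameter")
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  rank_tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > rank_tol)
  k <- n_components
  if (rank < n_components) {
    warn_ee(sprintf("rank %d below requested %d components; returning %d",
                    rank, n_components, rank), "ee_rank_deficient")
    k <- rank
  }
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_star <- which.max(abs(V[, j]))
    if (V[i_star, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(X)
  attr(scores, "explained_variance") <- sv$d[seq_len(k)]^2 / max(1, n - 1)
  scores
}

#' Full preprocessing pipeline
#'
#' \code{filter_cells_genes} then \code{lognormalize} then
#' \code{select_variable_genes} then \code{pca_reduce}.
#'
#' @param M \code{count_matrix}.
#' @param min_features_per_cell,min_cells_per_gene filter thresholds.
#' @param n_top variable genes to keep (clamped to the surviving gene
#'   count).
#' @param n_components PCA components (clamped to the feasible maximum).
#' @param scale log-normalization scale factor.
#' @return PCA score matrix.
#' @export
preprocess_counts <- function(M, min_features_per_cell = 200L,
                              min_cells_per_gene = 50L, n_top = 2000L,
                              n_components = 50L, scale = 1e4) {
  Mf <- filter_cells_genes(M, min_features_per_cell, min_cells_per_gene)
  X <- lognormalize(Mf, scale = scale)
  X <- select_variable_genes(X, n_top = min(n_top, ncol(X)))
  pca_reduce(X, n_components = min(n_components, nrow(X) - 1L, ncol(X)))
}
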