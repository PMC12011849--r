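#' Log counts-per-10k normalization
#'
#' `value = log(1 + 1e4 * count / cell_total)` with the natural log — the
#' de facto single-cell convention. Cells with zero total counts produce
#' all-zero columns with a warning.
#'
#' @param counts nonnegative integer genes x cells matrix (dense or
#'   `Matrix` sparse).
#' @param scale_factor counts-per scaling, default 1e4.
#' @return Dense genes x cells matrix of log-normalized values, with the
#'   normalization parameters in `attr(, "provenance")`.
#' @export
normalize_log_cp10k <- function(counts, scale_factor = 1e4) {
  m <- as.matrix(counts)
  .assert(all(m >= 0), "counts must be nonnegative")
  .assert(all(m == floor(m)), "counts must be integers")
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts produce all-zero columns")
    tot[zero] <- 1
  }
  out <- log1p(sweep(m, 2L, tot / scale_factor, "/"))
  attr(out, "provenance") <- list(scale_factor = scale_factor,
                                  log_base = "natural")
  out
}

#' Z-score each gene across samples
#'
#' Per gene: subtract the mean and divide by the sample standard
#' deviation (n-1 denominator) across samples. Zero-variance genes map to
#' all-zero rows with a warning.
#'
#' @param m numeric matrix.
#' @param sample_axis `"cols"` (default; genes are rows) or `"rows"`.
#' @return Matrix of the same shape.
#' @export
zscore_genes <- function(m, sample_axis = c("cols", "rows")) {
  sample_axis <- match.arg(sample_axis)
  flip <- sample_axis == "rows"
  if (flip) m <- t(m)
  .assert(ncol(m) >= 2L, "need at least 2 samples to z-score")
  mu <- rowMeans(m)
  sdv <- sqrt(.row_vars(m))
  zv <- sdv == 0 | !is.finite(sdv)
  if (any(zv))
    warning(sum(zv), " zero-variance gene(s) mapped to all-zero rows")
  sdv[zv] <- 1
  out <- (m - mu) / sdv
  out[zv, ] <- 0
  if (flip) out <- t(out)
  out
}

#' Select highly variable genes
#'
#' Ranks genes by dispersion (variance / mean of the de-logged normalized
#' values), standardized within 20 equal-frequency mean bins, and returns
#' the top `n_top`. Deterministic; ties broken by gene identifier order.
#' Zero-variance genes are never selected.
#'
#' @param m log-normalized genes x cells matrix with gene rownames.
#' @param n_top number of genes to return.
#' @param n_bins mean bins for dispersion standardization.
#' @return Character vector of `n_top` gene ids, highest dispersion first.
#' @export
select_hvgs <- function(m, n_top = 2000L, n_bins = 20L) {
  .assert(n_top > 0L, "n_top must be positive")
  .assert(n_top <= nrow(m), "n_top exceeds number of genes")
  .assert(!is.null(rownames(m)), "matrix must have gene rownames")
  x <- expm1(m)
  mu <- rowMeans(x)
  v <- .row_vars(x)
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- v > 0
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(n_bins, nrow(m)), labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    s <- stats::sd(disp[sel])
    if (!is.finite(s) || s == 0) s <- 1
    z[sel] <- (disp[sel] - mean(disp[sel])) / s
  }
  z[!keep] <- -Inf
  ord <- order(-z, rownames(m))
  head(rownames(m)[ord][keep[ord]], n_top)
}

#' Principal component analysis of cells
#'
#' Exact truncated singular value decomposition of the column-centered
#' cells x genes matrix. Sign convention: each component is oriented so
#' its largest-magnitude gene loading is positive. Input is expected as a
#' z-scored genes x cells matrix (rows optionally clipped; see
#' `clip`).
#'
#' @param m z-scored genes x cells matrix.
#' @param n_components number of components to keep.
#' @param clip symmetric value bound applied before decomposition to
#'   limit outlier leverage (`Inf` disables); recorded in provenance.
#' @return A `pca_result`: list with `cell_scores` (cells x k),
#'   `gene_loadings` (genes x k), `variance_explained` (length k
#'   proportions), `sdev`.
#' @export
compute_pca <- function(m, n_components = 30L, clip = 10) {
  .assert(n_components >= 1L, "n_components must be positive")
  .assert(n_components <= min(dim(m)),
          "n_components exceeds matrix dimensions")
  m <- pmin(pmax(m, -clip), clip)
  x <- t(m)                              # cells x genes
  x <- sweep(x, 2L, colMeans(x), "-")
  sv <- svd(x, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  total_var <- sum(x^2)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u, 2L, d * flip, "*")
  loadings <- sweep(sv$v, 2L, flip, "*")
  rownames(scores) <- colnames(m)
  rownames(loadings) <- rownames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  structure(list(cell_scores = scores, gene_loadings = loadings,
                 variance_explained = d^2 / total_var, sdev = d / sqrt(nrow(x) - 1),
                 provenance = list(clip = clip, centered = TRUE)),
            class = "pca_result")
}

#' Rank genes by correlation with a principal component
#'
#' Pearson correlation of each gene's expression across cells with the
#' component's cell scores, sorted descending. This is the rank statistic
#' fed to pre-ranked GSEA. Zero-variance genes get correlation 0.
#'
#' @param m genes x cells expression matrix with rownames.
#' @param pca a [compute_pca()] result on the same cells.
#' @param component component index (default 1).
#' @return data.frame (gene, cor) sorted by decreasing correlation, ties
#'   broken by gene id.
#' @export
rank_genes_by_pc <- function(m, pca, component = 1L) {
  .assert(component >= 1L && component <= ncol(pca$cell_scores),
          "component does not exist")
  s <- pca$cell_scores[, component]
  .assert(ncol(m) == length(s), "matrix and PCA cell counts differ")
  sdv <- sqrt(.row_vars(m))
  r <- suppressWarnings(as.vector(stats::cor(t(m), s)))
  r[sdv == 0 | !is.finite(r)] <- 0
  out <- data.frame(gene = rownames(m), cor = r, stringsAsFactors = FALSE)
  out[order(-out$cor, out$gene), , drop = FALSE]
}

#' Graph-based clustering of cells
#'
#' Builds a shared-nearest-neighbor (Jaccard-weighted kNN) graph on the
#' PCA cell scores and partitions it with Leiden community detection
#' (modularity objective) under a recorded seed. Labels are stable under
#' cell reordering up to renaming.
#'
#' @param pca a [compute_pca()] result.
#' @param k_neighbors neighbors per cell for the kNN graph.
#' @param resolution Leiden resolution; smaller values yield fewer
#'   clusters.
#' @param seed RNG seed for the Leiden refinement.
#' @param n_pcs number of leading components used (default: all).
#' @param prune SNN edges with Jaccard weight below this are dropped.
#' @return Integer cluster labels named by cell.
#' @export
cluster_cells <- function(pca, k_neighbors = 20L, resolution = 0.8,
                          seed = 1L, n_pcs = NULL, prune = 1 / 15) {
  .assert(k_neighbors > 0L, "k_neighbors must be positive")
  scores <- pca$cell_scores
  if (!is.null(n_pcs)) scores <- scores[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(scores)
  .assert(k_neighbors < n, "k_neighbors must be smaller than cell count")
  d <- as.matrix(stats::dist(scores))
  # kNN sets include the cell itself for a symmetric Jaccard overlap
  nn <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ], decreasing = FALSE)
    ord[seq_len(k_neighbors + 1L)]
  })
  nn_mat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) nn_mat[i, nn[[i]]] <- TRUE
  shared <- tcrossprod(nn_mat * 1)
  k1 <- k_neighbors + 1L
  jac <- shared / (2 * k1 - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = 5L)
  labels <- igraph::membership(comm)
  # canonical renaming by order of first appearance, for permutation
  # invariance up to labels
  labels <- as.integer(factor(labels, levels = unique(labels)))
  names(labels) <- rownames(scores)
  labels
}
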