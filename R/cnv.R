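# Reference-relative, genome-ordered inference of copy-number profiles
# from expression: center on reference cells, clip, smooth along each
# chromosome, recenter per cell, then partition cells by profile burden.

#' Infer a smoothed copy-number profile from expression
#'
#' Single-pass pipeline: (1) subtract the reference-cell mean per gene;
#' (2) clip to `±clip`; (3) within each chromosome, replace each value
#' by the centered moving average over `window` genes (truncated at
#' chromosome ends, never spanning chromosomes); (4) subtract each
#' cell's median profile value; (5) clamp to `±clip`. Genes are sorted
#' internally by (chromosome, start, id); genes without positions are
#' dropped with a warning (at most 20% may be missing).
#'
#' @param norm log-normalized genes x cells matrix.
#' @param gene_meta data.frame with columns gene, chrom, start.
#' @param ref_cells reference cell ids or indices (nonempty).
#' @param window odd moving-average width in genes.
#' @param clip symmetric value bound.
#' @return A `cnv_profile`: list with `matrix` (cells x genes, genome
#'   order), `gene_order` (data.frame gene/chrom/start), `window`,
#'   `clip`, `reference_cells`.
#' @export
infer_cnv_profile <- function(norm, gene_meta, ref_cells, window = 101L,
                              clip = 3) {
  .assert(length(ref_cells) > 0L, "reference cell set is empty")
  .assert(window %% 2L == 1L, "window must be odd")
  if (is.character(ref_cells)) ref_cells <- match(ref_cells, colnames(norm))
  .assert(!anyNA(ref_cells), "unknown reference cells")
  known <- rownames(norm) %in% gene_meta$gene
  .assert(mean(known) >= 0.8,
          "positions known for fewer than 80% of genes")
  if (any(!known))
    warning(sum(!known), " gene(s) without positions dropped")
  norm <- norm[known, , drop = FALSE]
  gm <- gene_meta[match(rownames(norm), gene_meta$gene), ]
  ord <- order(gm$chrom, gm$start, gm$gene)
  norm <- norm[ord, , drop = FALSE]
  gm <- gm[ord, ]
  per_chrom <- table(gm$chrom)
  .assert(all(per_chrom >= window),
          "every used chromosome must hold at least `window` genes")

  rel <- norm - rowMeans(norm[, ref_cells, drop = FALSE])
  rel <- pmin(pmax(rel, -clip), clip)

  half <- (window - 1L) / 2L
  smooth <- rel
  for (ch in unique(gm$chrom)) {
    rows <- which(gm$chrom == ch)
    block <- rel[rows, , drop = FALSE]
    n <- nrow(block)
    cs <- apply(block, 2L, cumsum)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    upper <- cs[hi, , drop = FALSE]
    lower <- rbind(0, cs)[lo, , drop = FALSE]
    smooth[rows, ] <- (upper - lower) / (hi - lo + 1L)
  }
  prof <- t(smooth)
  med <- apply(prof, 1L, stats::median)
  prof <- prof - med
  prof <- pmin(pmax(prof, -clip), clip)
  structure(list(matrix = prof,
                 gene_order = gm[, c("gene", "chrom", "start")],
                 window = window, clip = clip,
                 reference_cells = colnames(norm)[ref_cells]),
            class = "cnv_profile")
}

#' Subcluster cells by copy-number profile
#'
#' Average-linkage hierarchical clustering of cells on Euclidean profile
#' distance, cut into `k` major groups. Because average linkage tends to
#' split off singleton outliers first, the dendrogram is cut at
#' increasing granularity until `k` clusters of at least `min_cells`
#' cells emerge; cells in smaller branches are absorbed into the major
#' cluster with the nearest centroid. Each cell's burden is the mean
#' absolute profile value; clusters are renamed `SCNV_hi` ... `SCNV_lo`
#' by descending mean burden. When the top and bottom clusters differ in
#' mean burden by less than `flat_tol` a "no distinct SCNV structure"
#' warning is raised.
#'
#' @param profile a [infer_cnv_profile()] object.
#' @param k number of major clusters (>= 2).
#' @param min_cells minimum size of a major cluster (default 1% of
#'   cells, at least 2).
#' @param flat_tol burden-difference threshold for the flatness warning.
#' @return list with `cluster` (named cell -> label), `burden` (named
#'   per-cell mean |profile|), `cluster_burden` (named mean burden per
#'   cluster, descending).
#' @export
subcluster_cnv <- function(profile, k = 2L, min_cells = NULL,
                           flat_tol = 0.02) {
  m <- profile$matrix
  .assert(k >= 2L, "k must be at least 2")
  .assert(k <= nrow(m), "k exceeds the number of cells")
  if (is.null(min_cells)) min_cells <- max(2L, ceiling(0.01 * nrow(m)))
  hc <- stats::hclust(stats::dist(m), method = "average")
  raw <- stats::cutree(hc, k = k)
  for (kk in k:min(nrow(m), 10L * k)) {
    cand <- stats::cutree(hc, k = kk)
    big <- names(which(table(cand) >= min_cells))
    if (length(big) >= k) {
      big <- names(sort(table(cand)[big], decreasing = TRUE))[seq_len(k)]
      centroids <- vapply(big, function(cl) {
        colMeans(m[cand == as.integer(cl), , drop = FALSE])
      }, numeric(ncol(m)))
      small <- which(!(cand %in% as.integer(big)))
      if (length(small) > 0L) {
        d2 <- vapply(seq_len(k), function(j) {
          rowSums((m[small, , drop = FALSE] -
                     matrix(centroids[, j], length(small), ncol(m),
                            byrow = TRUE))^2)
        }, numeric(length(small)))
        d2 <- matrix(d2, nrow = length(small))
        cand[small] <- as.integer(big)[max.col(-d2, ties.method = "first")]
      }
      raw <- cand
      break
    }
  }
  burden <- rowMeans(abs(m))
  cl_burden <- sort(tapply(burden, raw, mean), decreasing = TRUE)
  lab <- if (k == 2L) c("SCNV_hi", "SCNV_lo") else
    c("SCNV_hi", paste0("SCNV_mid", seq_len(k - 2L)), "SCNV_lo")
  names(lab) <- names(cl_burden)
  cluster <- stats::setNames(lab[as.character(raw)], rownames(m))
  if (max(cl_burden) - min(cl_burden) < flat_tol)
    warning("no distinct SCNV structure: cluster burdens differ by less than ",
            flat_tol)
  list(cluster = cluster, burden = burden,
       cluster_burden = stats::setNames(as.numeric(cl_burden), lab))
}
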