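# Consensus weighted co-expression network construction on metacells:
# signed adjacency -> topological overlap -> per-donor scaling ->
# consensus -> static tree cut -> eigengenes / kME / trait correlation.

#' Aggregate cells into metacells
#'
#' Correlation estimates on sparse single cells are noisy; averaging each
#' cell with its nearest neighbors in PC space sharpens gene-gene
#' correlation while preserving donor identity. Per donor, seed cells are
#' visited in a seeded random order; each accepted metacell is the mean
#' of the seed and its `k_agg - 1` nearest neighbors, and a candidate is
#' rejected when it shares more than `max_shared` cells with any accepted
#' metacell.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param pca [compute_pca()] result on the same cells.
#' @param donor per-cell donor labels (aligned to columns of `norm`).
#' @param k_agg cells aggregated per metacell; `k_agg = 1` returns the
#'   cells themselves.
#' @param max_shared maximum cell overlap between two metacells.
#' @param seed RNG seed for the visiting order.
#' @param n_pcs leading components used for the neighbor search.
#' @return A `metacells` object: list with `expr` (genes x metacells,
#'   arithmetic mean of members), `membership` (list of member cell ids),
#'   `donor` (per metacell).
#' @export
make_metacells <- function(norm, pca, donor, k_agg = 25L, max_shared = 10L,
                           seed = 1L, n_pcs = NULL) {
  .assert(ncol(norm) == length(donor), "donor labels must align to cells")
  scores <- pca$cell_scores
  if (!is.null(n_pcs)) scores <- scores[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  expr_cols <- list()
  membership <- list()
  mc_donor <- character(0)
  for (d in unique(donor)) {
    idx <- which(donor == d)
    if (length(idx) < k_agg) {
      warning("donor ", d, " has fewer than k_agg cells; skipped")
      next
    }
    dd <- as.matrix(stats::dist(scores[idx, , drop = FALSE]))
    order_seeds <- sample(seq_along(idx))
    used <- list()
    for (s in order_seeds) {
      nb <- order(dd[s, ])[seq_len(k_agg)]   # includes s itself
      ok <- all(vapply(used, function(u) {
        length(intersect(u, nb)) <= max_shared
      }, logical(1)))
      if (!ok) next
      used[[length(used) + 1L]] <- nb
      cells <- idx[nb]
      expr_cols[[length(expr_cols) + 1L]] <-
        rowMeans(norm[, cells, drop = FALSE])
      membership[[length(membership) + 1L]] <- colnames(norm)[cells]
      mc_donor <- c(mc_donor, d)
    }
  }
  .assert(length(expr_cols) > 0L, "no metacells could be formed")
  expr <- do.call(cbind, expr_cols)
  colnames(expr) <- sprintf("mc%04d", seq_len(ncol(expr)))
  names(membership) <- colnames(expr)
  structure(list(expr = expr, membership = membership, donor = mc_donor,
                 params = list(k_agg = k_agg, max_shared = max_shared,
                               seed = seed)),
            class = "metacells")
}

#' Summarize a per-cell value over metacells
#'
#' Maps any per-cell quantity (group indicator, score, flag) to metacells
#' by applying `fun` over each metacell's member cells.
#'
#' @param mc a [make_metacells()] object.
#' @param cell_values named vector (names = cell ids).
#' @param fun summary function, default [mean()].
#' @return Named vector, one value per metacell.
#' @export
metacell_summary <- function(mc, cell_values, fun = mean) {
  vapply(mc$membership, function(cells) {
    fun(cell_values[cells])
  }, numeric(1))
}

# signed adjacency from a correlation matrix
.signed_adjacency <- function(cormat, beta) ((1 + cormat) / 2)^beta

#' Pick the soft-thresholding power per donor
#'
#' For each donor and candidate power, builds the signed adjacency on
#' that donor's metacells, computes per-gene connectivity, and regresses
#' `log10(freq(k))` on `log10(k)` over 10 connectivity bins. Returns the
#' smallest power whose scale-free fit reaches `rsq_target`, else the
#' power maximizing the fit with a warning.
#'
#' @param mc a [make_metacells()] object.
#' @param powers ascending candidate integer powers.
#' @param rsq_target scale-free fit threshold (default 0.8).
#' @return Named integer vector of chosen powers, one per donor, with the
#'   fit table in `attr(, "fits")`.
#' @export
pick_soft_threshold <- function(mc, powers = 1:20, rsq_target = 0.8) {
  .assert(length(powers) > 0L && !is.unsorted(powers),
          "powers must be a nonempty ascending list")
  donors <- unique(mc$donor)
  fits <- list()
  chosen <- stats::setNames(integer(length(donors)), donors)
  for (d in donors) {
    expr <- mc$expr[, mc$donor == d, drop = FALSE]
    keep <- sqrt(.row_vars(expr)) > 0
    cormat <- stats::cor(t(expr[keep, , drop = FALSE]))
    rsqs <- vapply(powers, function(b) {
      adj <- .signed_adjacency(cormat, b)
      k <- rowSums(adj) - 1
      .scale_free_rsq(k)
    }, numeric(1))
    ok <- which(rsqs >= rsq_target)
    if (length(ok) > 0L) {
      chosen[d] <- powers[ok[1L]]
    } else {
      chosen[d] <- powers[which.max(rsqs)]
      warning("donor ", d, ": no power reached R^2 >= ", rsq_target,
              "; using the best fit (R^2 = ",
              signif(max(rsqs), 3), ")")
    }
    fits[[d]] <- data.frame(power = powers, rsq = rsqs)
  }
  attr(chosen, "fits") <- fits
  chosen
}

# scale-free topology fit: R^2 of log10(freq) ~ log10(mean k) over bins
.scale_free_rsq <- function(k, n_bins = 10L) {
  if (length(unique(round(k, 10))) < 2L) return(0)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3L) {
    warning("fewer than 3 occupied connectivity bins; fit degenerate")
    return(0)
  }
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  summary(fit)$r.squared
}

#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with Pearson correlation
#' across metacells; `a_ii = 1`. Zero-variance genes are excluded with a
#' warning.
#'
#' @param mc a [make_metacells()] object, or a genes x samples matrix.
#' @param beta soft-thresholding power.
#' @param donor restrict to one donor's metacells (optional).
#' @return Symmetric gene x gene adjacency with entries in \[0, 1\].
#' @export
build_adjacency <- function(mc, beta, donor = NULL) {
  expr <- if (inherits(mc, "metacells")) mc$expr else mc
  if (!is.null(donor) && inherits(mc, "metacells"))
    expr <- expr[, mc$donor == donor, drop = FALSE]
  .assert(ncol(expr) >= 3L, "need at least 3 metacells")
  v <- .row_vars(expr)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) excluded from the network")
    expr <- expr[v > 0, , drop = FALSE]
  }
  adj <- .signed_adjacency(stats::cor(t(expr)), beta)
  diag(adj) <- 1
  adj
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. Measures how much two genes share network neighbors in
#' addition to their direct connection.
#'
#' @param adj symmetric adjacency with unit diagonal.
#' @return Symmetric TOM with entries in \[0, 1\] and unit diagonal.
#' @export
compute_tom <- function(adj) {
  .assert(isSymmetric(unname(adj), tol = 1e-10), "adjacency must be symmetric")
  .assert(all(abs(diag(adj) - 1) < 1e-10), "adjacency diagonal must be 1")
  a2 <- adj %*% adj
  l <- a2 - 2 * adj                 # removes u = i and u = j terms (diag 1)
  k <- rowSums(adj) - 1
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  (tom + t(tom)) / 2
}

#' Consensus topological overlap across donors
#'
#' Each donor TOM is rescaled so its 95th percentile (off-diagonal)
#' matches the first donor's, then combined element-wise at quantile `q`
#' across donors; the default `q = 0` is the parallel minimum — the
#' classical consensus: an edge is only as strong as its weakest donor
#' support.
#'
#' @param toms list of TOMs sharing gene order.
#' @param q consensus quantile in \[0, 1\].
#' @param scale_quantile percentile used for cross-donor calibration.
#' @return Consensus TOM.
#' @export
consensus_tom <- function(toms, q = 0, scale_quantile = 0.95) {
  .assert(length(toms) >= 1L, "need at least one TOM")
  gn <- rownames(toms[[1L]])
  for (tm in toms)
    .assert(identical(rownames(tm), gn) && identical(colnames(tm), gn),
            "TOMs must share an identical gene set and order")
  off <- upper.tri(toms[[1L]])
  ref_q <- stats::quantile(toms[[1L]][off], scale_quantile)
  scaled <- lapply(toms, function(tm) {
    qd <- stats::quantile(tm[off], scale_quantile)
    if (qd > 0) tm <- tm * (ref_q / qd)
    tm
  })
  cons <- scaled[[1L]]
  if (length(scaled) > 1L) {
    if (q == 0) {
      for (i in 2:length(scaled)) cons <- pmin(cons, scaled[[i]])
    } else if (q == 1) {
      for (i in 2:length(scaled)) cons <- pmax(cons, scaled[[i]])
    } else {
      arr <- array(unlist(scaled), dim = c(dim(cons), length(scaled)))
      cons[] <- apply(arr, c(1, 2), stats::quantile, probs = q)
    }
  }
  cons <- pmin(cons, 1)
  diag(cons) <- 1
  dimnames(cons) <- dimnames(toms[[1L]])
  cons
}

# module naming follows the size-ranked color convention
.module_colors <- c("turquoise", "blue", "brown", "yellow", "green",
                    "red", "black", "pink", "magenta", "purple",
                    "greenyellow", "tan", "salmon", "cyan", "midnightblue",
                    "lightcyan", "grey60", "lightgreen", "lightyellow")

#' Detect modules by static cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' `1 - TOM`, cut at a fixed height; branches smaller than
#' `min_module_size` are merged into `"grey"` (unassigned). Modules are
#' named by size rank with the conventional color sequence.
#'
#' @param tom topological overlap matrix with gene dimnames.
#' @param min_module_size smallest retained module.
#' @param cut_height static cut height on the dendrogram.
#' @return Named character vector gene -> module label.
#' @export
detect_modules <- function(tom, min_module_size = 25L, cut_height = 0.99) {
  genes <- rownames(tom)
  .assert(!is.null(genes), "TOM must carry gene names")
  diss <- 1 - tom
  # enforce exact symmetry for dist()
  diss <- (diss + t(diss)) / 2
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  assignment <- rep("grey", length(genes))
  names(assignment) <- genes
  if (length(keep) == 0L) {
    warning("all genes unassigned (grey); no branch reached min_module_size")
    return(assignment)
  }
  keep <- keep[order(-sizes[keep])]
  labels <- .module_colors[seq_along(keep)]
  if (length(keep) > length(.module_colors))
    labels <- c(.module_colors,
                paste0("module",
                       seq_len(length(keep) - length(.module_colors))))[
                         seq_along(keep)]
  for (i in seq_along(keep)) assignment[raw == as.integer(keep[i])] <- labels[i]
  assignment
}

#' Module eigengenes
#'
#' Per module: the first principal component of the z-scored member-gene
#' submatrix across metacells, oriented to correlate positively with the
#' module's average expression and scaled to unit variance. A single-gene
#' module's eigengene is that z-scored gene.
#'
#' @param mc a [make_metacells()] object or genes x samples matrix.
#' @param assignment gene -> module vector from [detect_modules()];
#'   `"grey"` is ignored.
#' @return metacells x modules eigengene matrix.
#' @export
module_eigengenes <- function(mc, assignment) {
  expr <- if (inherits(mc, "metacells")) mc$expr else mc
  mods <- setdiff(unique(assignment), "grey")
  .assert(length(mods) > 0L, "assignment contains no modules")
  me <- vapply(mods, function(m) {
    genes <- names(assignment)[assignment == m]
    sub <- expr[genes, , drop = FALSE]
    z <- zscore_genes(sub)
    if (nrow(z) == 1L) {
      e <- as.vector(z)
    } else {
      sv <- svd(t(z), nu = 1L, nv = 0L)
      e <- sv$u[, 1L] * sv$d[1L]
    }
    avg <- colMeans(z)
    if (stats::sd(e) > 0 && stats::cor(e, avg) < 0) e <- -e
    if (stats::sd(e) > 0) e <- as.vector(scale(e))
    e
  }, numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  me
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene with every module eigengene across
#' metacells. Zero-variance genes get kME 0 (flagged in
#' `attr(, "zero_variance")`).
#'
#' @param mc a [make_metacells()] object or genes x samples matrix.
#' @param eigengenes a [module_eigengenes()] matrix.
#' @return genes x modules kME matrix.
#' @export
compute_kme <- function(mc, eigengenes) {
  expr <- if (inherits(mc, "metacells")) mc$expr else mc
  .assert(nrow(eigengenes) == ncol(expr),
          "eigengenes must align to metacells")
  kme <- suppressWarnings(stats::cor(t(expr), eigengenes))
  zv <- sqrt(.row_vars(expr)) == 0
  kme[zv, ] <- 0
  kme[!is.finite(kme)] <- 0
  attr(kme, "zero_variance") <- rownames(expr)[zv]
  kme
}

#' Reassign genes to their best-fitting module by kME
#'
#' Optional cleanup pass after the static cut: a gene moves to its
#' maximum-kME module when that kME exceeds the kME for its current
#' module by more than `gap`. Grey genes are never reassigned.
#'
#' @param assignment gene -> module vector.
#' @param kme [compute_kme()] matrix.
#' @param gap minimum kME advantage required to move a gene.
#' @return Updated assignment.
#' @export
reassign_by_kme <- function(assignment, kme, gap = 0.1) {
  for (g in names(assignment)) {
    cur <- assignment[g]
    if (cur == "grey" || !(cur %in% colnames(kme))) next
    best <- colnames(kme)[which.max(kme[g, ])]
    if (best != cur && kme[g, best] - kme[g, cur] > gap)
      assignment[g] <- best
  }
  assignment
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each trait
#' (0/1 indicator or real covariate aligned to metacells), with the
#' two-sided t-test p-value. Constant traits are dropped with a warning.
#'
#' @param eigengenes [module_eigengenes()] matrix.
#' @param traits metacells x traits data.frame or matrix.
#' @return list with matrices `cor` and `p` (modules x traits).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  .assert(nrow(traits) == nrow(eigengenes),
          "traits must align to metacells")
  const <- apply(traits, 2L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant trait(s) dropped: ",
            paste(colnames(traits)[const], collapse = ", "))
    traits <- traits[, !const, drop = FALSE]
  }
  .assert(ncol(traits) > 0L, "no usable traits")
  r <- stats::cor(eigengenes, traits)
  n <- nrow(eigengenes)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(cor = r, p = p)
}

#' Top hub genes of a module
#'
#' Member genes ranked by descending kME for their module; ties broken by
#' gene id. Asking for more genes than the module holds returns the full
#' ranked list with a warning.
#'
#' @param kme [compute_kme()] matrix.
#' @param assignment gene -> module vector.
#' @param module module label.
#' @param n number of hub genes.
#' @return Character vector of gene ids.
#' @export
top_hub_genes <- function(kme, assignment, module, n = 10L) {
  .assert(module %in% assignment, "module not present in assignment")
  genes <- names(assignment)[assignment == module]
  if (n > length(genes)) {
    warning("module ", module, " has only ", length(genes), " genes")
    n <- length(genes)
  }
  ord <- order(-kme[genes, module], genes)
  genes[ord][seq_len(n)]
}
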