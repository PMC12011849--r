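# Normalization, z-scoring, HVG selection, PCA, PC ranking, clustering.

test_that("log CP10K normalization matches hand computation", {
  counts <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  norm <- normalize_log_cp10k(counts)
  expect_equal(norm[, 1], c(g1 = log(10001), g2 = 0))
  # scale invariance: doubling every count in a cell leaves it unchanged
  m <- matrix(rpois(40, 5), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:5)))
  doubled <- m
  doubled[, 3] <- 2L * doubled[, 3]
  expect_equal(normalize_log_cp10k(m)[, 3], normalize_log_cp10k(doubled)[, 3])
  expect_error(normalize_log_cp10k(matrix(-1, 1, 2)), "nonnegative")
})

test_that("zero-total cells produce all-zero columns with a warning", {
  m <- matrix(c(1L, 2L, 0L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(norm <- normalize_log_cp10k(m), "zero total")
  expect_equal(unname(norm[, "b"]), c(0, 0))
})

test_that("gene z-scoring matches its definition and is idempotent", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  expect_warning(z <- zscore_genes(m), "zero-variance")
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  set.seed(1)
  m2 <- matrix(rnorm(60), 6, 10)
  z1 <- zscore_genes(m2)
  expect_lt(max(abs(rowMeans(z1))), 1e-12)
  expect_equal(zscore_genes(z1), z1, tolerance = 1e-10)
  expect_error(zscore_genes(m2[, 1, drop = FALSE]), "2 samples")
  # rows as samples
  expect_equal(zscore_genes(t(m2), sample_axis = "rows"), t(z1))
})

test_that("HVG selection is deterministic and excludes flat genes", {
  set.seed(2)
  m <- matrix(rpois(100 * 30, 4), 100, 30,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  norm <- normalize_log_cp10k(m)
  norm[7, ] <- 0.5   # constant gene on the normalized scale
  hv_all <- select_hvgs(norm, nrow(norm) - 1L)
  expect_false("g007" %in% hv_all)
  expect_identical(select_hvgs(norm, 10L), select_hvgs(norm, 10L))
  expect_error(select_hvgs(norm, 0L), "positive")
  expect_error(select_hvgs(norm, 1000L), "exceeds")
})

test_that("planted module genes are enriched among HVGs", {
  sc <- fixture_sim()
  hv <- select_hvgs(fixture_norm(), 200L)
  mod_genes <- sc$gene_meta$gene[sc$gene_meta$module != "none"]
  frac_in_top <- mean(mod_genes %in% hv)
  frac_overall <- 200 / nrow(sc$counts)
  expect_gt(frac_in_top, 2 * frac_overall)
})

test_that("PCA is an exact truncated SVD with the stated sign convention", {
  set.seed(3)
  # rank-1 matrix: one component explains everything
  u <- rnorm(30); v <- rnorm(20)
  m1 <- outer(u - mean(u), v)
  dimnames(m1) <- list(paste0("g", 1:30), paste0("c", 1:20))
  p1 <- compute_pca(m1, 2L, clip = Inf)
  expect_gt(p1$variance_explained[1], 0.999)
  # full reconstruction
  m <- matrix(rnorm(25 * 40), 25, 40,
              dimnames = list(paste0("g", 1:25), paste0("c", 1:40)))
  z <- zscore_genes(m)
  p <- compute_pca(z, 25L, clip = Inf)
  recon <- p$cell_scores %*% t(p$gene_loadings)
  centered <- t(z) - colMeans(t(z))[col(t(z))]
  centered <- scale(t(z), center = TRUE, scale = FALSE)
  expect_lt(sqrt(sum((recon - centered)^2)), 1e-6)
  # orthonormal loadings, non-increasing variance, total <= 1
  expect_equal(unname(crossprod(p$gene_loadings)), diag(25),
               tolerance = 1e-8)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_lte(sum(p$variance_explained), 1 + 1e-12)
  # sign convention: largest-magnitude loading positive
  for (j in 1:5) {
    l <- p$gene_loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_error(compute_pca(z, 100L), "exceeds")
})

test_that("PC1 separates two planted groups", {
  set.seed(4)
  n <- 500
  m <- cbind(matrix(rnorm(80 * n), 80, n),
             matrix(rnorm(80 * n, mean = 1.5), 80, n))
  dimnames(m) <- list(paste0("g", 1:80), paste0("c", 1:(2 * n)))
  p <- compute_pca(zscore_genes(m), 5L)
  lab <- rep(c(FALSE, TRUE), each = n)
  auc <- suppressWarnings(roc_auc(p$cell_scores[, 1], lab)$auc)
  expect_gte(max(auc, 1 - auc), 0.95)
})

test_that("genes are ranked by Pearson correlation with the component", {
  # 3-cell hand example: cor((1,2,3), (1,2,4)) = 0.982
  m <- rbind(gA = c(1, 2, 3), gB = c(3, 1, 2))
  fake_pca <- structure(list(cell_scores = cbind(PC1 = c(1, 2, 4))),
                        class = "pca_result")
  rk <- rank_genes_by_pc(m, fake_pca, 1L)
  expect_equal(rk$cor[rk$gene == "gA"], 0.982, tolerance = 1e-3)
  # gene equal to scores ranks first with r = 1; its negative ranks last
  m2 <- rbind(pos = c(1, 2, 4), neg = -c(1, 2, 4), flat = c(1, 1, 1))
  rk2 <- rank_genes_by_pc(m2, fake_pca, 1L)
  expect_identical(rk2$gene[1], "pos")
  expect_identical(rk2$gene[3], "neg")
  expect_equal(rk2$cor[1], 1)
  expect_equal(rk2$cor[3], -1)
  expect_equal(rk2$cor[rk2$gene == "flat"], 0)
  expect_error(rank_genes_by_pc(m2, fake_pca, 5L), "component")
})

test_that("Leiden clustering separates well-separated blobs exactly", {
  set.seed(5)
  n <- 80
  scores <- rbind(matrix(rnorm(n * 2), n, 2),
                  matrix(rnorm(n * 2, mean = 10), n, 2))
  rownames(scores) <- paste0("c", seq_len(2 * n))
  pca <- structure(list(cell_scores = scores), class = "pca_result")
  cl <- cluster_cells(pca, k_neighbors = 10L, resolution = 0.1, seed = 1L)
  truth <- rep(1:2, each = n)
  expect_equal(adjusted_rand_index(cl, truth), 1.0)
  # permutation invariance up to relabeling
  perm <- sample(2 * n)
  pca2 <- structure(list(cell_scores = scores[perm, ]), class = "pca_result")
  cl2 <- cluster_cells(pca2, k_neighbors = 10L, resolution = 0.1, seed = 1L)
  expect_equal(adjusted_rand_index(cl2, truth[perm]), 1.0)
  # vanishing resolution on a connected graph collapses to one cluster
  cl3 <- cluster_cells(pca, k_neighbors = 150L, resolution = 1e-4, seed = 1L)
  expect_equal(length(unique(cl3)), 1L)
  expect_error(cluster_cells(pca, k_neighbors = 0L), "positive")
})

test_that("clustering recovers the planted condition structure", {
  sc <- fixture_sim()
  cl <- cluster_cells(fixture_pca(), k_neighbors = 20L, resolution = 0.8,
                      seed = 1L)
  truth <- paste0(sc$cell_meta$group,
                  ifelse(sc$cell_meta$resistant, "_r", ""))
  expect_gte(adjusted_rand_index(cl, truth), 0.8)
})
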