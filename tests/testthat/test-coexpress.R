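# Metacells, soft threshold, adjacency, TOM, consensus, module
# detection, eigengenes, kME, trait correlation, hubs.

test_that("metacells with k_agg = 1 are the cells themselves", {
  norm <- fixture_norm()[, 1:60]
  sc <- fixture_sim()
  pca <- structure(list(cell_scores = fixture_pca()$cell_scores[1:60, ]),
                   class = "pca_result")
  mc <- make_metacells(norm, pca, sc$cell_meta$donor[1:60], k_agg = 1L,
                       max_shared = 0L, seed = 1L)
  expect_equal(ncol(mc$expr), 60L)
  ord <- match(colnames(norm), vapply(mc$membership, `[[`, character(1), 1L))
  expect_equal(unname(mc$expr[, ord]), unname(norm), tolerance = 1e-12)
})

test_that("metacell expression is the exact mean of its members", {
  norm <- fixture_norm()
  sc <- fixture_sim()
  mc <- make_metacells(norm, fixture_pca(), sc$cell_meta$donor,
                       k_agg = 25L, max_shared = 10L, seed = 2L)
  for (i in c(1L, ncol(mc$expr))) {
    members <- mc$membership[[i]]
    expect_equal(length(members), 25L)
    expect_equal(mc$expr[, i], rowMeans(norm[, members]), tolerance = 1e-12)
  }
  # aggregation sharpens module co-expression relative to raw cells
  tol_genes <- sc$gene_meta$gene[sc$gene_meta$module == "mod_tolerant"][1:20]
  cor_cells <- stats::cor(t(norm[tol_genes, ]))
  cor_mc <- stats::cor(t(mc$expr[tol_genes, ]))
  off <- upper.tri(cor_cells)
  expect_gt(mean(cor_mc[off]), mean(cor_cells[off]))
})

test_that("soft threshold selection matches an independent implementation", {
  mc <- structure(list(), class = "metacells")
  set.seed(10)
  # block-structured expression: 3 latent factors over 90 genes
  n_mc <- 60
  f <- matrix(rnorm(3 * n_mc), 3, n_mc)
  expr <- do.call(rbind, lapply(1:3, function(b) {
    matrix(rep(f[b, ], each = 30), 30, n_mc) * 0.8 +
      matrix(rnorm(30 * n_mc, sd = 0.6), 30, n_mc)
  }))
  rownames(expr) <- sprintf("g%02d", 1:90)
  mc$expr <- expr
  mc$donor <- rep("D1", n_mc)
  powers <- 1:12
  chosen <- suppressWarnings(pick_soft_threshold(mc, powers))
  # independent oracle: re-derive the criterion with separate code
  cormat <- stats::cor(t(expr))
  rsq_of <- function(beta) {
    adj <- ((1 + cormat) / 2)^beta
    k <- colSums(adj) - 1
    brk <- seq(min(k), max(k), length.out = 11L)
    bin <- findInterval(k, brk, rightmost.closed = TRUE)
    freq <- table(bin)
    kbar <- tapply(k, bin, mean)
    keep <- freq > 0 & kbar > 0
    if (sum(keep) < 3) return(0)
    stats::cor(log10(as.numeric(freq[keep])), log10(kbar[keep]))^2
  }
  rsqs <- vapply(powers, rsq_of, numeric(1))
  oracle <- if (any(rsqs >= 0.8)) powers[which(rsqs >= 0.8)[1]] else
    powers[which.max(rsqs)]
  expect_lte(abs(chosen[["D1"]] - oracle), 2L)
  # gene-order invariance
  mc2 <- mc
  perm <- sample(nrow(expr))
  mc2$expr <- expr[perm, ]
  chosen2 <- suppressWarnings(pick_soft_threshold(mc2, powers))
  expect_identical(unname(chosen), unname(chosen2))
})

test_that("degenerate connectivity falls back with a warning", {
  mc <- structure(list(expr = NULL, donor = rep("D1", 10)),
                  class = "metacells")
  base <- seq_len(10)
  mc$expr <- rbind(g1 = base, g2 = 2 * base + 3, g3 = 5 * base)
  expect_warning(pick_soft_threshold(mc, 1:5), "degenerate|best fit")
})

test_that("signed adjacency matches its closed form", {
  a <- rep(c(-1, 1), 4)
  d <- rep(c(-1, -1, 1, 1), 2)
  m <- rbind(g1 = a, g2 = 2 * a + 3, g3 = -a, g4 = d)
  adj <- build_adjacency(m, beta = 6)
  expect_equal(adj["g1", "g2"], 1)
  expect_equal(adj["g1", "g3"], 0)
  expect_equal(adj["g1", "g4"], (1 / 2)^6)   # cor 0 -> 0.015625
  expect_true(all(adj >= 0 & adj <= 1))
  # zero-variance gene excluded with warning
  m2 <- rbind(m, g5 = rep(1, 8))
  expect_warning(adj2 <- build_adjacency(m2, 6), "zero-variance")
  expect_false("g5" %in% rownames(adj2))
})

test_that("TOM matches the hand example and a brute-force oracle", {
  adj3 <- matrix(0.5, 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  diag(adj3) <- 1
  tom3 <- compute_tom(adj3)
  expect_equal(tom3[1, 2], 0.5)     # (0.25 + 0.5) / (1 + 1 - 0.5)
  # zero off-diagonal adjacency gives zero off-diagonal TOM
  eye <- diag(4)
  dimnames(eye) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(compute_tom(eye), eye)
  # brute-force triple loop on random instances
  set.seed(11)
  for (rep in 1:3) {
    n <- 20
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tom <- compute_tom(a)
    oracle <- diag(n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      oracle[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    expect_lt(max(abs(tom - oracle)), 1e-12)
    expect_true(isSymmetric(unname(tom)))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  expect_error(compute_tom(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("consensus TOM is the scaled parallel minimum", {
  set.seed(12)
  n <- 15
  a <- matrix(runif(n * n, 0, 0.9), n, n); a <- (a + t(a)) / 2; diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  t1 <- compute_tom(a)
  expect_equal(consensus_tom(list(t1, t1)), t1, tolerance = 1e-12)
  b <- matrix(runif(n * n, 0, 0.9), n, n); b <- (b + t(b)) / 2; diag(b) <- 1
  dimnames(b) <- dimnames(a)
  t2 <- compute_tom(b)
  cons <- consensus_tom(list(t1, t2))
  off <- upper.tri(cons)
  q95 <- stats::quantile(t1[off], 0.95)
  s2 <- t2 * as.numeric(q95 / stats::quantile(t2[off], 0.95))
  expect_true(all(cons[off] <= t1[off] + 1e-12))
  expect_true(all(cons[off] <= s2[off] + 1e-12))
  expect_equal(cons[off], pmin(t1, s2)[off], tolerance = 1e-12)
  t3 <- t2[-1, -1]
  expect_error(consensus_tom(list(t1, t3)), "gene set")
})

test_that("static cut recovers constructed TOM blocks exactly", {
  n <- 40
  tom <- matrix(0.1, n, n)
  tom[1:20, 1:20] <- 0.6
  tom[21:40, 21:40] <- 0.6
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  asg <- detect_modules(tom, min_module_size = 10L, cut_height = 0.6)
  expect_equal(length(setdiff(unique(asg), "grey")), 2L)
  det <- split(names(asg), asg)
  det$grey <- NULL
  truth <- list(a = sprintf("g%02d", 1:20), b = sprintf("g%02d", 21:40))
  expect_equal(unname(best_match_jaccard(truth, det)), c(1, 1))
  # permutation invariance up to label names
  perm <- sample(n)
  asg2 <- detect_modules(tom[perm, perm], min_module_size = 10L,
                         cut_height = 0.6)
  expect_equal(adjusted_rand_index(asg[names(asg2)], asg2), 1.0)
  # min_module_size larger than the gene count leaves everything grey
  expect_warning(asg3 <- detect_modules(tom, min_module_size = 100L,
                                        cut_height = 0.6), "grey")
  expect_true(all(asg3 == "grey"))
})

test_that("eigengenes behave like first principal components", {
  set.seed(13)
  expr <- matrix(rnorm(10 * 50), 10, 50,
                 dimnames = list(paste0("g", 1:10), paste0("m", 1:50)))
  # single-gene module: eigengene equals the z-scored gene
  asg1 <- stats::setNames(c("m1", rep("grey", 9)), rownames(expr))
  me1 <- module_eigengenes(expr, asg1)
  expect_equal(abs(stats::cor(me1[, "m1"], expr["g1", ])), 1,
               tolerance = 1e-12)
  expect_gt(stats::cor(me1[, "m1"], expr["g1", ]), 0)
  # two identical genes: eigengene proportional to either
  expr2 <- rbind(expr, g11 = expr["g1", ])
  asg2 <- stats::setNames(c("mA", rep("grey", 9), "mA"), rownames(expr2))
  me2 <- module_eigengenes(expr2, asg2)
  expect_equal(abs(stats::cor(me2[, "mA"], expr2["g1", ])), 1,
               tolerance = 1e-12)
  # PCA optimality: eigengene direction explains at least as much
  # member variance as any single member gene's direction
  asg3 <- stats::setNames(rep("mod", 10), rownames(expr))
  me3 <- module_eigengenes(expr, asg3)
  kme_e <- as.vector(stats::cor(t(expr), me3[, "mod"]))
  for (g in rownames(expr)) {
    kme_g <- as.vector(stats::cor(t(expr), expr[g, ]))
    expect_gte(sum(kme_e^2) + 1e-10, sum(kme_g^2))
  }
  # unit variance, sign tied to module average
  expect_equal(stats::sd(me3[, "mod"]), 1, tolerance = 1e-12)
  expect_gt(stats::cor(me3[, "mod"], colMeans(zscore_genes(expr))), 0)
})

test_that("kME is the gene-eigengene correlation with flagged flats", {
  set.seed(14)
  expr <- matrix(rnorm(8 * 40), 8, 40,
                 dimnames = list(paste0("g", 1:8), paste0("m", 1:40)))
  expr["g8", ] <- 3
  asg <- stats::setNames(c("mA", rep("grey", 7)), rownames(expr))
  me <- module_eigengenes(expr, asg)
  kme <- compute_kme(expr, me)
  expect_equal(kme["g1", "mA"], 1, tolerance = 1e-12)
  expect_equal(kme["g8", "mA"], 0)
  expect_true("g8" %in% attr(kme, "zero_variance"))
  expect_true(all(abs(kme) <= 1 + 1e-12))
})

test_that("module-trait correlation is exact and antisymmetric", {
  set.seed(15)
  expr <- matrix(rnorm(12 * 30), 12, 30,
                 dimnames = list(paste0("g", 1:12), paste0("m", 1:30)))
  asg <- stats::setNames(rep(c("mA", "mB"), each = 6), rownames(expr))
  me <- module_eigengenes(expr, asg)
  traits <- cbind(self = me[, "mA"], rand = rnorm(30), flat = rep(1, 30))
  expect_warning(tc <- module_trait_correlation(me, traits), "constant")
  expect_equal(tc$cor["mA", "self"], 1, tolerance = 1e-12)
  expect_lt(tc$p["mA", "self"], 1e-10)
  tc2 <- module_trait_correlation(me, cbind(neg = -me[, "mA"],
                                            rand = traits[, "rand"]))
  expect_equal(tc2$cor[, "neg"], -tc$cor[, "self"], tolerance = 1e-12)
})

test_that("hub genes are the kME-ranked prefix of the module", {
  set.seed(16)
  expr <- matrix(rnorm(10 * 30), 10, 30,
                 dimnames = list(paste0("g", 1:10), paste0("m", 1:30)))
  asg <- stats::setNames(rep("mA", 10), rownames(expr))
  me <- module_eigengenes(expr, asg)
  kme <- compute_kme(expr, me)
  top3 <- top_hub_genes(kme, asg, "mA", 3L)
  full <- top_hub_genes(kme, asg, "mA", 10L)
  expect_identical(top3, full[1:3])
  expect_equal(kme[full, "mA"], sort(kme[, "mA"], decreasing = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(t2 <- top_hub_genes(kme, asg, "mA", 50L), "only")
  expect_identical(t2, full)
})

test_that("consensus modules recover the planted structure end to end", {
  run <- fixture_run()
  r <- run$results
  truth <- fixture_truth_sets()
  det <- split(names(r$assignment), r$assignment)
  det$grey <- NULL
  jac <- best_match_jaccard(truth, det)
  expect_true(all(jac >= 0.8))
  # planted members point to their own detected module by kME
  mm <- fixture_module_map(r$assignment)
  expect_equal(length(unique(mm)), 3L)
  own_best <- vapply(names(truth), function(tm) {
    genes <- intersect(truth[[tm]], rownames(r$kme))
    mean(colnames(r$kme)[max.col(r$kme[genes, , drop = FALSE])] == mm[[tm]])
  }, numeric(1))
  expect_true(all(own_best >= 0.95))
  # the planted tolerant module correlates most with the resistant trait
  tol_det <- mm[["mod_tolerant"]]
  tc <- r$trait_cor$cor
  expect_identical(rownames(tc)[which.max(tc[, "frac_rMDSC"])], tol_det)
  # hub genes live inside the planted module
  hubs <- top_hub_genes(r$kme, r$assignment, tol_det, 10L)
  expect_gte(mean(hubs %in% truth$mod_tolerant), 0.9)
})
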