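# Signature scoring, ROC/logistic evaluation, label transfer, OLS
# association.

test_that("signature scores average z-scored genes", {
  expr <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1))
  colnames(expr) <- paste0("s", 1:3)
  expect_equal(unname(signature_score(expr, c("g1", "g2"))), c(0, 0, 0))
  expect_equal(unname(signature_score(expr, "g1")), c(-1, 0, 1))
  # absent genes dropped with warning naming them; none present errors
  expect_warning(s <- signature_score(expr, c("g1", "gX")), "gX")
  expect_equal(unname(s), c(-1, 0, 1))
  expect_error(suppressWarnings(signature_score(expr, "gZ")), "no signature")
  # zero mean across samples for any signature
  set.seed(19)
  big <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  expect_lt(abs(mean(signature_score(big, paste0("g", 3:12)))), 1e-12)
  # invariance to affine rescaling of an input gene row
  big2 <- big
  big2["g3", ] <- 7 * big2["g3", ] + 100
  expect_equal(signature_score(big, paste0("g", 3:12)),
               signature_score(big2, paste0("g", 3:12)), tolerance = 1e-12)
})

test_that("rank AUC matches hand counts and pair enumeration", {
  expect_warning(r1 <- roc_auc(c(0.1, 0.2, 0.9, 0.8), c(0, 0, 1, 1)),
                 "separation")
  expect_equal(r1$auc, 1.0)
  r <- suppressWarnings(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)))
  expect_equal(r$auc, 0.75)          # 3 concordant of 4 pos-neg pairs
  # ROC endpoints and monotonicity
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # complement symmetry
  set.seed(20)
  s <- rnorm(60); l <- rep(c(TRUE, FALSE), 30)
  expect_equal(roc_auc(s, l)$auc, 1 - roc_auc(-s, l)$auc, tolerance = 1e-12)
})

test_that("logistic-probability AUC equals the rank AUC", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(100)
    y <- stats::rbinom(100, 1, stats::plogis(0.3 + 1.5 * x))
    if (length(unique(y)) < 2) next
    r <- roc_auc(x, y)
    expect_lt(abs(r$auc - r$auc_logistic), 1e-9)
    # cross-check the Newton fit against glm
    g <- stats::glm(y ~ x, family = stats::binomial)
    expect_equal(r$logistic$slope, unname(stats::coef(g)[2]),
                 tolerance = 1e-6)
  }
  # perfect separation: slope capped with warning, AUC intact from ranks
  expect_warning(rp <- roc_auc(c(1, 2, 3, 10, 11, 12),
                               c(0, 0, 0, 1, 1, 1)), "separation")
  expect_equal(rp$auc, 1.0)
})

test_that("rank AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  for (i in 1:5) {
    s <- rnorm(80) + rep(c(0, 0.8), each = 40)
    l <- rep(c(0, 1), each = 40)
    mine <- roc_auc(s, l)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(23)
  aucs <- replicate(100, {
    suppressWarnings(roc_auc(rnorm(200), rep(c(0, 1), 100))$auc)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("module separation evaluation finds the max-min module", {
  set.seed(24)
  expr <- matrix(rnorm(40 * 60), 40, 60,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:60)))
  lab <- rep(c(FALSE, TRUE), each = 30)
  expr[1:10, lab] <- expr[1:10, lab] + 2         # mA separates
  asg <- stats::setNames(rep(c("mA", "mB", "grey", "mC"), each = 10),
                         rownames(expr))
  ev <- evaluate_module_separation(asg, expr, list(main = lab))
  expect_identical(ev$best, "mA")
  expect_gt(ev$auc["mA", "main"], 0.95)
  expect_lt(abs(ev$auc["mB", "main"] - 0.5), 0.25)   # unrelated module
  expect_false("grey" %in% rownames(ev$auc))
  # NA labels drop samples from a contrast
  lab2 <- lab; lab2[1:10] <- NA
  ev2 <- evaluate_module_separation(asg, expr, list(main = lab2))
  expect_true(all(is.finite(ev2$auc)))
})

test_that("centroid transfer reproduces reference labels exactly", {
  set.seed(25)
  expr <- matrix(rnorm(60 * 90), 60, 90,
                 dimnames = list(paste0("g", 1:60), paste0("s", 1:90)))
  lab <- rep(c("A", "B", "C"), each = 30)
  expr[1:20, lab == "A"] <- expr[1:20, lab == "A"] + 2
  expr[21:40, lab == "B"] <- expr[21:40, lab == "B"] + 2
  expr[41:60, lab == "C"] <- expr[41:60, lab == "C"] + 2
  pred <- transfer_labels(expr, lab, expr)
  expect_equal(pred$label, lab)
  # the centroids themselves map to their own label with top confidence
  z <- zscore_genes(expr)
  centroids <- vapply(unique(lab), function(l) {
    rowMeans(z[, lab == l, drop = FALSE])
  }, numeric(nrow(z)))
  pred_c <- transfer_labels(expr, lab, centroids)
  expect_equal(pred_c$label, unique(lab))
  expect_true(all(pred_c$confidence >= 1 / 3))
  expect_error(transfer_labels(expr[1:10, ], lab[1:10], expr[1:10, ]),
               "shared genes")
})

test_that("transfer recovers resistant cells in regenerated data", {
  ref <- fixture_sim()
  query <- simulate_sc_experiment(sim_config(seed = 43L))
  ref_norm <- fixture_norm()
  q_norm <- normalize_log_cp10k(query$counts)
  lab <- ifelse(ref$cell_meta$resistant, "resistant",
                ifelse(ref$cell_meta$group == "TS", "TS_other",
                       ref$cell_meta$group))
  pred <- transfer_labels(ref_norm, lab, q_norm)
  acc <- mean((pred$label == "resistant") == query$cell_meta$resistant)
  expect_gte(acc, 0.9)
})

test_that("OLS association recovers known coefficients", {
  set.seed(26)
  a <- rnorm(1000); b <- rnorm(1000)
  exact <- multivariate_association(a, a, b)
  expect_equal(exact$estimate[exact$term == "covariate_a"], 1,
               tolerance = 1e-10)
  expect_lt(exact$p[exact$term == "covariate_a"], 1e-10)
  expect_lt(abs(exact$estimate[exact$term == "covariate_b"]), 0.05)
  y <- a + b + rnorm(1000, sd = 0.1)
  fit <- multivariate_association(y, a, b)
  expect_equal(fit$estimate[2:3], c(1, 1), tolerance = 0.05)
  # permuting the response destroys both associations
  set.seed(27)
  pvals <- replicate(100, {
    multivariate_association(sample(y), a, b)$p[2]
  })
  expect_gt(mean(pvals > 0.05), 0.85)
  expect_lt(abs(mean(pvals) - 0.5), 0.15)
  expect_error(multivariate_association(y, a, a * 1.0000001), "collinear")
  expect_error(multivariate_association(y[1:5], a[1:5], b[1:5]), "10")
})
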