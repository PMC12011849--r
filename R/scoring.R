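# Signature scoring, logistic/ROC discrimination, centroid label
# transfer, and the pathway-vs-profiles multivariate association.

#' Signature score per sample
#'
#' Each gene is z-scored across all samples (n-1 standard deviation);
#' the score of a sample is the mean of the z-scores over the signature
#' genes. Signature genes absent from the matrix are dropped with a
#' warning naming them.
#'
#' @param expr genes x samples matrix with gene rownames.
#' @param genes signature gene ids.
#' @return Named numeric vector of per-sample scores (mean 0 across
#'   samples by construction).
#' @export
signature_score <- function(expr, genes) {
  .assert(ncol(expr) >= 2L, "need at least 2 samples")
  present <- intersect(genes, rownames(expr))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    warning("signature gene(s) absent from the matrix: ",
            paste(missing, collapse = ", "))
  .assert(length(present) >= 1L, "no signature gene present in the matrix")
  z <- zscore_genes(expr[present, , drop = FALSE])
  colMeans(z)
}

# two-parameter logistic regression by Newton-Raphson
.logistic_fit <- function(x, y, tol = 1e-10, max_iter = 100L,
                          slope_cap = 30) {
  beta <- c(0, 0)
  X <- cbind(1, x)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- as.vector(crossprod(X, y - p))
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (abs(beta[2]) > slope_cap) break
  }
  if (!converged && abs(beta[2]) >= slope_cap)
    beta[2] <- sign(beta[2]) * slope_cap
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       converged = converged)
}

# Mann-Whitney rank AUC with half credit for ties
.rank_auc <- function(scores, labels) {
  pos <- labels
  r <- rank(scores)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC AUC of a score against a binary label
#'
#' Fits a univariate logistic model of the label on the score (own
#' Newton iterations), then computes the AUC both from the predicted
#' probabilities and by the Mann-Whitney rank formula with half credit
#' for ties. The two must agree (monotone-transform invariance) whenever
#' the fitted slope is positive; the rank AUC is authoritative and is
#' what the report stores.
#'
#' @param scores numeric vector.
#' @param labels binary vector (logical, 0/1, or two-level factor); the
#'   positive class is `TRUE` / `1` / the second level.
#' @return A `score_report` list: `auc` (rank AUC), `auc_logistic`,
#'   `logistic` (intercept, slope, converged), `roc` (data.frame fpr,
#'   tpr, monotone from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  .assert(!anyNA(labels) && length(labels) == length(scores),
          "labels must be binary and aligned to scores")
  .assert(any(labels) && any(!labels), "both classes must be present")
  fit <- .logistic_fit(scores, as.numeric(labels))
  if (.rank_auc(scores, labels) %in% c(0, 1)) {
    warning("perfect separation: logistic slope capped; AUC taken from ranks")
    fit$slope <- sign(fit$slope) * min(abs(fit$slope), 30)
  }
  prob <- 1 / (1 + exp(-(fit$intercept + fit$slope * scores)))
  auc_rank <- .rank_auc(scores, labels)
  auc_log <- .rank_auc(prob, labels)
  # ROC curve over score thresholds (descending)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord])
  fp <- cumsum(!labels[ord])
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[keep] / sum(!labels)),
                    tpr = c(0, tp[keep] / sum(labels)))
  structure(list(auc = auc_rank, auc_logistic = auc_log,
                 logistic = fit, roc = roc,
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "score_report")
}

#' Evaluate module signatures as group separators
#'
#' For each module, the member genes form a signature; the signature is
#' scored on `expr` and its ROC AUC computed for every contrast. The
#' "best" module maximizes the minimum AUC across contrasts — the module
#' that separates well in *every* comparison.
#'
#' @param assignment gene -> module vector (grey skipped).
#' @param expr genes x samples matrix.
#' @param contrasts named list of binary label vectors aligned to
#'   samples; `NA` labels exclude a sample from that contrast.
#' @return list with `auc` (modules x contrasts matrix), `best` (module
#'   label), `scores` (modules x samples signature scores).
#' @export
evaluate_module_separation <- function(assignment, expr, contrasts) {
  mods <- setdiff(unique(assignment), "grey")
  .assert(length(mods) > 0L, "no modules to evaluate")
  .assert(length(contrasts) >= 1L && !is.null(names(contrasts)),
          "contrasts must be a named list")
  mods <- mods[vapply(mods, function(m) {
    any(names(assignment)[assignment == m] %in% rownames(expr))
  }, logical(1))]
  scores <- t(vapply(mods, function(m) {
    suppressWarnings(
      signature_score(expr, names(assignment)[assignment == m]))
  }, numeric(ncol(expr))))
  auc <- vapply(contrasts, function(lab) {
    sel <- !is.na(lab)
    vapply(mods, function(m) {
      roc_auc(scores[m, sel], lab[sel])$auc
    }, numeric(1))
  }, numeric(length(mods)))
  auc <- matrix(auc, nrow = length(mods),
                dimnames = list(mods, names(contrasts)))
  best <- mods[which.max(apply(auc, 1L, min))]
  list(auc = auc, best = best, scores = scores)
}

#' Centroid-correlation label transfer
#'
#' A transparent, deterministic stand-in for anchor-based reference
#' mapping: both datasets are restricted to shared genes and z-scored
#' independently; per-label reference centroids are computed; each query
#' sample is assigned the label whose centroid has the highest Spearman
#' correlation with it, with a softmax of the correlations as
#' confidence.
#'
#' @param ref_expr,query_expr genes x samples matrices with gene
#'   rownames.
#' @param ref_labels per-reference-sample labels.
#' @param min_shared minimum shared genes (default 50).
#' @return data.frame (sample, label, confidence) plus the correlation
#'   matrix in `attr(, "correlations")`.
#' @export
transfer_labels <- function(ref_expr, ref_labels, query_expr,
                            min_shared = 50L) {
  shared <- intersect(rownames(ref_expr), rownames(query_expr))
  .assert(length(shared) >= min_shared,
          sprintf("need at least %d shared genes (found %d)",
                  min_shared, length(shared)))
  .assert(ncol(ref_expr) == length(ref_labels),
          "ref_labels must align to reference samples")
  zr <- zscore_genes(ref_expr[shared, , drop = FALSE])
  zq <- zscore_genes(query_expr[shared, , drop = FALSE])
  labs <- sort(unique(as.character(ref_labels)))
  centroids <- vapply(labs, function(l) {
    rowMeans(zr[, ref_labels == l, drop = FALSE])
  }, numeric(length(shared)))
  cors <- stats::cor(zq, centroids, method = "spearman")
  pred <- labs[max.col(cors, ties.method = "first")]
  conf <- t(apply(cors, 1L, function(r) exp(r) / sum(exp(r))))
  out <- data.frame(sample = colnames(query_expr), label = pred,
                    confidence = conf[cbind(seq_len(nrow(cors)),
                                            max.col(cors, "first"))],
                    stringsAsFactors = FALSE)
  attr(out, "correlations") <- cors
  out
}

#' Multivariate association of a pathway score with two profiles
#'
#' Ordinary least squares of a per-cell pathway score on an intercept
#' and two per-cell profile scores (e.g., an expression-based score and
#' a copy-number burden), with two-sided t-test p-values per
#' coefficient. Used to ask whether a pathway tracks expression state,
#' genomic state, or both.
#'
#' @param response numeric response vector.
#' @param covariate_a,covariate_b numeric covariates.
#' @param collinearity_limit reject when `|cor(a, b)|` reaches this.
#' @return data.frame (term, estimate, se, t, p).
#' @export
multivariate_association <- function(response, covariate_a, covariate_b,
                                     collinearity_limit = 0.99) {
  .assert(length(response) >= 10L, "need at least 10 observations")
  r_ab <- stats::cor(covariate_a, covariate_b)
  .assert(is.finite(r_ab) && abs(r_ab) < collinearity_limit,
          sprintf("covariates are collinear (|r| = %.3f)", abs(r_ab)))
  fit <- stats::lm(response ~ covariate_a + covariate_b)
  cf <- summary(fit)$coefficients
  data.frame(term = c("intercept", "covariate_a", "covariate_b"),
             estimate = cf[, 1], se = cf[, 2], t = cf[, 3], p = cf[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}
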