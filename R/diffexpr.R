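#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with enforced monotonicity,
#' capped at 1. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  .assert(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
          "p-values must be finite numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Exact two-sided rank-sum p-value by full enumeration of group-A rank
# assignments; handles ties exactly. Only used for small groups.
.exact_ranksum_p <- function(x, y) {
  n_a <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(r), n_a)
  w_all <- colSums(matrix(r[combos], nrow = n_a))
  mu <- mean(w_all)
  # two-sided: total probability of rank sums at least as extreme
  dev <- abs(w_all - mu)
  min(1, mean(dev >= abs(w_obs - mu) - 1e-9))
}

# Vectorized tie- and continuity-corrected normal approximation for the
# two-sided rank-sum test, one gene per row.
.normal_ranksum_p <- function(m_a, m_b) {
  n_a <- ncol(m_a)
  n_b <- ncol(m_b)
  n <- n_a + n_b
  comb <- cbind(m_a, m_b)
  r <- t(apply(comb, 1L, rank))
  w <- rowSums(r[, seq_len(n_a), drop = FALSE])
  mu <- n_a * (n + 1) / 2
  tie_term <- apply(comb, 1L, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  sigma2[sigma2 <= 0] <- NA
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  z[!is.finite(z)] <- 0
  z <- pmax(z, 0)
  2 * stats::pnorm(-z)
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided rank-sum test between two disjoint cell groups on
#' log-normalized values, with log2 fold change computed on de-logged
#' means. Uses the tie- and continuity-corrected normal approximation,
#' switching to exact enumeration when both groups have at most
#' `exact_max` cells. P-values are BH-adjusted over all tested genes.
#'
#' @param m log-normalized genes x cells matrix with dimnames.
#' @param cells_a,cells_b disjoint cell id (or index) vectors, each of
#'   size >= 2.
#' @param contrast label stored with the table.
#' @param eps pseudocount in the fold-change ratio.
#' @param exact_max exact-enumeration group size bound.
#' @return data.frame (gene, log2fc, p, padj, pct_a, pct_b, contrast);
#'   `log2fc > 0` means higher in `cells_a`.
#' @export
wilcoxon_de <- function(m, cells_a, cells_b, contrast = "A_vs_B",
                        eps = 1e-9, exact_max = 10L) {
  if (is.character(cells_a)) cells_a <- match(cells_a, colnames(m))
  if (is.character(cells_b)) cells_b <- match(cells_b, colnames(m))
  .assert(!anyNA(cells_a) && !anyNA(cells_b), "unknown cell ids")
  .assert(length(intersect(cells_a, cells_b)) == 0L,
          "cell groups must be disjoint")
  .assert(length(cells_a) >= 2L && length(cells_b) >= 2L,
          "both groups need at least 2 cells")
  m_a <- m[, cells_a, drop = FALSE]
  m_b <- m[, cells_b, drop = FALSE]
  mean_a <- rowMeans(expm1(m_a))
  mean_b <- rowMeans(expm1(m_b))
  log2fc <- log2((mean_a + eps) / (mean_b + eps))
  if (length(cells_a) <= exact_max && length(cells_b) <= exact_max) {
    p <- vapply(seq_len(nrow(m)), function(i) {
      .exact_ranksum_p(m_a[i, ], m_b[i, ])
    }, numeric(1))
  } else {
    p <- .normal_ranksum_p(m_a, m_b)
  }
  # genes constant across both groups carry no evidence
  const <- apply(cbind(m_a, m_b), 1L, function(v) all(v == v[1L]))
  p[const] <- 1
  data.frame(gene = rownames(m), log2fc = log2fc, p = p,
             padj = bh_adjust(p),
             pct_a = rowMeans(m_a > 0), pct_b = rowMeans(m_b > 0),
             contrast = contrast, stringsAsFactors = FALSE,
             row.names = NULL)
}
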