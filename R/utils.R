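# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

#' Row variances with the n-1 denominator
#' @noRd
.row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Derive a reproducible sub-seed from a base seed and a label.
#'
#' Stage/sub-task seeds are derived deterministically from one global seed
#' so individual stages can be rerun in isolation. Kept below 2^31 - 1.
#' @noRd
.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h * 7919) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Agreement between two partitions of the same items, corrected for
#' chance; 1 means identical up to label renaming, 0 is the expectation
#' under independent random partitions.
#'
#' @param a,b label vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  .assert(length(a) == length(b), "labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Best-match Jaccard overlap of planted vs detected gene sets
#'
#' For each reference set, the maximum Jaccard index over all detected
#' sets. Used to quantify recovery of planted modules.
#'
#' @param truth named list of reference gene vectors.
#' @param detected named list of detected gene vectors.
#' @return Named numeric vector, one value per reference set.
#' @export
best_match_jaccard <- function(truth, detected) {
  vapply(truth, function(tg) {
    if (length(detected) == 0L) return(0)
    max(vapply(detected, function(dg) {
      length(intersect(tg, dg)) / length(union(tg, dg))
    }, numeric(1)))
  }, numeric(1))
}
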