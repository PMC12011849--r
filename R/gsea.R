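# Pre-ranked gene set enrichment with a Monte-Carlo gene-permutation
# null (classic weighted Kolmogorov-Smirnov-like running statistic).

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path file path.
#' @return Named list of character gene vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character gene vectors.
#' @param path output path.
#' @param description per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Enrichment score from sorted hit positions.
# absw: |statistic| for the ranked genes (descending order), pos: sorted
# hit positions, N: universe size. Weight w = 1 (classic weighted form):
# hits advance by |stat| / sum_set |stat|, misses retreat by 1/(N - k).
# Returns the signed maximum deviation and the index (into pos) of the
# extremum for the leading edge.
.es_from_positions <- function(pos, absw, N) {
  k <- length(pos)
  w <- absw[pos]
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / k, k) else w <- w / sw
  phit <- cumsum(w)
  if (N == k) {  # degenerate: every gene is a hit
    es <- max(phit)
    return(list(es = es, at = which.max(phit), degenerate = TRUE))
  }
  miss_after <- (pos - seq_len(k)) / (N - k)   # misses seen before hit i
  top <- phit - miss_after                      # running score at hit i
  bottom <- c(0, phit[-k]) - (pos - 1 - (seq_len(k) - 1)) / (N - k)
  i_top <- which.max(top)
  i_bot <- which.min(bottom)
  if (top[i_top] >= -bottom[i_bot])
    list(es = top[i_top], at = i_top, degenerate = FALSE)
  else
    list(es = bottom[i_bot], at = i_bot, degenerate = FALSE)
}

#' Pre-ranked gene set enrichment analysis
#'
#' Genes are sorted by descending statistic (ties broken by gene id for
#' determinism). The running enrichment score advances by
#' `|stat| / sum_set |stat|` at set members and retreats by
#' `1/(N - N_hit)` elsewhere; the enrichment score (ES) is the signed
#' maximum deviation. Significance comes from `n_perm` random same-size
#' gene sets drawn under the given seed:
#' `p = (1 + #\{|ES_null| >= |ES|\}) / (1 + n_perm)`;
#' `NES = ES / mean |ES_null|` over null scores of matching sign.
#' Adjusted p-values are BH across the reported sets. The leading edge
#' is the member genes up to the ES extremum.
#'
#' @param ranked named numeric vector of statistics (names = genes), or
#'   a two-column data.frame (gene, statistic).
#' @param gene_sets named list of gene vectors (e.g. [read_gmt()]).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed RNG seed.
#' @param min_size sets with fewer ranked members are skipped with a
#'   note.
#' @return data.frame (set_name, size, es, nes, p, padj, leading_edge
#'   (comma-separated), degenerate, n_perm_used, seed).
#' @export
preranked_gsea <- function(ranked, gene_sets, n_perm = 10000L, seed = 1L,
                           min_size = 5L) {
  if (is.data.frame(ranked))
    ranked <- stats::setNames(ranked[[2L]], ranked[[1L]])
  .assert(all(is.finite(ranked)), "statistics must be finite")
  .assert(!is.null(names(ranked)), "ranked statistics must be named by gene")
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse p-value grid")
  ord <- order(-ranked, names(ranked))
  stat <- ranked[ord]
  genes <- names(stat)
  absw <- abs(stat)
  N <- length(genes)
  gene_pos <- stats::setNames(seq_len(N), genes)
  set.seed(seed)

  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], genes)
    k <- length(members)
    if (k < min_size) {
      message("set ", nm, " skipped: only ", k, " gene(s) in the ranking")
      return(NULL)
    }
    pos <- sort(unname(gene_pos[members]))
    obs <- .es_from_positions(pos, absw, N)
    if (obs$degenerate || k == N) {
      return(data.frame(set_name = nm, size = k, es = obs$es, nes = NA_real_,
                        p = NA_real_, padj = NA_real_,
                        leading_edge = paste(genes[pos[seq_len(obs$at)]],
                                             collapse = ","),
                        degenerate = TRUE, n_perm_used = 0L, seed = seed,
                        stringsAsFactors = FALSE))
    }
    null_es <- vapply(seq_len(n_perm), function(i) {
      .es_from_positions(sort(sample.int(N, k)), absw, N)$es
    }, numeric(1))
    p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + n_perm)
    same_sign <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same_sign) > 0L)
      obs$es / mean(abs(same_sign)) else NA_real_
    le <- genes[pos[seq_len(obs$at)]]
    data.frame(set_name = nm, size = k, es = obs$es, nes = nes, p = p,
               padj = NA_real_, leading_edge = paste(le, collapse = ","),
               degenerate = FALSE, n_perm_used = n_perm, seed = seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  .assert(!is.null(out), "no gene set passed the size filter")
  usable <- !out$degenerate
  out$padj[usable] <- bh_adjust(out$p[usable])
  out
}
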