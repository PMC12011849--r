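# Dual-contrast quadrant classification of genes into stress-tolerant vs
# stress-sensitive, and module down-selection.

#' Classify genes into tolerance quadrants from two DEG contrasts
#'
#' Combines two differential-expression tables over the same gene
#' universe: the cytokine contrast (T vs C; positive = up in treated
#' cells) and the resistance contrast (resistant cluster vs other
#' stressed cells; positive = up in resistant cells). Genes significant
#' in *both* contrasts ("shared DEGs") are placed in a sign quadrant:
#' concordant induction (`+,+`) is `tolerant_up`, induction lost or
#' reversed under stress (`+,-`) is `sensitive_up`, and the mirrored
#' pairs classify down-regulated genes. Genes significant in at most one
#' contrast are `unshared`.
#'
#' @param deg_ct [wilcoxon_de()] table for T vs C (A = T).
#' @param deg_r [wilcoxon_de()] table for resistant vs other stressed
#'   cells (A = resistant).
#' @param padj_cutoff,lfc_cutoff significance gates applied to both
#'   contrasts (adjusted p below, absolute log2 fold change at least).
#' @param assignment optional gene -> module vector to carry module
#'   labels into the output.
#' @return data.frame (gene, lfc_CT, lfc_rMDSC, quadrant, module).
#' @export
classify_gene_tolerance <- function(deg_ct, deg_r, padj_cutoff = 0.05,
                                    lfc_cutoff = 0.25, assignment = NULL) {
  .assert(setequal(deg_ct$gene, deg_r$gene),
          "the two DEG tables must cover the same gene universe")
  deg_r <- deg_r[match(deg_ct$gene, deg_r$gene), ]
  sig_ct <- deg_ct$padj < padj_cutoff & abs(deg_ct$log2fc) >= lfc_cutoff
  sig_r <- deg_r$padj < padj_cutoff & abs(deg_r$log2fc) >= lfc_cutoff
  shared <- sig_ct & sig_r
  quadrant <- rep("unshared", nrow(deg_ct))
  up_ct <- deg_ct$log2fc > 0
  up_r <- deg_r$log2fc > 0
  quadrant[shared & up_ct & up_r] <- "tolerant_up"
  quadrant[shared & up_ct & !up_r] <- "sensitive_up"
  quadrant[shared & !up_ct & !up_r] <- "tolerant_down"
  quadrant[shared & !up_ct & up_r] <- "sensitive_down"
  out <- data.frame(gene = deg_ct$gene, lfc_CT = deg_ct$log2fc,
                    lfc_rMDSC = deg_r$log2fc, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  out$module <- if (is.null(assignment)) NA_character_ else
    unname(assignment[out$gene])
  out
}

#' Down-select candidate stress-tolerant modules
#'
#' A module is a candidate when it contains at least `min_shared` shared
#' DEGs and the majority of those shared DEGs are `tolerant_up`.
#' Candidates are ranked by tolerant-up fraction, then by shared-DEG
#' count. This is the step that narrows the module set to those both
#' MDSC-related (cytokine-induced) and stress-tolerant.
#'
#' @param assignment gene -> module vector (grey excluded).
#' @param tol a [classify_gene_tolerance()] table.
#' @param min_shared minimum shared DEGs per candidate module.
#' @return data.frame (module, n_shared, n_tolerant_up, tolerant_fraction)
#'   of candidates, best first; zero rows (with a warning) when no module
#'   qualifies.
#' @export
downselect_modules <- function(assignment, tol, min_shared = 5L) {
  comp <- module_tolerance_composition(assignment, tol)
  cand <- comp[comp$n_shared >= min_shared &
                 comp$n_tolerant_up > comp$n_shared / 2, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no module passes down-selection")
    return(cand)
  }
  cand[order(-cand$tolerant_fraction, -cand$n_shared, cand$module), ,
       drop = FALSE]
}

#' Tolerance composition of each module
#'
#' Counts and fractions of tolerant-up / sensitive-up / other quadrants
#' among each module's shared DEGs.
#'
#' @param assignment gene -> module vector.
#' @param tol a [classify_gene_tolerance()] table.
#' @return data.frame with one row per non-grey module: `n_shared`,
#'   `n_tolerant_up`, `n_sensitive_up`, `n_other`, and the corresponding
#'   fractions (which sum to 1 when `n_shared > 0`).
#' @export
module_tolerance_composition <- function(assignment, tol) {
  mods <- setdiff(unique(assignment), "grey")
  rows <- lapply(mods, function(m) {
    genes <- names(assignment)[assignment == m]
    q <- tol$quadrant[tol$gene %in% genes]
    q <- q[q != "unshared"]
    n <- length(q)
    n_tol <- sum(q == "tolerant_up")
    n_sen <- sum(q == "sensitive_up")
    data.frame(module = m, n_shared = n, n_tolerant_up = n_tol,
               n_sensitive_up = n_sen, n_other = n - n_tol - n_sen,
               tolerant_fraction = if (n > 0) n_tol / n else 0,
               sensitive_fraction = if (n > 0) n_sen / n else 0,
               other_fraction = if (n > 0) (n - n_tol - n_sen) / n else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module = character(0), n_shared = integer(0),
                      n_tolerant_up = integer(0), n_sensitive_up = integer(0),
                      n_other = integer(0), tolerant_fraction = numeric(0),
                      sensitive_fraction = numeric(0),
                      other_fraction = numeric(0))
  out
}
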