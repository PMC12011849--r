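# Readers and writers for the 10x-style MTX triplet, metadata tables,
# gene positions, and signature files.

#' Write a count matrix as a 10x-style triplet
#'
#' Writes `matrix.mtx` (Matrix Market coordinate, 1-based indices),
#' `features.tsv`, `barcodes.tsv`, plus `cell_meta.tsv`,
#' `gene_meta.tsv`, and `truth.json` when a simulated dataset is given.
#'
#' @param x an `sc_dataset` from [simulate_sc_experiment()] or a genes x
#'   cells count matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- if (inherits(x, "sc_dataset")) x$counts else x
  sp <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (inherits(x, "sc_dataset")) {
    utils::write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(x$gene_meta, file.path(dir, "gene_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- list(
      modules = lapply(x$truth$modules, function(m) unclass(m)),
      cnv_blocks = x$truth$cnv_blocks,
      resistant_cells = x$truth$resistant_cells,
      carrier_cells = x$truth$carrier_cells)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

# first existing of path, path.gz
.find_variant <- function(dir, base) {
  for (p in file.path(dir, c(base, paste0(base, ".gz"))))
    if (file.exists(p)) return(p)
  stop("missing file: ", base, " in ", dir, call. = FALSE)
}

#' Load a 10x-style MTX triplet as a count matrix
#'
#' Reads `matrix.mtx` (plus `features.tsv` and `barcodes.tsv`; gzipped
#' variants are accepted transparently), checks that axis lengths match
#' the header, sums duplicate coordinate entries with a warning, and
#' rejects non-integer values.
#'
#' @param dir directory holding the triplet.
#' @return Dense integer genes x cells matrix with dimnames.
#' @export
load_counts_mtx <- function(dir) {
  mtx_path <- .find_variant(dir, "matrix.mtx")
  features <- readLines(.find_variant(dir, "features.tsv"))
  features <- vapply(strsplit(features, "\t"), `[[`, character(1), 1L)
  barcodes <- readLines(.find_variant(dir, "barcodes.tsv"))
  m <- Matrix::readMM(mtx_path)
  .assert(nrow(m) == length(features),
          "feature count does not match matrix rows")
  .assert(ncol(m) == length(barcodes),
          "barcode count does not match matrix columns")
  if (methods::is(m, "TsparseMatrix") &&
      anyDuplicated(cbind(m@i, m@j)) > 0L)
    warning("duplicate coordinate entries summed")
  dense <- as.matrix(m)
  .assert(all(dense == floor(dense)) && all(dense >= 0),
          "count input must hold nonnegative integers")
  storage.mode(dense) <- "integer"
  dimnames(dense) <- list(features, barcodes)
  dense
}

#' Read gene positions from a BED-like TSV
#'
#' Columns: chrom, start, end, gene_id (0-based half-open coordinates),
#' no header.
#'
#' @param path file path.
#' @return data.frame (gene, chrom, start, end).
#' @export
read_gene_positions <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  .assert(ncol(bed) >= 4L, "BED-like file needs chrom, start, end, gene_id")
  data.frame(gene = bed[[4L]], chrom = bed[[1L]], start = bed[[2L]],
             end = bed[[3L]], stringsAsFactors = FALSE)
}

#' Write gene positions as a BED-like TSV
#'
#' @param gene_meta data.frame with gene, chrom, start, end.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(gene_meta, path) {
  utils::write.table(gene_meta[, c("chrom", "start", "end", "gene")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a signature file (one gene id per line, or GMT)
#'
#' @param path file path; `.gmt` files are parsed with [read_gmt()] and
#'   returned as a list, otherwise a plain character vector is returned.
#' @return Character vector of gene ids, or a named list for GMT input.
#' @export
read_signature <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) return(read_gmt(path))
  lines <- readLines(path)
  lines[nzchar(lines)]
}

# write a TSV with a provenance header line ("# stage: ... params: ...")
.write_stage_tsv <- function(df, path, stage, params = list()) {
  hdr <- sprintf("# stage: %s | params: %s", stage,
                 paste(names(params), unlist(params), sep = "=",
                       collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
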