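#' Planted co-expression module specification
#'
#' Describes one gene module planted by the simulator: which genes belong
#' to it, how strongly they co-vary (a shared per-cell latent factor), and
#' how their mean expression shifts under cytokine treatment and serum
#' starvation. Effects are log2-scale shifts of the negative-binomial
#' mean.
#'
#' The tolerance class encodes the biology being emulated: a *tolerant*
#' module is induced by cytokines (`effect_T > 0`) and its induction is
#' retained in stress-resistant cells (`effect_TS_resistant > 0`); a
#' *sensitive* module is induced by cytokines but its induction is lost or
#' reversed in resistant cells (`effect_TS_resistant <= 0`); a *neutral*
#' module only co-varies, with no condition response.
#'
#' @param name module label.
#' @param gene_ids character vector of member gene identifiers.
#' @param latent_loading positive real; log2-scale standard deviation of
#'   the shared latent factor driving within-module correlation.
#' @param effect_T log2 shift in cytokine-treated (T) cells.
#' @param effect_TS_resistant log2 shift in resistant cells of the
#'   cytokine + starvation (TS) group.
#' @param effect_TS_other log2 shift in non-resistant TS cells.
#' @param tolerance_class one of `"tolerant"`, `"sensitive"`, `"neutral"`.
#' @return A `planted_module` list.
#' @export
planted_module <- function(name, gene_ids, latent_loading = 0.6,
                           effect_T = 0, effect_TS_resistant = 0,
                           effect_TS_other = 0,
                           tolerance_class = c("neutral", "tolerant", "sensitive")) {
  tolerance_class <- match.arg(tolerance_class)
  .assert(is.character(gene_ids) && length(gene_ids) > 0L,
          "gene_ids must be a non-empty character vector")
  .assert(latent_loading > 0, "latent_loading must be positive")
  if (tolerance_class == "tolerant")
    .assert(effect_T > 0 && effect_TS_resistant > 0,
            "tolerant module requires effect_T > 0 and effect_TS_resistant > 0")
  if (tolerance_class == "sensitive")
    .assert(effect_T > 0 && effect_TS_resistant <= 0,
            "sensitive module requires effect_T > 0 and effect_TS_resistant <= 0")
  structure(list(name = name, gene_ids = gene_ids,
                 latent_loading = latent_loading, effect_T = effect_T,
                 effect_TS_resistant = effect_TS_resistant,
                 effect_TS_other = effect_TS_other,
                 tolerance_class = tolerance_class),
            class = "planted_module")
}

#' Default planted modules for a given gene universe
#'
#' Three disjoint 50-gene modules: a stress-tolerant module (induced in T,
#' retained in resistant TS cells), a stress-sensitive module (induced in
#' T, reversed in resistant TS cells), and a neutral co-expression block.
#' Member genes are interleaved along the gene index (stride 9) so that,
#' once genes are laid out on the synthetic chromosomes, co-expression
#' modules are genomically dispersed rather than positional runs — as in
#' real genomes — and the last chromosome stays module-free for planted
#' copy-number blocks.
#'
#' @param gene_ids full gene universe (needs >= 450 genes for the default
#'   stride layout).
#' @param effect_T log2 cytokine induction used for both responsive
#'   modules.
#' @return list of [planted_module()] objects.
#' @export
default_modules <- function(gene_ids, effect_T = 1.5) {
  .assert(length(gene_ids) >= 450L, "need at least 450 genes for default modules")
  idx <- function(offset) gene_ids[seq(offset, by = 9L, length.out = 50L)]
  list(
    planted_module("mod_tolerant", idx(1L), latent_loading = 0.6,
                   effect_T = effect_T, effect_TS_resistant = effect_T,
                   effect_TS_other = 0.1, tolerance_class = "tolerant"),
    planted_module("mod_sensitive", idx(4L), latent_loading = 0.6,
                   effect_T = effect_T, effect_TS_resistant = -0.5,
                   effect_TS_other = 0.5, tolerance_class = "sensitive"),
    planted_module("mod_neutral", idx(7L), latent_loading = 0.6,
                   effect_T = 0, effect_TS_resistant = 0,
                   effect_TS_other = 0, tolerance_class = "neutral")
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic single-cell and bulk
#' generators. Defaults encode the emulated study design: multiple donors,
#' three culture arms (C = control, T = cytokine-treated, TS = cytokine +
#' serum starvation), planted tolerant/sensitive/neutral co-expression
#' modules, a resistant subpopulation present only in TS, one planted
#' chromosomal copy-number block, and a paired multi-source bulk design
#' with source-level batch effects.
#'
#' @param n_donors number of donors (single cell).
#' @param n_cells_per_group cells per donor per group.
#' @param groups ordered group labels; must be exactly C, T, TS.
#' @param n_genes total genes.
#' @param n_chromosomes synthetic chromosomes; genes are split evenly and
#'   given evenly spaced 0-based half-open coordinates.
#' @param modules list of [planted_module()]; `NULL` = [default_modules()].
#' @param resistant_fraction fraction of TS cells flagged resistant.
#' @param cnv_blocks list of lists with fields `chrom` (1-based
#'   chromosome index), `start` (1-based gene index within the
#'   chromosome), `length` (genes spanned), `dosage` (log2 copy ratio).
#' @param cnv_carrier_fraction fraction of T and TS cells carrying the
#'   planted blocks.
#' @param nb_dispersion negative-binomial dispersion (1/size), shared.
#' @param library_size_lognormal `c(meanlog, sdlog)` of per-cell total
#'   counts.
#' @param base_logmean_sd sd of per-gene baseline log2 abundance.
#' @param donor_effect_sd sd of per-donor per-gene log2 offsets.
#' @param ts_response_sd sd of the per-gene serum-starvation response
#'   (log2 shifts applied to every TS cell, resistant or not), emulating
#'   the broad stress program shared by starved cells.
#' @param n_sources bulk: number of MDSC sources.
#' @param n_samples_per_arm bulk: samples per source per arm
#'   (MDSC / control).
#' @param source_batch_sd bulk: sd of per-source per-gene batch offsets.
#' @param n_sensitive_sources bulk: number of sources (the first ones) in
#'   which sensitive-module genes are induced in MDSC samples.
#' @param bulk_noise_sd bulk: residual log2 noise sd.
#' @param seed integer seed; the same configuration and seed reproduce
#'   bit-identical datasets.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_donors = 2L, n_cells_per_group = 200L,
                       groups = c("C", "T", "TS"),
                       n_genes = 600L, n_chromosomes = 4L,
                       modules = NULL, resistant_fraction = 0.25,
                       cnv_blocks = list(list(chrom = 4L, start = 1L,
                                              length = 150L, dosage = 0.8)),
                       cnv_carrier_fraction = 0.5,
                       nb_dispersion = 0.3,
                       library_size_lognormal = c(log(5000), 0.3),
                       base_logmean_sd = 1,
                       donor_effect_sd = 0.1,
                       ts_response_sd = 0.4,
                       n_sources = 5L, n_samples_per_arm = 4L,
                       source_batch_sd = 0.5, n_sensitive_sources = 2L,
                       bulk_noise_sd = 0.5,
                       seed = 1L) {
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(modules)) modules <- default_modules(gene_ids)
  cfg <- list(n_donors = as.integer(n_donors),
              n_cells_per_group = as.integer(n_cells_per_group),
              groups = groups, n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              modules = modules, resistant_fraction = resistant_fraction,
              cnv_blocks = cnv_blocks,
              cnv_carrier_fraction = cnv_carrier_fraction,
              nb_dispersion = nb_dispersion,
              library_size_lognormal = library_size_lognormal,
              base_logmean_sd = base_logmean_sd,
              donor_effect_sd = donor_effect_sd,
              ts_response_sd = ts_response_sd,
              n_sources = as.integer(n_sources),
              n_samples_per_arm = as.integer(n_samples_per_arm),
              source_batch_sd = source_batch_sd,
              n_sensitive_sources = as.integer(n_sensitive_sources),
              bulk_noise_sd = bulk_noise_sd,
              seed = as.integer(seed),
              gene_ids = gene_ids)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants (exact C/T/TS groups, disjoint module
#' gene sets, in-range fractions, positive sizes, CNV blocks inside their
#' chromosome). Called by the generators; exported so pipeline configs can
#' be validated before any stage runs.
#'
#' @param cfg a [sim_config()].
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_sim_config <- function(cfg) {
  .assert(inherits(cfg, "sim_config"), "not a sim_config")
  .assert(identical(cfg$groups, c("C", "T", "TS")),
          "groups must be exactly C, T, TS")
  .assert(cfg$n_donors >= 1L && cfg$n_cells_per_group >= 1L &&
            cfg$n_genes >= 1L && cfg$n_chromosomes >= 1L,
          "all counts must be >= 1")
  .assert(cfg$resistant_fraction >= 0 && cfg$resistant_fraction <= 1,
          "resistant_fraction must be in [0, 1]")
  .assert(cfg$nb_dispersion > 0, "nb_dispersion must be positive")
  .assert(cfg$source_batch_sd >= 0, "source_batch_sd must be nonnegative")
  mod_genes <- unlist(lapply(cfg$modules, `[[`, "gene_ids"))
  .assert(!anyDuplicated(mod_genes),
          "module gene sets must be disjoint")
  .assert(all(mod_genes %in% cfg$gene_ids),
          "module genes must belong to the gene universe")
  gm <- .gene_positions(cfg)
  per_chrom <- table(gm$chrom)
  for (b in cfg$cnv_blocks) {
    .assert(b$chrom >= 1L && b$chrom <= cfg$n_chromosomes,
            "cnv block on unknown chromosome")
    .assert(b$start >= 1L &&
              b$start + b$length - 1L <= per_chrom[[paste0("chr", b$chrom)]],
            "cnv block exceeds chromosome gene range")
  }
  invisible(cfg)
}

# Synthetic gene coordinates: genes split evenly over chromosomes, starts
# evenly spaced, 0-based half-open. Only rank order along the chromosome
# matters downstream.
.gene_positions <- function(cfg) {
  chrom_idx <- rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_genes)
  chrom_idx <- sort(chrom_idx)
  within <- stats::ave(seq_len(cfg$n_genes), chrom_idx, FUN = seq_along)
  data.frame(gene = cfg$gene_ids,
             chrom = paste0("chr", chrom_idx),
             start = (within - 1L) * 1000L,
             end = within * 1000L,
             stringsAsFactors = FALSE)
}

# gene -> module / tolerance class lookup tables
.gene_module_map <- function(cfg) {
  module <- rep("none", cfg$n_genes)
  tol <- rep("none", cfg$n_genes)
  names(module) <- names(tol) <- cfg$gene_ids
  for (m in cfg$modules) {
    module[m$gene_ids] <- m$name
    tol[m$gene_ids] <- m$tolerance_class
  }
  list(module = module, tolerance = tol)
}

#' Simulate a multi-donor three-arm single-cell experiment
#'
#' Draws negative-binomial counts for every gene and cell of a C/T/TS
#' design. Per-gene baseline abundances and per-cell library sizes set the
#' NB mean; each planted module adds a shared per-cell latent Gaussian
#' factor (scaled by its loading) plus group- and resistance-dependent
#' log2 shifts; planted copy-number blocks multiply the mean of spanned
#' genes by `2^dosage` in carrier cells. The resistant flag exists only in
#' the TS group and is reported in the metadata for evaluation; the
#' analysis pipeline never reads it.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sc_dataset`: list with integer matrix
#'   `counts` (genes x cells), `cell_meta` (cell, donor, group, resistant,
#'   cnv_carrier), `gene_meta` (gene, chrom, start, end, module,
#'   tolerance_class), and `truth` (planted modules, CNV blocks, effect
#'   sizes).
#' @export
simulate_sc_experiment <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n_genes <- cfg$n_genes
  gm <- .gene_positions(cfg)
  maps <- .gene_module_map(cfg)
  gm$module <- unname(maps$module)
  gm$tolerance_class <- unname(maps$tolerance)

  donors <- sprintf("D%d", seq_len(cfg$n_donors))
  cell_meta <- do.call(rbind, lapply(donors, function(d) {
    do.call(rbind, lapply(cfg$groups, function(g) {
      data.frame(cell = sprintf("%s_%s_c%04d", d, g,
                                seq_len(cfg$n_cells_per_group)),
                 donor = d, group = g, stringsAsFactors = FALSE)
    }))
  }))
  n_cells <- nrow(cell_meta)

  # resistant flags: TS only, hidden from the pipeline
  cell_meta$resistant <- FALSE
  ts_idx <- which(cell_meta$group == "TS")
  n_res <- round(cfg$resistant_fraction * length(ts_idx))
  if (n_res > 0L)
    cell_meta$resistant[sample(ts_idx, n_res)] <- TRUE

  # CNV carriers among stressed/treated cells
  cell_meta$cnv_carrier <- FALSE
  tt_idx <- which(cell_meta$group %in% c("T", "TS"))
  n_car <- round(cfg$cnv_carrier_fraction * length(tt_idx))
  if (n_car > 0L && length(cfg$cnv_blocks) > 0L)
    cell_meta$cnv_carrier[sample(tt_idx, n_car)] <- TRUE

  # baseline log2 abundance and per-cell library size
  base_log2 <- stats::rnorm(n_genes, mean = 0, sd = cfg$base_logmean_sd)
  prop <- 2^base_log2
  prop <- prop / sum(prop)
  lib <- stats::rlnorm(n_cells, cfg$library_size_lognormal[1],
                       cfg$library_size_lognormal[2])

  donor_off <- matrix(stats::rnorm(n_genes * cfg$n_donors, 0,
                                   cfg$donor_effect_sd),
                      n_genes, cfg$n_donors, dimnames = list(NULL, donors))
  # broad serum-starvation program shared by all TS cells
  ts_resp <- stats::rnorm(n_genes, 0, cfg$ts_response_sd)

  # log2 shift matrix from modules (latent factor + condition effects)
  shift <- matrix(0, n_genes, n_cells)
  gene_row <- stats::setNames(seq_len(n_genes), cfg$gene_ids)
  is_T <- cell_meta$group == "T"
  is_TS <- cell_meta$group == "TS"
  for (m in cfg$modules) {
    rows <- gene_row[m$gene_ids]
    latent <- stats::rnorm(n_cells) * m$latent_loading
    eff <- numeric(n_cells)
    eff[is_T] <- m$effect_T
    eff[is_TS & cell_meta$resistant] <- m$effect_TS_resistant
    eff[is_TS & !cell_meta$resistant] <- m$effect_TS_other
    shift[rows, ] <- shift[rows, ] +
      matrix(latent + eff, length(rows), n_cells, byrow = TRUE)
  }

  # planted copy-number blocks in carrier cells
  for (b in cfg$cnv_blocks) {
    on_chrom <- which(gm$chrom == paste0("chr", b$chrom))
    rows <- on_chrom[b$start:(b$start + b$length - 1L)]
    shift[rows, cell_meta$cnv_carrier] <-
      shift[rows, cell_meta$cnv_carrier] + b$dosage
  }

  shift[, is_TS] <- shift[, is_TS] + ts_resp
  shift <- shift + donor_off[, match(cell_meta$donor, donors)]
  mu <- (prop %o% lib) * 2^shift
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   n_genes, n_cells,
                   dimnames = list(cfg$gene_ids, cell_meta$cell))
  storage.mode(counts) <- "integer"

  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gm,
                 truth = list(modules = cfg$modules,
                              cnv_blocks = cfg$cnv_blocks,
                              resistant_cells =
                                cell_meta$cell[cell_meta$resistant],
                              carrier_cells =
                                cell_meta$cell[cell_meta$cnv_carrier],
                              library_size =
                                stats::setNames(lib, cell_meta$cell)),
                 config = cfg),
            class = "sc_dataset")
}

#' Simulate a multi-source bulk MDSC/control design
#'
#' Emulates a validation compendium in which MDSCs and matched control
#' myeloid cells come from several independent sources (tissues/models)
#' with source-level batch structure: every source contributes paired
#' MDSC and control arms; a per-source per-gene Gaussian batch offset (sd
#' `source_batch_sd`) is added to all samples; tolerant-module genes are
#' shifted by their `effect_T` in every MDSC sample, while
#' sensitive-module genes are shifted only in the first
#' `n_sensitive_sources` sources — the generative analogue of
#' stress-sensitive induction holding in some environments but not others.
#' Values are on a log2 scale.
#'
#' @param cfg a [sim_config()]; bulk fields used, single-cell ignored.
#' @return Object of class `bulk_dataset`: list with `expr` (genes x
#'   samples, log2 scale) and `sample_meta` (sample, source, is_mdsc).
#' @export
simulate_bulk_sources <- function(cfg) {
  validate_sim_config(cfg)
  .assert(cfg$n_sources >= 2L, "need at least 2 sources")
  .assert(cfg$n_samples_per_arm >= 1L, "n_samples_per_arm must be >= 1")
  set.seed(.derive_seed(cfg$seed, "bulk"))
  n_genes <- cfg$n_genes
  sources <- sprintf("S%d", seq_len(cfg$n_sources))
  sample_meta <- do.call(rbind, lapply(sources, function(s) {
    data.frame(sample = sprintf("%s_%s_%d", s,
                                rep(c("mdsc", "ctrl"),
                                    each = cfg$n_samples_per_arm),
                                rep(seq_len(cfg$n_samples_per_arm), 2L)),
               source = s,
               is_mdsc = rep(c(TRUE, FALSE), each = cfg$n_samples_per_arm),
               stringsAsFactors = FALSE)
  }))
  n_samples <- nrow(sample_meta)
  base <- stats::rnorm(n_genes, mean = 4, sd = cfg$base_logmean_sd)
  batch <- matrix(stats::rnorm(n_genes * cfg$n_sources, 0,
                               cfg$source_batch_sd),
                  n_genes, cfg$n_sources, dimnames = list(NULL, sources))
  expr <- matrix(base, n_genes, n_samples) +
    batch[, match(sample_meta$source, sources)] +
    matrix(stats::rnorm(n_genes * n_samples, 0, cfg$bulk_noise_sd),
           n_genes, n_samples)
  dimnames(expr) <- list(cfg$gene_ids, sample_meta$sample)

  sens_sources <- sources[seq_len(min(cfg$n_sensitive_sources,
                                      cfg$n_sources))]
  gene_row <- stats::setNames(seq_len(n_genes), cfg$gene_ids)
  for (m in cfg$modules) {
    rows <- gene_row[m$gene_ids]
    if (m$tolerance_class == "tolerant") {
      expr[rows, sample_meta$is_mdsc] <-
        expr[rows, sample_meta$is_mdsc] + m$effect_T
    } else if (m$tolerance_class == "sensitive") {
      cols <- sample_meta$is_mdsc & sample_meta$source %in% sens_sources
      expr[rows, cols] <- expr[rows, cols] + m$effect_T
    }
  }
  structure(list(expr = expr, sample_meta = sample_meta, config = cfg),
            class = "bulk_dataset")
}
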