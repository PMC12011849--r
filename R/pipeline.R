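# End-to-end orchestration: simulate -> preprocess -> cluster -> DE ->
# metacells -> consensus modules -> tolerance -> down-selection ->
# scoring -> kME GSEA -> CNV inference, with per-stage artifacts and a
# run manifest.

.pipeline_stages <- c("simulate", "preprocess", "cluster", "de",
                      "metacells", "modules", "tolerance", "scoring",
                      "gsea", "cnv")

#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks plus stage toggles and one
#' global seed from which every stage seed is derived. Any block can be
#' overridden before [run_pipeline()].
#'
#' @param seed global integer seed.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, preprocess = TRUE, cluster = TRUE,
                  de = TRUE, metacells = TRUE, modules = TRUE,
                  tolerance = TRUE, scoring = TRUE, gsea = TRUE,
                  cnv = TRUE),
    simulate = list(),                      # overrides for sim_config()
    input_dir = NULL,                       # 10x triplet when simulate off
    preprocess = list(n_hvg = 300L, n_pcs = 20L, clip = 10),
    cluster = list(k_neighbors = 20L, resolution = 0.8),
    de = list(padj_cutoff = 0.05, lfc_cutoff = 0.25, top_signature = 100L),
    metacells = list(k_agg = 25L, max_shared = 10L),
    modules = list(powers = 1:20, min_module_size = 25L,
                   cut_height = 0.99, consensus_q = 0, kme_gap = 0.1),
    tolerance = list(min_shared = 5L),
    scoring = list(),
    gsea = list(n_perm = 1000L, min_size = 5L, gmt = NULL),
    cnv = list(window = 101L, clip = 3, k = 2L)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Values in the file override the defaults; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(user$seed %||% 1L)
  for (key in setdiff(names(user), "seed")) {
    .assert(key %in% names(cfg), paste0("unknown config key: ", key))
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      for (sub in names(user[[key]])) {
        .assert(sub %in% names(cfg[[key]]) || key %in% c("simulate", "scoring"),
                paste0("unknown config key: ", key, "$", sub))
        cfg[[key]][[sub]] <- user[[key]][[sub]]
      }
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Every stage's parameters are checked against that stage's
#' preconditions before any stage runs; an invalid parameter rejects the
#' whole run with no outputs written.
#'
#' @param config a `pipeline_config`.
#' @return `config`, invisibly; errors on violation.
#' @export
validate_pipeline_config <- function(config) {
  .assert(inherits(config, "pipeline_config") || is.list(config),
          "not a pipeline config")
  p <- config$preprocess
  .assert(p$n_hvg > 0L && p$n_pcs > 0L, "preprocess: n_hvg and n_pcs must be positive")
  .assert(config$cluster$k_neighbors > 0L, "cluster: k_neighbors must be positive")
  .assert(config$cluster$resolution > 0, "cluster: resolution must be positive")
  d <- config$de
  .assert(d$padj_cutoff > 0 && d$padj_cutoff <= 1, "de: padj_cutoff must be in (0, 1]")
  .assert(d$lfc_cutoff >= 0, "de: lfc_cutoff must be nonnegative")
  m <- config$metacells
  .assert(m$k_agg >= 1L && m$max_shared >= 0L, "metacells: invalid aggregation")
  mo <- config$modules
  .assert(length(mo$powers) > 0L && !is.unsorted(mo$powers),
          "modules: powers must be ascending and nonempty")
  .assert(mo$min_module_size >= 1L, "modules: min_module_size must be >= 1")
  .assert(mo$consensus_q >= 0 && mo$consensus_q <= 1,
          "modules: consensus_q must be in [0, 1]")
  .assert(config$tolerance$min_shared >= 1L, "tolerance: min_shared must be >= 1")
  g <- config$gsea
  .assert(g$n_perm >= 1L, "gsea: n_perm must be positive")
  cv <- config$cnv
  .assert(cv$window %% 2L == 1L, "cnv: window must be odd")
  .assert(cv$k >= 2L, "cnv: k must be >= 2")
  if (isTRUE(config$stages$simulate)) {
    sim_cfg <- do.call(sim_config, c(config$simulate,
                                     list(seed = config$seed)))
    validate_sim_config(sim_cfg)
  } else {
    .assert(!is.null(config$input_dir),
            "input_dir required when the simulate stage is off")
  }
  invisible(config)
}

#' Identify the resistant (rMDSC-like) cluster among stressed cells
#'
#' The resistant flag is never read by the pipeline; instead, the
#' cluster is found the way the study logic dictates: resistant cells
#' are the stressed cells with *preserved MDSC features*. Every detected
#' co-expression module whose member genes are predominantly
#' cytokine-induced (significant and up in T vs C) is scored per cell;
#' among clusters whose cells are mostly from the stressed (TS) group,
#' the resistant cluster is the one in which some cytokine-induced
#' module remains most highly expressed (maximum over induced modules of
#' the cluster-mean signature score). Taking the maximum rather than the
#' average makes the call robust to induced programs that collapse under
#' stress: preserving any full MDSC program marks resistance.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param clusters per-cell cluster labels.
#' @param group per-cell group labels (C/T/TS).
#' @param deg_ct T-vs-C [wilcoxon_de()] table (A = T).
#' @param assignment gene -> module vector from the network stage.
#' @param padj_cutoff,lfc_cutoff significance gates defining induced
#'   genes.
#' @param induced_fraction minimum fraction of induced member genes for
#'   a module to count as cytokine-induced.
#' @param min_cells smallest cluster considered.
#' @return list with `cluster` (label), `induced_modules`,
#'   `module_scores` (cells x induced modules), `candidates`.
#' @export
identify_resistant_cluster <- function(norm, clusters, group, deg_ct,
                                       assignment,
                                       padj_cutoff = 0.05,
                                       lfc_cutoff = 0.25,
                                       induced_fraction = 0.5,
                                       min_cells = 10L) {
  induced_gene <- deg_ct$gene[deg_ct$padj < padj_cutoff &
                                deg_ct$log2fc >= lfc_cutoff]
  mods <- setdiff(unique(assignment), "grey")
  frac_ind <- vapply(mods, function(m) {
    genes <- names(assignment)[assignment == m]
    mean(genes %in% induced_gene)
  }, numeric(1))
  induced <- mods[frac_ind >= induced_fraction]
  if (length(induced) == 0L) induced <- mods[which.max(frac_ind)]
  .assert(length(induced) >= 1L, "no cytokine-induced module found")
  module_scores <- vapply(induced, function(m) {
    signature_score(norm, names(assignment)[assignment == m])
  }, numeric(ncol(norm)))
  tab <- table(clusters, group)
  frac_ts <- tab[, "TS"] / rowSums(tab)
  sizes <- rowSums(tab)
  cand <- rownames(tab)[frac_ts > 0.5 & sizes >= min_cells]
  .assert(length(cand) >= 1L, "no TS-dominated cluster found")
  score <- vapply(cand, function(cl) {
    max(colMeans(module_scores[clusters == cl, , drop = FALSE]))
  }, numeric(1))
  list(cluster = cand[which.max(score)], induced_modules = induced,
       module_scores = module_scores,
       candidates = data.frame(cluster = cand, frac_ts = frac_ts[cand],
                               score = score, stringsAsFactors = FALSE))
}

#' Run the full discovery pipeline
#'
#' Executes, on synthetic or loaded data: normalization, HVG selection,
#' PCA, graph clustering, the two DEG contrasts (T vs C; resistant
#' cluster vs other stressed cells), metacell aggregation, per-donor
#' soft thresholds, consensus TOM, module detection, eigengenes/kME,
#' module-trait correlation, tolerance quadrant classification, module
#' down-selection, signature scoring with ROC AUC on the single-cell
#' contrasts and the multi-source bulk set, kME-ranked GSEA, and CNV
#' inference. Each stage writes its artifact under `out_dir` and the
#' manifest records provenance (config hash, per-file checksums, derived
#' seeds). Any stage failure aborts with the failing stage named and a
#' `FAILED` marker next to the partial outputs.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @param out_dir output directory; `NULL` for a temporary directory.
#' @return list with `results` (in-memory stage outputs) and `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  validate_pipeline_config(config)
  if (is.null(out_dir)) out_dir <- tempfile("stressmod_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  on_stage <- function(s) isTRUE(config$stages[[s]])
  seeds <- stats::setNames(
    lapply(.pipeline_stages, function(s) .derive_seed(config$seed, s)),
    .pipeline_stages)
  manifest <- list(tool = "stressmod",
                   version = as.character(utils::packageVersion("stressmod")),
                   config_hash = .config_hash(config),
                   seed = config$seed, stage_seeds = seeds,
                   started = format(Sys.time(), usetz = TRUE),
                   stages = list())
  res <- list()
  current_stage <- NULL
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      outputs = basename(files),
      checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                          basename(files))),
      timestamp = format(Sys.time(), usetz = TRUE))
  }
  run <- tryCatch({
    # ---- simulate / load -------------------------------------------
    current_stage <- "simulate"
    if (on_stage("simulate")) {
      sim_cfg <- do.call(sim_config, c(config$simulate,
                                       list(seed = seeds$simulate)))
      sc <- simulate_sc_experiment(sim_cfg)
      bulk <- simulate_bulk_sources(sim_cfg)
      sim_dir <- file.path(out_dir, "simulate")
      write_counts_10x(sc, sim_dir)
      utils::write.table(
        data.frame(sample = bulk$sample_meta$sample,
                   bulk$sample_meta[, c("source", "is_mdsc")],
                   t(bulk$expr)), file.path(sim_dir, "bulk_expr.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      record("simulate", list.files(sim_dir, full.names = TRUE))
    } else {
      counts <- load_counts_mtx(config$input_dir)
      meta_path <- file.path(config$input_dir, "cell_meta.tsv")
      .assert(file.exists(meta_path), "cell_meta.tsv required alongside the triplet")
      cell_meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
      gm_path <- file.path(config$input_dir, "gene_meta.tsv")
      gene_meta <- if (file.exists(gm_path))
        utils::read.table(gm_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE) else NULL
      sc <- list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta, truth = NULL)
      bulk <- NULL
    }
    res$sc <- sc
    res$bulk <- bulk

    # ---- preprocess -------------------------------------------------
    current_stage <- "preprocess"
    pp <- config$preprocess
    norm <- normalize_log_cp10k(sc$counts)
    n_hvg <- min(pp$n_hvg, nrow(norm))
    hvgs <- select_hvgs(norm, n_top = n_hvg)
    z <- zscore_genes(norm[hvgs, , drop = FALSE])
    n_pcs <- min(pp$n_pcs, nrow(z) - 1L, ncol(z) - 1L)
    pca <- compute_pca(z, n_components = n_pcs, clip = pp$clip)
    res$norm <- norm; res$hvgs <- hvgs; res$pca <- pca
    pp_dir <- file.path(out_dir, "preprocess"); dir.create(pp_dir, showWarnings = FALSE)
    .write_stage_tsv(data.frame(gene = hvgs), file.path(pp_dir, "hvgs.tsv"),
                     "preprocess", list(n_hvg = n_hvg))
    .write_stage_tsv(data.frame(cell = rownames(pca$cell_scores),
                                round(pca$cell_scores, 6)),
                     file.path(pp_dir, "pca_cell_scores.tsv"),
                     "preprocess", list(n_pcs = n_pcs, clip = pp$clip))
    record("preprocess", list.files(pp_dir, full.names = TRUE))

    # ---- cluster ----------------------------------------------------
    current_stage <- "cluster"
    clusters <- cluster_cells(pca, k_neighbors = config$cluster$k_neighbors,
                              resolution = config$cluster$resolution,
                              seed = seeds$cluster)
    res$clusters <- clusters
    cl_dir <- file.path(out_dir, "cluster"); dir.create(cl_dir, showWarnings = FALSE)
    .write_stage_tsv(data.frame(cell = names(clusters), cluster = clusters),
                     file.path(cl_dir, "clusters.tsv"), "cluster",
                     config$cluster)
    record("cluster", list.files(cl_dir, full.names = TRUE))

    # ---- differential expression: cytokine contrast -----------------
    current_stage <- "de"
    grp <- sc$cell_meta$group
    de_par <- config$de
    deg_ct <- wilcoxon_de(norm, which(grp == "T"), which(grp == "C"),
                          contrast = "T_vs_C")
    res$deg_ct <- deg_ct
    de_dir <- file.path(out_dir, "de"); dir.create(de_dir, showWarnings = FALSE)
    .write_stage_tsv(deg_ct, file.path(de_dir, "deg_T_vs_C.tsv"), "de", de_par)

    # ---- metacells --------------------------------------------------
    current_stage <- "metacells"
    mc <- make_metacells(norm, pca, sc$cell_meta$donor,
                         k_agg = config$metacells$k_agg,
                         max_shared = config$metacells$max_shared,
                         seed = seeds$metacells)
    res$metacells <- mc

    # ---- consensus modules ------------------------------------------
    current_stage <- "modules"
    mo <- config$modules
    powers <- pick_soft_threshold(mc, powers = mo$powers)
    donors <- unique(mc$donor)
    toms <- lapply(donors, function(d) {
      compute_tom(build_adjacency(mc, beta = powers[[d]], donor = d))
    })
    cons <- consensus_tom(toms, q = mo$consensus_q)
    assignment <- detect_modules(cons, min_module_size = mo$min_module_size,
                                 cut_height = mo$cut_height)
    me <- module_eigengenes(mc, assignment)
    kme <- compute_kme(mc, me)
    if (mo$kme_gap > 0)
      assignment <- reassign_by_kme(assignment, kme, gap = mo$kme_gap)

    # ---- resistance contrast (needs the detected modules) -----------
    current_stage <- "de"
    # when one cluster swallows (nearly) the whole TS compartment the
    # resistance contrast is undefined; recluster the TS cells alone
    ts_tab <- table(clusters[grp == "TS"])
    if (max(ts_tab) / sum(ts_tab) > 0.9) {
      ts_cells <- sc$cell_meta$cell[grp == "TS"]
      sub_pca <- pca
      sub_pca$cell_scores <- pca$cell_scores[ts_cells, , drop = FALSE]
      sub_lab <- cluster_cells(sub_pca,
                               k_neighbors = config$cluster$k_neighbors,
                               resolution = config$cluster$resolution,
                               seed = .derive_seed(seeds$cluster, "ts_refine"))
      clusters <- as.character(clusters)
      names(clusters) <- sc$cell_meta$cell
      clusters[ts_cells] <- paste0("TS.", sub_lab)
      res$clusters <- clusters
    }
    rid <- identify_resistant_cluster(norm, clusters, grp, deg_ct,
                                      assignment,
                                      padj_cutoff = de_par$padj_cutoff,
                                      lfc_cutoff = de_par$lfc_cutoff)
    is_ts <- grp == "TS"
    in_r <- clusters == rid$cluster
    deg_r <- wilcoxon_de(norm, which(is_ts & in_r), which(is_ts & !in_r),
                         contrast = "rMDSC_vs_otherTS")
    res$deg_r <- deg_r; res$resistant_cluster <- rid
    .write_stage_tsv(deg_r, file.path(de_dir, "deg_rMDSC_vs_otherTS.tsv"),
                     "de", de_par)
    record("de", list.files(de_dir, full.names = TRUE))

    current_stage <- "modules"
    cell_r <- stats::setNames(as.numeric(in_r), sc$cell_meta$cell)
    traits <- cbind(
      frac_C = metacell_summary(mc, stats::setNames(as.numeric(grp == "C"),
                                                    sc$cell_meta$cell)),
      frac_T = metacell_summary(mc, stats::setNames(as.numeric(grp == "T"),
                                                    sc$cell_meta$cell)),
      frac_TS = metacell_summary(mc, stats::setNames(as.numeric(grp == "TS"),
                                                     sc$cell_meta$cell)),
      frac_rMDSC = metacell_summary(mc, cell_r))
    trait_cor <- module_trait_correlation(me, traits)
    res$soft_powers <- powers; res$assignment <- assignment
    res$eigengenes <- me; res$kme <- kme; res$trait_cor <- trait_cor
    mod_dir <- file.path(out_dir, "modules"); dir.create(mod_dir, showWarnings = FALSE)
    .write_stage_tsv(data.frame(gene = names(assignment), module = assignment),
                     file.path(mod_dir, "assignment.tsv"), "modules",
                     list(min_module_size = mo$min_module_size,
                          cut_height = mo$cut_height,
                          consensus_q = mo$consensus_q,
                          powers = paste(unlist(powers), collapse = "/")))
    .write_stage_tsv(data.frame(metacell = rownames(me), round(me, 6)),
                     file.path(mod_dir, "eigengenes.tsv"), "modules", list())
    .write_stage_tsv(data.frame(gene = rownames(kme), round(kme, 6)),
                     file.path(mod_dir, "kme.tsv"), "modules", list())
    .write_stage_tsv(data.frame(module = rownames(trait_cor$cor),
                                round(trait_cor$cor, 6)),
                     file.path(mod_dir, "module_trait_cor.tsv"), "modules",
                     list())
    record("modules", list.files(mod_dir, full.names = TRUE))

    # ---- tolerance classification & down-selection ------------------
    current_stage <- "tolerance"
    tol <- classify_gene_tolerance(deg_ct, deg_r,
                                   padj_cutoff = de_par$padj_cutoff,
                                   lfc_cutoff = de_par$lfc_cutoff,
                                   assignment = assignment)
    candidates <- downselect_modules(assignment, tol,
                                     min_shared = config$tolerance$min_shared)
    composition <- module_tolerance_composition(assignment, tol)
    res$tolerance <- tol; res$candidates <- candidates
    res$composition <- composition
    tol_dir <- file.path(out_dir, "tolerance"); dir.create(tol_dir, showWarnings = FALSE)
    .write_stage_tsv(tol, file.path(tol_dir, "tolerance.tsv"), "tolerance",
                     config$tolerance)
    jsonlite::write_json(candidates, file.path(tol_dir, "candidates.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    record("tolerance", list.files(tol_dir, full.names = TRUE))

    # ---- scoring ----------------------------------------------------
    current_stage <- "scoring"
    lab_tc <- ifelse(grp == "T", TRUE, ifelse(grp == "C", FALSE, NA))
    lab_r <- ifelse(is_ts, in_r, NA)
    sc_eval <- evaluate_module_separation(
      assignment, norm, list(T_vs_C = lab_tc, rMDSC_vs_otherTS = lab_r))
    res$sc_eval <- sc_eval
    if (!is.null(bulk)) {
      bulk_eval <- evaluate_module_separation(
        assignment, bulk$expr, list(MDSC_vs_ctrl = bulk$sample_meta$is_mdsc))
      res$bulk_eval <- bulk_eval
    }
    sco_dir <- file.path(out_dir, "scoring"); dir.create(sco_dir, showWarnings = FALSE)
    .write_stage_tsv(data.frame(module = rownames(sc_eval$auc),
                                round(sc_eval$auc, 6)),
                     file.path(sco_dir, "sc_auc.tsv"), "scoring", list())
    if (!is.null(bulk))
      .write_stage_tsv(data.frame(module = rownames(res$bulk_eval$auc),
                                  round(res$bulk_eval$auc, 6)),
                       file.path(sco_dir, "bulk_auc.tsv"), "scoring", list())
    record("scoring", list.files(sco_dir, full.names = TRUE))

    # ---- kME-ranked GSEA -------------------------------------------
    current_stage <- "gsea"
    if (on_stage("gsea")) {
      top_mod <- if (nrow(candidates) > 0L) candidates$module[1L] else
        sc_eval$best
      gene_sets <- if (!is.null(config$gsea$gmt)) {
        read_gmt(config$gsea$gmt)
      } else if (on_stage("simulate")) {
        stats::setNames(lapply(sc$truth$modules, `[[`, "gene_ids"),
                        vapply(sc$truth$modules, `[[`, character(1), "name"))
      } else NULL
      if (!is.null(gene_sets) && top_mod %in% colnames(kme)) {
        ranking <- stats::setNames(kme[, top_mod], rownames(kme))
        gsea_res <- preranked_gsea(ranking, gene_sets,
                                   n_perm = config$gsea$n_perm,
                                   seed = seeds$gsea,
                                   min_size = config$gsea$min_size)
        res$gsea <- gsea_res
        res$gsea_module <- top_mod
        gsea_dir <- file.path(out_dir, "gsea"); dir.create(gsea_dir, showWarnings = FALSE)
        .write_stage_tsv(gsea_res, file.path(gsea_dir, "gsea.tsv"), "gsea",
                         list(module = top_mod, n_perm = config$gsea$n_perm))
        record("gsea", list.files(gsea_dir, full.names = TRUE))
      }
    }

    # ---- CNV inference ---------------------------------------------
    current_stage <- "cnv"
    if (on_stage("cnv") && !is.null(sc$gene_meta)) {
      ref <- sc$cell_meta$cell[grp == "C"]
      prof <- infer_cnv_profile(norm, sc$gene_meta, ref,
                                window = config$cnv$window,
                                clip = config$cnv$clip)
      # subcluster within the cytokine-treated group so copy-number
      # structure is not confounded with between-group programs
      treated <- sc$cell_meta$cell[grp == "T"]
      sub_prof <- prof
      sub_prof$matrix <- prof$matrix[treated, , drop = FALSE]
      cnv_cl <- subcluster_cnv(sub_prof, k = config$cnv$k)
      res$cnv_profile <- prof; res$cnv_clusters <- cnv_cl
      cnv_dir <- file.path(out_dir, "cnv"); dir.create(cnv_dir, showWarnings = FALSE)
      .write_stage_tsv(data.frame(cell = names(cnv_cl$cluster),
                                  cluster = cnv_cl$cluster,
                                  burden = round(cnv_cl$burden, 6)),
                       file.path(cnv_dir, "cnv_clusters.tsv"), "cnv",
                       config$cnv)
      record("cnv", list.files(cnv_dir, full.names = TRUE))
    }
    TRUE
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", current_stage, "\n",
                      conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = res, manifest = manifest, out_dir = out_dir))
}

# md5 of the canonical JSON serialization of a config
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Deterministic checksums from a run manifest
#'
#' Flattens the per-stage file checksums (timestamps excluded) for
#' reproducibility comparisons: two runs with identical config and seed
#' must agree on every value.
#'
#' @param manifest a [run_pipeline()] manifest.
#' @return Named character vector `stage/file -> md5`.
#' @export
manifest_checksums <- function(manifest) {
  out <- character(0)
  for (s in names(manifest$stages)) {
    ck <- unlist(manifest$stages[[s]]$checksums)
    names(ck) <- paste0(s, "/", names(ck))
    out <- c(out, ck)
  }
  out
}
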