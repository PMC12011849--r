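# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# default-condition single-cell simulation (seed fixed for the suite)
fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_sc_experiment(sim_config(seed = 42L))
  }
  .fixture_env$sim
}

fixture_norm <- function() {
  if (is.null(.fixture_env$norm)) {
    .fixture_env$norm <- normalize_log_cp10k(fixture_sim()$counts)
  }
  .fixture_env$norm
}

fixture_pca <- function() {
  if (is.null(.fixture_env$pca)) {
    norm <- fixture_norm()
    hv <- select_hvgs(norm, 300L)
    .fixture_env$pca <- compute_pca(zscore_genes(norm[hv, ]), 20L)
  }
  .fixture_env$pca
}

# one full default pipeline run, reused by several module tests
fixture_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- suppressWarnings(
      run_pipeline(default_pipeline_config(seed = 42L)))
  }
  .fixture_env$run
}

# planted gene sets of the fixture simulation
fixture_truth_sets <- function() {
  sc <- fixture_sim()
  sets <- split(sc$gene_meta$gene, sc$gene_meta$module)
  sets$none <- NULL
  sets
}

# map each planted module to its best-matching detected module label
fixture_module_map <- function(assignment) {
  truth <- fixture_truth_sets()
  vapply(truth, function(tg) {
    tab <- table(assignment[tg])
    names(which.max(tab))
  }, character(1))
}
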