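# stressmod

Discovery and evaluation of **stress-tolerant gene co-expression
modules** as cross-source signatures of monocytic myeloid-derived
suppressor cells (M-MDSCs).

## The problem

MDSC transcriptomic signatures rarely transfer between sources: a gene
panel that separates MDSCs from control monocytes in one induction model
or tissue often fails in another. `stressmod` implements a discovery
procedure built on a selection principle: expose cytokine-induced
myeloid cells to an additional stressor (serum starvation), find the
subpopulation that *resists* it while keeping MDSC features, and keep
only the co-expression modules whose cytokine induction survives the
stress. Genes are classified by a dual-contrast quadrant rule — log2
fold change of treated vs control cells on one axis, resistant vs other
stressed cells on the other — into *stress-tolerant* (concordant) and
*stress-sensitive* (discordant) groups, and candidate modules are those
dominated by tolerant genes.

The toolkit provides, as composable functions behind one pipeline:

* a seeded **synthetic-data generator** (negative-binomial single-cell
  counts with planted co-expression modules, a resistant subpopulation,
  copy-number blocks, and a paired multi-source bulk design) with full
  ground truth for validation;
* **preprocessing**: log-CP10K normalization, HVG selection, PCA,
  SNN-graph Leiden clustering;
* **differential expression**: vectorized tie-corrected Wilcoxon
  rank-sum tests with BH adjustment;
* **consensus co-expression networks** on metacells: signed adjacency
  `((1 + r)/2)^beta`, scale-free soft-threshold selection, topological
  overlap matrices, per-donor consensus (parallel minimum after
  percentile calibration), static tree cut, module eigengenes, kME,
  module-trait correlation, hub genes;
* **tolerance classification** and module down-selection;
* **signature scoring** (mean of gene-wise z-scores) with logistic/ROC
  evaluation (rank AUC with tie half-credit), a centroid label-transfer
  classifier, and OLS pathway-association tests;
* **pre-ranked GSEA** with a Monte-Carlo gene-permutation null;
* **copy-number inference** from expression (reference-centered,
  clipped, chromosome-wise moving average, per-cell recentering) with
  SCNV-high/low subclustering.

## Worked example

```r
library(stressmod)

run <- run_pipeline(default_pipeline_config(seed = 42), out_dir = "run42")

# which modules survived down-selection?
run$results$candidates[, c("module", "n_shared", "tolerant_fraction")]
#>   module n_shared tolerant_fraction
#> 1    red       50                 1

# module x contrast AUCs on the single-cell data
round(run$results$sc_eval$auc, 3)
#>           T_vs_C rMDSC_vs_otherTS
#> red        0.902            0.970
#> turquoise  0.037            0.345
#> blue       0.034            0.367
#> yellow     0.891            0.089
#> green      0.313            0.363
#> brown      0.492            0.394

# and on the simulated multi-source bulk set
round(run$results$bulk_eval$auc, 3)
#>           MDSC_vs_ctrl
#> red              1.000
#> turquoise        0.438
#> blue             0.510
#> yellow           0.635
#> green            0.445
#> brown            0.555
```

At this seed the detected `red` module is the planted stress-tolerant
module (module colors follow the size-rank convention, so the label
varies between runs). It is the only down-selected candidate: all 50 of
its shared DEGs fall in the tolerant-up quadrant. It achieves the best
minimum AUC across the two single-cell contrasts (0.902 / 0.970) and
separates MDSC from control samples across all five simulated bulk
sources (AUC 1.0), while `yellow` — the planted stress-sensitive module,
equally cytokine-induced — collapses in the resistance contrast (AUC
0.089, i.e. strongly *down* in resistant cells) and generalizes poorly
across bulk sources (AUC 0.635). That ordering — tolerant modules
travel across sources, sensitive ones do not — is the package's central
reproducible claim.

Per-stage artifacts (DEG tables, module assignment, kME, tolerance
quadrants, AUC tables, CNV clusters) are written under `run42/` as TSV
with provenance headers, plus `manifest.json` with config hash, derived
seeds, and file checksums.

A thin command-line wrapper ships in `inst/scripts/stressmod.R`:

```sh
Rscript inst/scripts/stressmod.R run --seed 42 --out run42
Rscript inst/scripts/stressmod.R simulate --seed 1 --out simdata
Rscript inst/scripts/stressmod.R gsea --ranking kme.tsv --gmt sets.gmt
```

## Scope

All quantitative guarantees are demonstrated on the bundled generator
(see the methods vignette for the generative model, parameter defaults,
and what the simulation does *not* emulate). The package does not bundle
any external dataset, gene-set collection, or published signature.
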