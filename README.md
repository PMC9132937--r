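# cibop

Analysis toolkit for **cell type-specific in vivo biotinylation
proteomics** (CIBOP): experiments in which the biotin ligase TurboID is
expressed in one cell type of a living animal, biotinylated proteins are
enriched on streptavidin and quantified by label-free mass spectrometry
(LFQ-MS), and matched multiplex immunoassays read the biotinylated
(cell-type-derived) pool of cytokines and phospho-proteins directly.

The package is for proteomics analysts working downstream of a
MaxQuant-style search: it consumes `proteinGroups.txt`-like intensity
tables and plate fluorescence matrices and produces enrichment calls,
regional protein signatures, over-representation statistics, and
bait-normalized cell-type-derived analyte levels — together with a
synthetic-data generator whose planted ground truth validates every stage.

## What it computes

**Preprocessing (Perseus-equivalent).** Intensities are log2 transformed;
rows are filtered by a minimum number of valid values (total, or per
design group); missing values are imputed from a down-shifted normal: for
a sample with observed mean μ and sd σ, each missing cell is drawn from

    N(μ − shift·σ, (width·σ)²),  width = 0.3, shift = 1.8

modeling left-censored (low-abundance) dropout. Abundances are then
normalized to the bait: with per-sample bait log2 value b_j and reference
r, every value is shifted x_ij ← x_ij − (b_j − r), so the bait becomes
constant across samples and within-sample structure is preserved exactly.

**Differential enrichment.** Per-protein unpaired two-sided t-tests
(pooled-variance Student by default, Welch available). A protein is called
enriched when |log2 FC| ≥ log2(2) and unadjusted p ≤ 0.05 (both
boundary-inclusive); core regional signatures use one-vs-rest tests at
≥4-fold, p ≤ 0.05, with multi-region qualifiers assigned to the
max-fold-change region.

**Over-representation.** For background size N, term size K, hit-list
size n and overlap k: exact hypergeometric tail p = P(X ≥ k) and the
finite-population-corrected Z

    z = (k − nK/N) / sqrt( n·(K/N)·(1−K/N)·(N−n)/(N−1) ),

with gene sets flagged enriched at z > 1.96.

**Immunoassay (Luminex) processing.** Background subtraction with
clipping at zero; the cell-type-derived fraction as the adapted/standard
signal ratio with a ≥50% predominant-origin rule; control subtraction and
per-region bait normalization of adapted signal; avidin-blocking control
checks.

**Exploration.** PCA of samples, UPGMA clustering on 1 − Pearson
distances, K-means profile clustering (k = 5 default), annotation-list
intersection, and a z-scored joint MS + immunoassay matrix for integrated
embeddings.

## Worked example

The shipped demo simulates a regional cohort (600 proteins, 2 genotypes ×
2 mice × 5 brain regions × 2 technical replicates, 10% enriched proteins
at Δlog2 = 3, 9 of them region-specific at Δlog2 = 2.5, residual sd 0.5,
MNAR dropout) and runs the full pipeline:

```r
library(cibop)
cfg <- pipeline_config_from_yaml(system.file("extdata",
         "demo_config.yaml", package = "cibop"))
cfg$out_dir <- "demo_out"
res <- run_pipeline(cfg)

res$recovery
#> recovery_metrics [enrichment]
#>   sensitivity: 0.983  specificity: 1  FDR: 0

res$recovery_regional
#> recovery_metrics [regional]
#>   9/9 regional proteins in correct region (0 wrong, 0 false)

table(res$enrichment$class)
#> enriched_a         ns
#>         59        538
```

`sensitivity` is the fraction of truly enriched proteins that survive
preprocessing and are called at ≥2-fold / p ≤ 0.05 against controls;
`FDR` the fraction of calls that are false; the regional block counts
planted region-specific proteins recovered in their correct region by the
one-vs-rest ≥4-fold rule. All tables in `demo_out/` carry a provenance
header (seed, configuration hash) and are byte-identical across re-runs.

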