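---
title: "Methods: from biotinylated proteomes to cell-type signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from biotinylated proteomes to cell-type signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cibop)
```

## The experimental system

In cell type-specific in vivo biotinylation proteomics, a promiscuous
biotin ligase (TurboID, carrying a V5 tag) is expressed in one cell type
of the mouse brain via a Cre driver, biotin is supplied in drinking
water, and biotinylated proteins are enriched from regional lysates on
streptavidin beads and quantified by label-free MS. Control animals do
not express the ligase; what streptavidin still retrieves from them —
chiefly the endogenously biotinylated carboxylases (pyruvate carboxylase
and relatives) plus nonspecific binders — defines the background
proteome. The ligase's own MS intensity in each labeled sample is a
built-in internal standard: it tracks per-region differences in ligase
expression and labeling efficiency, and the analysis normalizes to it.

This vignette explains each modeling choice the package makes, its
defaults, and what the validation on synthetic data does and does not
demonstrate.

## Preprocessing

**Missingness and imputation.** Label-free MS reports an unquantified
protein as intensity 0; `read_protein_groups()` converts zeros to
missing. Missingness in LFQ is predominantly left-censored — dim peptides
drop below the identification limit — so missing values are imputed from
a normal distribution shifted below the observed signal:
for a sample with observed mean $\mu$ and standard deviation $\sigma$,
each missing cell is drawn independently from
$\mathcal N(\mu - 1.8\sigma,\ (0.3\sigma)^2)$. The width 0.3 and
down-shift 1.8 are the established Perseus defaults for this procedure
and are exposed as `ImputationParams`. Moments are computed **per
sample** from observed values only (also the Perseus convention); a
whole-matrix scope is available. Each sample draws from its own sub-seed
(`derive_seed(seed, paste0("impute/", sample))`), so removing a sample
never perturbs the draws of the others.

**Valid-value filtering.** Before imputation, rows with too few observed
values are removed — imputing a protein observed once would manufacture
data. The scheme is either a minimum count across all samples or a
minimum within every listed design group. The pipeline default restricts
the per-group rule to the labeled (IP) samples: proteins absent from
controls are exactly the interesting ones, and the bait itself is
structurally absent from controls, so requiring validity in the control
group would delete it.

**Bait normalization.** With bait log2 value $b_j$ in sample $j$ and
reference $r$ (default: mean of $b_j$ over normalized samples), every
value is shifted $x_{ij} \leftarrow x_{ij} - (b_j - r)$. On the linear
scale this is division by the bait intensity ratio; in log2 space it is a
per-sample additive shift, which preserves every within-sample difference
$x_{ij} - x_{kj}$ exactly and makes the bait row constant. Control
samples lacking a bait value are exempted with a warning rather than
silently normalized. Order of operations is filter → impute → normalize;
on a fully observed matrix the first two are no-ops, so the order only
matters through which values feed the imputation moments, and it is
configurable.

## Differential enrichment

Per-protein unpaired two-sided t-tests compare labeled against control
samples (or one labeled driver against another). The pooled-variance
Student test is the default — technical replicates are treated as
independent columns, matching how such designs are usually analyzed in
Perseus — with Welch available for unequal variances. Degenerate variance
is handled explicitly: zero variance with equal means reports $t = 0$,
$p = 1$; zero variance with unequal means reports the machine-minimum p
and a `degenerate` flag (and is plotted at a capped $-\log_{10} p$).

Classification uses unadjusted p values by design: the enrichment
contrast is a validation screen with an expected massive effect, not a
discovery screen, and downstream over-representation operates on the
resulting lists rather than on individual proteins. Benjamini–Hochberg
adjustment is available as an opt-in column. Thresholds are
boundary-inclusive: exactly 2-fold at exactly p = 0.05 is called.

Core regional signatures run the same test one-region-vs-pooled-rest at
≥4-fold, p ≤ 0.05. With noisy data a protein can qualify in two regions;
it is then assigned to the region of maximal fold change and flagged
`multi_region`. Region groups are configurable (e.g. merging cortex and
hippocampus, whose profiles are close) rather than hard-coded.

## Over-representation

For a hit list of size $n$ within a fixed background of $N$ symbols and
a term covering $K$ of them, the overlap $k$ is scored two ways: the
exact hypergeometric upper tail $P(X \ge k)$ (equal to the one-sided
Fisher exact p of the 2×2 table), and the normal-approximation Z with
finite-population correction,
$$ z = \frac{k - nK/N}{\sqrt{\,n\,\tfrac KN\,(1-\tfrac KN)\,\tfrac{N-n}{N-1}}}. $$
Both are reported; the `enriched` flag follows $z > 1.96$, the operative
criterion in the AltAnalyze-style workflow this mirrors, with a
strict-Fisher mode available because the two disagree for small terms.
Symbols are upper-cased before any set operation (mouse `Gfap` must match
human-cased `GFAP` in curated lists), duplicate hits are removed, and
hits outside the background are dropped with a count — standard ORA
hygiene. Multi-symbol protein groups contribute their first symbol.

## Adapted immunoassay model

The standard Luminex sandwich assay reads total analyte through a
biotinylated detection antibody. The adapted assay omits that antibody,
so the streptavidin fluorophore reports only analytes biotinylated in
vivo — the cell-type-derived pool. Processing follows the signal model
directly: subtract per-analyte background (clipping at zero, since
fluorescence cannot be negative; clips are logged), form the
cell-type-derived fraction adapted/standard with a ≥50% rule for
predominant origin, and for regional comparisons subtract the
control-animal adapted signal (endogenous-biotin background) and divide
by the region's relative bait abundance from MS — linear-scale, because
fluorescence is linear. The normalization is therefore homogeneous of
degree −1 in bait abundance, a property the tests check exactly. The
avidin-blocking control (which should abolish adapted signal) is
summarized as a per-analyte residual fraction with a median-based pass
rule (default tolerance 0.1).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with planted truth for recovery scoring:

* two genotypes (labeled/control), `mice_per_group` mice each, dissected
  into regions, with per-region technical replicate counts (the default
  layout, 2 mice × 5 regions × 2 technical replicates, mirrors a
  regional cohort; a per-region override reproduces an 18-column layout
  with a 2-column hippocampus);
* baseline protein abundances $\mathcal N(24, 2^2)$ on the log2 scale —
  typical LFQ intensity magnitudes;
* a fraction (default 10%) of proteins enriched by `delta_enrich`
  (default 3 log2 units) in labeled samples, a fraction of those with an
  extra regional effect (`delta_region`, default 2.5) in one region;
* a bait row present only in labeled samples at configurable per-region
  levels — controls carry a structural missing value, which is what
  forces the bait-exemption logic downstream;
* endogenous-biotin proteins at equal expectation in both genotypes;
* additive Gaussian noise on the log2 scale (log-normal intensities),
  the standard LFQ assumption. `noise_sd` is defined as the marginal
  within-group sd of a sample column; it decomposes into a mouse-level
  draw shared by technical replicates (sd $\sqrt{3}/2 \cdot$ `noise_sd`)
  plus technical noise (sd `noise_sd`/2), so replicate columns of one
  mouse are correlated while the marginal sd stays `noise_sd` exactly;
* missing-not-at-random dropout applied afterwards on the log2 scale:
  each cell is removed with probability
  $\mathrm{logit}^{-1}((m - x)/s)$, a logistic in intensity with
  midpoint $m$ and slope $s$. The true censoring mechanism of LFQ is not
  known and the imputation literature only implies left-censoring; the
  logistic is a modeling stand-in chosen for its hard-threshold limit
  ($s \to 0$) and closed-form checkability, not an empirical claim.

All randomness flows from one master seed through string-keyed sub-seeds
(`derive_seed`), so identical configurations are bit-identical and
stages can be regenerated independently.

**What passing recovery tests show — and what they do not.** The
generator's world is normal, homoscedastic within groups, and free of
correlated contaminants, batch structure, shared-peptide ambiguity, and
ratio compression. Sensitivity/FDR measured on it validate the
*arithmetic and wiring* of the pipeline under its own assumptions; they
are not estimates of performance on real tissue data, where effect-size
distributions and missingness are less benign.

## Numerical choices and problem sizes

Ties at classification boundaries are inclusive (`≥`, `≤`). Constant
rows are errors for correlation distances (undefined), dropped with a
warning for z-scoring and clustering. K-means uses 25 restarts under a
derived seed; if fewer distinct profiles than k exist, k is reduced with
a warning. PCA fixes each component's sign so its largest-magnitude
loading is positive. The validation suite uses 2,000-protein cohorts
with 3 samples per group over 20 seeds for enrichment recovery,
1,000-protein 4-region cohorts (4 samples per region, 30 planted
regional proteins) for signature recovery, 10,000 null proteins for the
type-I error check, and exhaustive backgrounds up to N = 60 for the
hypergeometric/Fisher equivalence — sizes chosen so each property is
measured with comfortable Monte-Carlo margins while the whole suite runs
in seconds.

## Known limitations

No peptide-level modeling, protein rollup, or match-between-runs
simulation; no moderated (empirical-Bayes) test — with n of 2–4 per
group a limma-style approach would gain power but would not mirror the
workflow this package reimplements; no 5PL standard-curve fitting for
the immunoassays (analyses stay in fluorescence units within the assays'
linear range); 2-D embeddings (t-SNE and kin) are pluggable adapters
whose coordinates are deliberately outside the tested contract.
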