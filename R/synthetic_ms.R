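# Synthetic MS dataset generator with known ground truth. Emulates the
# statistical structure that the downstream analysis assumes: a labeled
# genotype expressing the biotin-ligase bait (absent in controls, with
# region-varying abundance), endogenous biotinylated carboxylase background
# present in all samples, planted cell-type enrichment and region-specific
# log-fold-change structure, additive Gaussian noise on the log2 scale
# (log-normal intensities), and intensity-dependent (missing-not-at-random)
# dropout applied as a separate step.

#' Configuration for the synthetic MS dataset generator
#'
#' Defaults mirror the transgenic regional study design: 2 mice per genotype
#' group, five brain regions per mouse, 2 technical replicates per region,
#' ~2000 quantifiable proteins with 10% truly cell-type enriched at a mean
#' log2 effect of 3, and a bait whose log2 abundance varies by region.
#'
#' @param n_proteins number of (non-bait) proteins.
#' @param regions region labels.
#' @param mice_per_group mice per genotype group.
#' @param tech_reps technical replicates per region: a single count, or a
#'   named vector with one entry per region.
#' @param frac_enriched fraction of proteins truly enriched in the labeled
#'   genotype.
#' @param delta_enrich mean log2 enrichment effect (labeled - control).
#' @param frac_regional fraction of the enriched proteins carrying an
#'   additional region-specific effect.
#' @param delta_region mean log2 regional effect.
#' @param base_mean,base_sd location and between-protein spread of baseline
#'   log2 intensity.
#' @param noise_sd within-group residual sd of a sample column on the log2
#'   scale. Technical replicates of one mouse share a mouse-level draw
#'   (sd `noise_sd * sqrt(3)/2`) plus technical noise (sd `noise_sd / 2`),
#'   so the marginal column sd equals `noise_sd`.
#' @param bait_log2_by_region named vector of bait log2 intensity per region
#'   in labeled samples; the bait is structurally absent (missing) in
#'   controls.
#' @param n_endogenous number of endogenous-biotin background proteins
#'   (present at equal expectation in both genotypes), drawn from the
#'   non-enriched proteins.
#' @param dropout_midpoint,dropout_slope logistic missing-not-at-random
#'   dropout parameters (log2 intensity units), applied by
#'   [apply_dropout()], not by the generator itself.
#' @param seed master seed.
#' @return validated list of class `synth_ms_config`.
#' @export
synth_ms_config <- function(n_proteins = 2000L,
                            regions = c("CTX", "HIP", "ST", "PM", "CB"),
                            mice_per_group = 2L,
                            tech_reps = 2L,
                            frac_enriched = 0.10,
                            delta_enrich = 3,
                            frac_regional = 0.15,
                            delta_region = 2.5,
                            base_mean = 24,
                            base_sd = 2,
                            noise_sd = 0.5,
                            bait_log2_by_region = NULL,
                            n_endogenous = 6L,
                            dropout_midpoint = 20,
                            dropout_slope = 1,
                            seed = 1L) {
  if (is.null(bait_log2_by_region))
    bait_log2_by_region <- stats::setNames(
      base_mean + 2 + seq_along(regions) * 0.5, regions)
  cfg <- list(n_proteins = as.integer(n_proteins), regions = regions,
              mice_per_group = as.integer(mice_per_group),
              tech_reps = tech_reps, frac_enriched = frac_enriched,
              delta_enrich = delta_enrich, frac_regional = frac_regional,
              delta_region = delta_region, base_mean = base_mean,
              base_sd = base_sd, noise_sd = noise_sd,
              bait_log2_by_region = bait_log2_by_region,
              n_endogenous = as.integer(n_endogenous),
              dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope, seed = as.integer(seed))
  fr <- c(cfg$frac_enriched, cfg$frac_regional)
  if (any(fr < 0 | fr > 1))
    stop_config("fractions must be in [0, 1]")
  if (cfg$n_proteins < 1L || cfg$mice_per_group < 1L ||
      length(cfg$regions) < 1L)
    stop_config("counts must be >= 1")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (cfg$n_endogenous > cfg$n_proteins)
    stop_config("n_endogenous exceeds n_proteins")
  if (length(cfg$tech_reps) > 1L &&
      !setequal(names(cfg$tech_reps), cfg$regions))
    stop_config("per-region tech_reps must name every region")
  if (!setequal(names(cfg$bait_log2_by_region), cfg$regions))
    stop_config("bait_log2_by_region must have one entry per region")
  structure(cfg, class = "synth_ms_config")
}

tech_reps_for <- function(config, region) {
  tr <- config$tech_reps
  if (length(tr) > 1L) as.integer(tr[[region]]) else as.integer(tr)
}

#' Generate a synthetic MS dataset with known ground truth
#'
#' Simulates a linear-scale intensity matrix (pre-dropout), its sample
#' design, protein metadata, and the planted truth. Labeled samples carry
#' the bait at the configured per-region level; control samples carry no
#' bait (structurally missing). Enriched proteins are elevated by
#' `delta_enrich` in labeled samples; regional proteins additionally by
#' `delta_region` in their region. Endogenous-biotin proteins are present at
#' equal expectation in both genotypes. With `noise_sd = 0` every column
#' equals its true group mean exactly.
#'
#' @param config a [synth_ms_config()].
#' @return list with `matrix` (linear-scale [intensity_matrix()]), `design`,
#'   `meta`, and `truth` (class `synth_truth`: `enriched_ids`,
#'   `regional_map` — named region per regional protein, `endogenous_ids`,
#'   `bait_id`, `true_means` — proteins x genotype:region log2 means).
#' @export
generate_ms_dataset <- function(config) {
  stopifnot(inherits(config, "synth_ms_config"))
  set.seed(derive_seed(config$seed, "ms-dataset"))
  P <- config$n_proteins
  ids <- sprintf("P%05d", seq_len(P))
  bait_id <- "TurboID-V5"

  n_enr <- round(config$frac_enriched * P)
  enriched <- sort(sample.int(P, n_enr))
  n_reg <- round(config$frac_regional * n_enr)
  regional_idx <- if (n_reg > 0) sort(sample(enriched, n_reg)) else integer()
  regional_map <- stats::setNames(
    sample(config$regions, length(regional_idx), replace = TRUE),
    ids[regional_idx])
  endo_pool <- setdiff(seq_len(P), enriched)
  if (config$n_endogenous > length(endo_pool))
    stop_config("not enough non-enriched proteins for endogenous set")
  endogenous <- sort(sample(endo_pool, config$n_endogenous))

  base <- stats::rnorm(P, config$base_mean, config$base_sd)
  names(base) <- ids

  # design: genotype x mouse x region x tech rep
  rows <- list()
  for (g in c("labeled", "control"))
    for (m in seq_len(config$mice_per_group))
      for (r in config$regions)
        for (t in seq_len(tech_reps_for(config, r)))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%s_m%d_t%d", g, r, m, t),
            genotype = g, region = r,
            mouse_id = sprintf("%s_m%d", g, m), tech_rep = t,
            stringsAsFactors = FALSE)
  dd <- do.call(rbind, rows)
  design <- sample_design(dd$sample_id, dd$genotype, dd$region, dd$mouse_id,
                          dd$tech_rep)

  # true log2 group means per (protein, genotype, region)
  cells <- expand.grid(genotype = c("labeled", "control"),
                       region = config$regions, stringsAsFactors = FALSE)
  cell_names <- paste(cells$genotype, cells$region, sep = ":")
  true_means <- matrix(base, nrow = P, ncol = nrow(cells),
                       dimnames = list(ids, cell_names))
  lab_cols <- cells$genotype == "labeled"
  true_means[enriched, lab_cols] <-
    true_means[enriched, lab_cols] + config$delta_enrich
  for (pid in names(regional_map)) {
    cell <- paste("labeled", regional_map[[pid]], sep = ":")
    true_means[pid, cell] <- true_means[pid, cell] + config$delta_region
  }

  mouse_sd <- config$noise_sd * sqrt(3) / 2
  tech_sd <- config$noise_sd / 2

  # mouse-level deviations, shared by technical replicates
  mkeys <- unique(paste(design$mouse_id, design$region, sep = ":"))
  mouse_dev <- matrix(stats::rnorm((P + 1L) * length(mkeys), 0, mouse_sd),
                      nrow = P + 1L, ncol = length(mkeys),
                      dimnames = list(c(ids, bait_id), mkeys))

  log2_vals <- matrix(NA_real_, nrow = P + 1L, ncol = nrow(design),
                      dimnames = list(c(ids, bait_id), design$sample_id))
  for (j in seq_len(nrow(design))) {
    g <- design$genotype[j]
    r <- design$region[j]
    mkey <- paste(design$mouse_id[j], r, sep = ":")
    mu <- true_means[, paste(g, r, sep = ":")]
    tech <- stats::rnorm(P + 1L, 0, tech_sd)
    log2_vals[ids, j] <- mu + mouse_dev[ids, mkey] + tech[seq_len(P)]
    if (g == "labeled") {
      log2_vals[bait_id, j] <- config$bait_log2_by_region[[r]] +
        mouse_dev[bait_id, mkey] + tech[P + 1L]
    }   # bait structurally absent (NA) in controls
  }

  meta <- data.frame(
    protein_group_id = c(ids, bait_id),
    gene_symbol = c(ids, bait_id),
    gene_symbols_full = c(ids, bait_id),
    is_reverse = FALSE, is_contaminant = FALSE,
    is_bait = c(rep(FALSE, P), TRUE),
    is_endogenous_biotin = c(seq_len(P) %in% endogenous, FALSE),
    stringsAsFactors = FALSE)

  truth <- structure(list(enriched_ids = ids[enriched],
                          regional_map = regional_map,
                          endogenous_ids = ids[endogenous],
                          bait_id = bait_id,
                          true_means = true_means,
                          config = config),
                     class = "synth_truth")
  list(matrix = intensity_matrix(2^log2_vals, scale = "linear"),
       design = design, meta = meta, truth = truth)
}

#' Apply intensity-dependent (MNAR) dropout to a log2 matrix
#'
#' Each cell is set missing independently with probability
#' `plogis((midpoint - x) / slope)`: low-intensity values drop out more
#' often, high-intensity values are retained — the left-censoring pattern
#' that down-shifted imputation assumes. As `slope` approaches 0 the rule
#' becomes a hard threshold at `midpoint`. The number of cells never
#' changes; only the missingness mask does, and no column is ever emptied
#' completely (if a draw would empty a column, its highest-intensity cell is
#' retained).
#'
#' @param mat a log2-scale [intensity_matrix()].
#' @param midpoint log2 intensity at which the dropout probability is 0.5.
#' @param slope logistic scale parameter (> 0).
#' @param seed RNG seed.
#' @return the matrix with missing cells added.
#' @export
apply_dropout <- function(mat, midpoint, slope, seed = 1L) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (im_scale(mat) != "log2")
    stop_config("apply_dropout expects a log2-scale matrix")
  if (slope <= 0) stop_config("slope must be > 0")
  v <- im_values(mat)
  set.seed(derive_seed(seed, "dropout"))
  p_miss <- stats::plogis((midpoint - v) / slope)
  drop <- !is.na(v) & stats::runif(length(v)) < p_miss
  for (j in seq_len(ncol(v))) {
    present <- which(!is.na(v[, j]))
    if (length(present) && all(drop[present, j])) {
      keep <- present[which.max(v[present, j])]
      drop[keep, j] <- FALSE
    }
  }
  v[drop] <- NA_real_
  intensity_matrix(v, scale = "log2", imputed = im_imputed(mat) & !drop)
}
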