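# Pipeline orchestration: configuration, stage ordering, provenance-stamped
# outputs. Three analysis presets cover the study designs this package
# targets: `aav` (labeled vs control enrichment only), `regional` (bait
# normalization + core signatures + profiles), `celltype` (two labeled
# drivers contrasted). The R functions themselves are the command surface;
# `run_pipeline()` ties them together for scripted use.

#' Build a pipeline configuration
#'
#' All analysis constants live here: the 2-fold enrichment and 4-fold core
#' signature thresholds, the unadjusted p cut-off 0.05, the Z cut-off 1.96,
#' five K-means clusters, and the Perseus-default imputation parameters
#' (width 0.3, down-shift 1.8).
#'
#' @param seed master seed; every stochastic stage derives its stream from
#'   it via [derive_seed()].
#' @param out_dir output directory for tables (created if absent).
#' @param synthetic if `TRUE`, data come from [generate_ms_dataset()] using
#'   `synth`; otherwise `matrix_path`/`design_path` are read.
#' @param synth named list of overrides for [synth_ms_config()].
#' @param apply_dropout whether to apply MNAR dropout to synthetic data
#'   before filtering/imputation.
#' @param matrix_path,design_path input files for real data.
#' @param gmt_path,background_path optional gene sets and background list
#'   for the over-representation stage.
#' @param filter list with `mode`, `k`, `group_col` for
#'   [filter_min_valid()].
#' @param impute list with `width`, `shift` for [impute_downshift()].
#' @param fc_enrich,fc_core,p_threshold,z_threshold,k_clusters analysis
#'   thresholds.
#' @param region_groups optional named list merging regions for the
#'   signature stage.
#' @param preset `"regional"` (default), `"aav"` (skip bait normalization
#'   and regional stages), or `"celltype"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("cibop_run_"),
                            synthetic = TRUE, synth = list(),
                            apply_dropout = TRUE,
                            matrix_path = NULL, design_path = NULL,
                            gmt_path = NULL, background_path = NULL,
                            filter = list(mode = "min-valid-per-group",
                                          k = 3L, group_col = "genotype",
                                          groups = "labeled"),
                            impute = list(width = 0.3, shift = 1.8),
                            fc_enrich = 2, fc_core = 4, p_threshold = 0.05,
                            z_threshold = 1.96, k_clusters = 5L,
                            region_groups = NULL,
                            preset = c("regional", "aav", "celltype")) {
  preset <- match.arg(preset)
  if (any(c(fc_enrich, fc_core) <= 1) || p_threshold <= 0 ||
      z_threshold <= 0 || k_clusters < 1)
    stop_config("thresholds must be positive (fold changes > 1)")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synthetic = synthetic, synth = synth,
                 apply_dropout = apply_dropout,
                 matrix_path = matrix_path, design_path = design_path,
                 gmt_path = gmt_path, background_path = background_path,
                 filter = filter, impute = impute, fc_enrich = fc_enrich,
                 fc_core = fc_core, p_threshold = p_threshold,
                 z_threshold = z_threshold,
                 k_clusters = as.integer(k_clusters),
                 region_groups = region_groups, preset = preset),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

# Hash of the analysis-relevant configuration. The output directory is
# provenance, not analysis configuration, so two runs of the same analysis
# into different directories share a hash (and must produce identical
# tables).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_tsv <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stage order: (synthesize or read) -> flag filtering -> log2 transform ->
#' [dropout, synthetic only] -> valid-value filtering -> down-shifted
#' imputation -> bait normalization -> labeled-vs-control enrichment ->
#' core regional signatures -> K-means profiles -> PCA ->
#' over-representation (if gene sets supplied) -> recovery scoring
#' (synthetic only). Every output table carries a provenance header with
#' the seed and a hash of the configuration; re-running with an identical
#' configuration reproduces byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the key result objects and the paths of
#'   all written tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  header <- c("# cibop pipeline output",
              paste0("# seed: ", config$seed),
              paste0("# config_hash: ", hash),
              paste0("# preset: ", config$preset))
  paths <- list()
  results <- list(config = config, config_hash = hash)

  ## ---- input stage ----
  if (config$synthetic) {
    scfg <- do.call(synth_ms_config,
                    utils::modifyList(list(seed = config$seed),
                                      config$synth))
    ds <- generate_ms_dataset(scfg)
    mat <- ds$matrix
    design <- ds$design
    meta <- ds$meta
    results$truth <- ds$truth
  } else {
    if (is.null(config$matrix_path) || is.null(config$design_path))
      stop_config("non-synthetic run requires matrix_path and design_path")
    if (!file.exists(config$matrix_path))
      stop_config("matrix file not found: ", config$matrix_path)
    pg <- read_protein_groups(config$matrix_path)
    mat <- pg$matrix
    meta <- pg$meta
    design <- read_sample_design(config$design_path)
  }
  design <- check_design(mat, design)

  ff <- filter_flagged(mat, meta)
  mat <- ff$matrix
  meta <- ff$meta
  mat <- log2_transform(mat)
  if (config$synthetic && config$apply_dropout) {
    scfg <- results$truth$config
    mat <- apply_dropout(mat, scfg$dropout_midpoint, scfg$dropout_slope,
                         seed = derive_seed(config$seed, "pipeline-dropout"))
  }

  ## ---- preprocess stage ----
  mat <- filter_min_valid(mat, design,
                          mode = config$filter$mode %||% "min-valid-total",
                          k = config$filter$k %||% 3L,
                          group_col = config$filter$group_col %||%
                            "genotype",
                          groups = config$filter$groups)
  mat <- suppressMessages(impute_downshift(
    mat, width = config$impute$width %||% 0.3,
    shift = config$impute$shift %||% 1.8,
    seed = derive_seed(config$seed, "pipeline-impute")))

  labeled <- select_samples(design, genotype = "labeled")
  control <- select_samples(design, genotype = "control")
  bait_present <- any(meta$is_bait &
                        meta$protein_group_id %in%
                          rownames(im_values(mat)))
  if (config$preset != "aav" && bait_present) {
    mat <- suppressWarnings(normalize_to_bait(mat, meta, samples = labeled))
  }
  results$matrix <- mat
  results$design <- design
  results$meta <- meta

  ## ---- enrichment stage ----
  enr <- two_group_test(mat, group_a = labeled, group_b = control)
  enr <- classify_enrichment(enr, fc_threshold = config$fc_enrich,
                             p_threshold = config$p_threshold)
  results$enrichment <- enr
  paths$enrichment <- file.path(config$out_dir, "enrichment.tsv")
  write_stamped_tsv(enr[order(enr$p_value, enr$protein_group_id), ],
                    paths$enrichment, header)

  ## ---- regional stage ----
  if (config$preset != "aav" && length(unique(design$region)) >= 2L) {
    lab_mat <- mat[, labeled]
    lab_design <- design[design$sample_id %in% labeled, , drop = FALSE]
    sig <- core_signatures(lab_mat, lab_design,
                           region_groups = config$region_groups,
                           fc_core = config$fc_core,
                           p_threshold = config$p_threshold)
    results$signatures <- sig
    paths$signatures <- file.path(config$out_dir, "signatures.tsv")
    asn <- sig$assignment
    write_stamped_tsv(asn[order(asn$region, asn$protein_group_id), ],
                      paths$signatures, header)

    km_input <- lab_mat
    km <- suppressWarnings(kmeans_profiles(
      km_input, k = min(config$k_clusters, nrow(im_values(km_input))),
      seed = derive_seed(config$seed, "pipeline-kmeans")))
    results$kmeans <- km
    paths$kmeans <- file.path(config$out_dir, "kmeans_clusters.tsv")
    write_stamped_tsv(data.frame(protein_group_id = names(km$assignment),
                                 cluster = unname(km$assignment)),
                      paths$kmeans, header)

    pca <- run_pca(lab_mat)
    results$pca <- pca
    paths$pca <- file.path(config$out_dir, "pca_variance.tsv")
    write_stamped_tsv(data.frame(
      component = seq_along(pca$variance_fractions_all),
      variance_fraction = pca$variance_fractions_all), paths$pca, header)
  }

  ## ---- over-representation stage ----
  if (!is.null(config$gmt_path)) {
    if (!file.exists(config$gmt_path))
      stop_config("GMT file not found: ", config$gmt_path)
    if (is.null(config$background_path) ||
        !file.exists(config$background_path %||% ""))
      stop_config("background list not found: ", config$background_path)
    terms <- read_gmt(config$gmt_path)
    bg <- read_background(config$background_path)
    hit_ids <- enr$protein_group_id[enr$class == "enriched_a"]
    hits <- meta$gene_symbol[match(hit_ids, meta$protein_group_id)]
    ora <- suppressWarnings(run_ora(hits, bg, terms,
                                    z_threshold = config$z_threshold))
    results$ora <- ora
    paths$ora <- file.path(config$out_dir, "ora.tsv")
    write_stamped_tsv(ora, paths$ora, header)
  }

  ## ---- recovery stage (synthetic) ----
  if (config$synthetic) {
    rec <- score_recovery(results$truth, enr,
                          universe = rownames(im_values(mat)))
    results$recovery <- rec
    rows <- data.frame(metric = c("sensitivity", "specificity", "fdr"),
                       value = c(rec$sensitivity, rec$specificity,
                                 rec$fdr))
    if (!is.null(results$signatures)) {
      rr <- score_recovery(results$truth, results$signatures)
      results$recovery_regional <- rr
      rows <- rbind(rows, data.frame(
        metric = "regional_correct_fraction", value = rr$sensitivity))
    }
    paths$recovery <- file.path(config$out_dir, "recovery.tsv")
    write_stamped_tsv(rows, paths$recovery, header)
  }

  results$paths <- paths
  invisible(results)
}
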