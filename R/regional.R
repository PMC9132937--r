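# Regional analysis: one-vs-rest core regional signatures, K-means profile
# clustering, enriched-vs-background overlap, PCA, hierarchical clustering
# (average linkage on 1 - Pearson), annotation-list intersection, and the
# joint MS + immunoassay integration matrix.

#' Core regional protein signatures (one-vs-rest)
#'
#' For each region group, runs a two-group test of that region's samples
#' against the pooled samples of all other regions and keeps proteins at
#' least `fc_core`-fold higher in the region (log2 difference of group means
#' `>= log2(fc_core)`) with `p <= p_threshold`. A protein qualifying in more
#' than one region (possible in noisy data) is assigned to the region of
#' maximal log2 fold change and flagged `multi_region`.
#'
#' @param mat fully observed, bait-normalized log2 [intensity_matrix()]
#'   restricted to the labeled samples under study.
#' @param design matching [sample_design()].
#' @param region_groups optional named list merging regions into groups, e.g.
#'   `list(CTX_HIP = c("CTX","HIP"), ST = "ST", PM = "PM", CB = "CB")`.
#'   Defaults to one group per distinct region in the design.
#' @param fc_core linear fold-change threshold (default 4).
#' @param p_threshold unadjusted p threshold (default 0.05).
#' @param variant t-test variant, see [two_group_test()].
#' @return a list of class `regional_signature_set`: `signatures` (named
#'   list of per-region data.frames with `protein_group_id`, `log2_fc`,
#'   `p_value`, `multi_region`), `assignment` (data.frame of all assigned
#'   proteins), and the thresholds used.
#' @export
core_signatures <- function(mat, design, region_groups = NULL, fc_core = 4,
                            p_threshold = 0.05, variant = "student") {
  stopifnot(inherits(mat, "intensity_matrix"))
  design <- check_design(mat, design)
  if (is.null(region_groups)) {
    regs <- unique(design$region)
    region_groups <- stats::setNames(as.list(regs), regs)
  }
  if (length(region_groups) < 2L)
    stop_config("need at least 2 region groups")
  all_ids <- colnames(im_values(mat))
  lfc_min <- log2(fc_core)

  tests <- lapply(region_groups, function(regions) {
    in_ids <- design$sample_id[design$region %in% regions]
    out_ids <- setdiff(all_ids, in_ids)
    if (length(in_ids) < 2L)
      stop_config("region group {", paste(regions, collapse = ","),
                  "} has fewer than 2 samples")
    two_group_test(mat, group_a = in_ids, group_b = out_ids,
                   variant = variant)
  })

  qual <- lapply(tests, function(tt)
    tt$log2_fc >= lfc_min & tt$p_value <= p_threshold)
  qual_mat <- do.call(cbind, qual)          # proteins x region groups
  lfc_mat <- do.call(cbind, lapply(tests, `[[`, "log2_fc"))
  p_mat <- do.call(cbind, lapply(tests, `[[`, "p_value"))
  rownames(qual_mat) <- rownames(lfc_mat) <- rownames(p_mat) <-
    tests[[1]]$protein_group_id

  n_qual <- rowSums(qual_mat)
  assigned <- which(n_qual > 0L)
  # tie rule: max log2 fold change among qualifying regions
  pick <- vapply(assigned, function(i) {
    cand <- which(qual_mat[i, ])
    cand[which.max(lfc_mat[i, cand])]
  }, integer(1))
  assignment <- data.frame(
    protein_group_id = rownames(qual_mat)[assigned],
    region = names(region_groups)[pick],
    log2_fc = lfc_mat[cbind(assigned, pick)],
    p_value = p_mat[cbind(assigned, pick)],
    multi_region = n_qual[assigned] > 1L,
    row.names = NULL, stringsAsFactors = FALSE)

  signatures <- lapply(names(region_groups), function(rg)
    assignment[assignment$region == rg, , drop = FALSE])
  names(signatures) <- names(region_groups)
  structure(list(signatures = signatures, assignment = assignment,
                 region_groups = region_groups, fc_core = fc_core,
                 p_threshold = p_threshold),
            class = "regional_signature_set")
}

#' @export
print.regional_signature_set <- function(x, ...) {
  cat(sprintf("regional_signature_set (fc >= %g, p <= %g):\n", x$fc_core,
              x$p_threshold))
  for (rg in names(x$signatures))
    cat(sprintf("  %s: %d proteins\n", rg, nrow(x$signatures[[rg]])))
  invisible(x)
}

#' K-means clustering of regional protein profiles
#'
#' Rows (proteins) are standardized to mean 0, sd 1 across samples before
#' clustering, so clusters capture profile shape, not abundance. Constant
#' rows (zero variance) cannot be standardized and are reported in
#' `dropped`. If fewer distinct profiles than `k` exist, `k` is reduced with
#' a warning and the effective `k` reported.
#'
#' @param mat a fully observed log2 [intensity_matrix()] (or plain matrix).
#' @param k number of clusters (default 5).
#' @param seed RNG seed making restarts deterministic.
#' @param n_restarts random restarts; the best within-cluster sum of squares
#'   wins.
#' @return list with `assignment` (named integer vector), `centers`,
#'   `k_effective`, `dropped`, `tot_withinss`.
#' @export
kmeans_profiles <- function(mat, k = 5L, seed = 1L, n_restarts = 25L) {
  v <- if (inherits(mat, "intensity_matrix")) im_values(mat) else mat
  if (anyNA(v)) stop_config("matrix must be fully observed")
  if (k > nrow(v)) stop_config("k exceeds number of proteins")
  sds <- apply(v, 1L, stats::sd)
  dropped <- rownames(v)[sds == 0]
  if (length(dropped))
    warning(sprintf("%d constant row(s) dropped before clustering",
                    length(dropped)))
  z <- (v[sds > 0, , drop = FALSE] - rowMeans(v[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  k_eff <- min(k, nrow(unique(z)))
  if (k_eff < k)
    warning(sprintf("only %d distinct profiles; k reduced from %d", k_eff,
                    k))
  set.seed(derive_seed(seed, "kmeans"))
  fit <- stats::kmeans(z, centers = k_eff, nstart = n_restarts,
                       iter.max = 100L)
  list(assignment = stats::setNames(fit$cluster, rownames(z)),
       centers = fit$centers, k_effective = k_eff, dropped = dropped,
       tot_withinss = fit$tot.withinss)
}

#' Overlap of enriched-proteome signatures with background-proteome
#' signatures
#'
#' For each region group, counts core-signature proteins of the
#' cell-type-enriched proteome that are also core markers of the same region
#' in the bulk (background) proteome, and the percentage
#' `100 * n_intersection / n_enriched_core`. Symbols (or identifiers) are
#' case-folded before matching.
#'
#' @param enriched_sig,background_sig `regional_signature_set`s computed
#'   with the same region grouping.
#' @return data.frame with one row per region: `region`, `n_enriched_core`,
#'   `n_background_core`, `n_intersection`, `percent_overlap`, plus a list
#'   column `exclusive_to_enriched`.
#' @export
overlap_with_background <- function(enriched_sig, background_sig) {
  stopifnot(inherits(enriched_sig, "regional_signature_set"),
            inherits(background_sig, "regional_signature_set"))
  if (!setequal(names(enriched_sig$signatures),
                names(background_sig$signatures)))
    stop_config("region sets differ between the two signature sets")
  regions <- names(enriched_sig$signatures)
  rows <- lapply(regions, function(rg) {
    e <- unique(fold_symbols(
      enriched_sig$signatures[[rg]]$protein_group_id))
    b <- unique(fold_symbols(
      background_sig$signatures[[rg]]$protein_group_id))
    inter <- intersect(e, b)
    data.frame(region = rg, n_enriched_core = length(e),
               n_background_core = length(b),
               n_intersection = length(inter),
               percent_overlap = if (length(e))
                 100 * length(inter) / length(e) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$exclusive_to_enriched <- lapply(regions, function(rg) {
    e <- unique(fold_symbols(
      enriched_sig$signatures[[rg]]$protein_group_id))
    b <- unique(fold_symbols(
      background_sig$signatures[[rg]]$protein_group_id))
    setdiff(e, b)
  })
  out
}

#' Principal component analysis of samples
#'
#' Samples (columns) are the observations; proteins are centered (not
#' scaled). The sign of each component is fixed so the loading of largest
#' magnitude is positive, making results reproducible across platforms.
#'
#' @param mat a fully observed log2 [intensity_matrix()] (or plain matrix).
#' @param n_components number of components to return (default all).
#' @return list with `scores` (samples x components), `loadings`
#'   (proteins x components), `variance_fractions`.
#' @export
run_pca <- function(mat, n_components = NULL) {
  v <- if (inherits(mat, "intensity_matrix")) im_values(mat) else mat
  if (anyNA(v)) stop_config("matrix must be fully observed")
  if (ncol(v) < 2L) stop_config("need at least 2 samples")
  fit <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  fr <- fit$sdev^2 / sum(fit$sdev^2)
  nc <- n_components %||% length(fr)
  nc <- min(nc, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(nc), drop = FALSE]
  sco <- fit$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco, loadings = rot, variance_fractions = fr[seq_len(nc)],
       variance_fractions_all = fr)
}

#' Hierarchical clustering with average linkage on 1 - Pearson correlation
#'
#' Distance between two items (rows or columns) is one minus their Pearson
#' correlation, giving distances in `[0, 2]`; trees are built by UPGMA
#' (average linkage), whose merge heights are non-decreasing.
#'
#' @param mat a fully observed matrix or [intensity_matrix()].
#' @param axis cluster `"columns"` (samples; default) or `"rows"`
#'   (proteins).
#' @param linkage linkage method passed to [stats::hclust()]; default
#'   `"average"`.
#' @return list with `tree` (an `hclust`), `order` (leaf labels in dendrogram
#'   order), `dist` (the distance object).
#' @export
hca <- function(mat, axis = c("columns", "rows"), linkage = "average") {
  axis <- match.arg(axis)
  v <- if (inherits(mat, "intensity_matrix")) im_values(mat) else mat
  if (anyNA(v)) stop_config("matrix must be fully observed")
  m <- if (axis == "rows") t(v) else v   # items end up in columns
  if (ncol(m) < 2L) stop_config("need at least 2 items to cluster")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop_config("constant item(s), correlation undefined: ",
                paste(colnames(m)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(m))
  tree <- stats::hclust(d, method = linkage)
  list(tree = tree, order = tree$labels[tree$order], dist = d)
}

#' Intersect proteins with an annotation list
#'
#' Generic list-intersection used e.g. against curated druggable-target
#' symbol lists; matching is case-folded. When `proteins` is a data.frame
#' (e.g. a signature assignment or classified enrichment table), grouping
#' columns such as `region` or `class` are carried through for a per-group
#' breakdown.
#'
#' @param proteins character vector of symbols, or a data.frame with a
#'   symbol column.
#' @param reference_list character vector of annotation symbols (non-empty).
#' @param list_name label recorded in the output.
#' @param symbol_col symbol column name when `proteins` is a data.frame.
#' @return data.frame of intersecting rows with a `list_name` column.
#' @export
annotate_with_list <- function(proteins, reference_list, list_name = "list",
                               symbol_col = "protein_group_id") {
  if (!length(reference_list)) stop_config("empty reference list")
  ref <- unique(fold_symbols(reference_list))
  if (is.data.frame(proteins)) {
    hit <- fold_symbols(proteins[[symbol_col]]) %in% ref
    out <- proteins[hit, , drop = FALSE]
  } else {
    syms <- unique(fold_symbols(proteins))
    out <- data.frame(symbol = intersect(syms, ref),
                      stringsAsFactors = FALSE)
  }
  if (nrow(out)) out$list_name <- list_name else out$list_name <- character()
  rownames(out) <- NULL
  out
}

#' Joint MS + immunoassay signature matrix for integrated embedding
#'
#' Stacks per-region mean profiles of core signature proteins with
#' normalized immunoassay analyte profiles into one feature x region matrix,
#' z-scoring every feature across regions so proteins and analytes are
#' comparable. Features constant across regions are dropped with a warning.
#' An optional 2-D embedding function (e.g. a t-SNE or PCA adapter) may be
#' supplied; only the shape of its output is part of the contract.
#'
#' @param ms_profiles numeric matrix, proteins x regions.
#' @param assay_profiles numeric matrix, analytes x regions, same region
#'   labels.
#' @param embedder optional `function(x, seed)` mapping an items x features
#'   matrix to an items x 2 coordinate matrix.
#' @param seed seed forwarded to the embedder.
#' @return list with `matrix` (z-scored features x regions), `dropped`, and
#'   `embedding` (`NULL` unless an embedder was supplied).
#' @export
joint_signature_matrix <- function(ms_profiles, assay_profiles,
                                   embedder = NULL, seed = 1L) {
  if (is.null(colnames(ms_profiles)) || is.null(colnames(assay_profiles)))
    stop_config("both inputs need region column labels")
  if (!setequal(colnames(ms_profiles), colnames(assay_profiles)))
    stop_config("region labels differ between MS and assay profiles")
  if (ncol(ms_profiles) < 2L)
    stop_config("need at least 2 regions to z-score")
  ap <- assay_profiles[, colnames(ms_profiles), drop = FALSE]
  stacked <- rbind(ms_profiles, ap)
  sds <- apply(stacked, 1L, stats::sd)
  dropped <- rownames(stacked)[sds == 0]
  if (length(dropped))
    warning(sprintf("%d feature(s) constant across regions dropped",
                    length(dropped)))
  z <- (stacked[sds > 0, , drop = FALSE] -
          rowMeans(stacked[sds > 0, , drop = FALSE])) / sds[sds > 0]
  emb <- if (!is.null(embedder)) embedder(z, seed) else NULL
  list(matrix = z, dropped = dropped, embedding = emb)
}
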