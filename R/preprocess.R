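# Perseus-equivalent preprocessing: valid-value filtering, down-shifted
# normal imputation of left-censored missing values, and per-sample bait
# (TurboID) normalization.

#' Filter protein rows by minimum number of valid values
#'
#' Removes rows with too few quantified (non-missing) values, either in total
#' across the in-scope samples or within every group of a design column.
#' In per-group mode a row must meet the minimum in EVERY group.
#'
#' @param mat a log2-scale [intensity_matrix()].
#' @param design a [sample_design()] covering the matrix columns (required
#'   for per-group mode).
#' @param mode `"min-valid-total"` or `"min-valid-per-group"`.
#' @param k minimum number of valid values required.
#' @param group_col design column defining the groups in per-group mode
#'   (default `"genotype"`).
#' @param groups optional subset of group levels that must meet `k`
#'   (default: all levels). Filtering on the labeled group only keeps
#'   proteins absent from controls — including the bait, which controls
#'   never contain.
#' @return the filtered `intensity_matrix`; the number of removed rows is
#'   reported via `message()` and attached as attribute `n_removed`.
#' @export
filter_min_valid <- function(mat, design = NULL,
                             mode = c("min-valid-total",
                                      "min-valid-per-group"),
                             k = 3L, group_col = "genotype",
                             groups = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "intensity_matrix"))
  if (im_scale(mat) != "log2")
    stop_config("filter_min_valid expects a log2-scale matrix")
  v <- im_values(mat)
  if (k < 1L) stop_config("k must be >= 1")
  if (mode == "min-valid-total") {
    if (k > ncol(v))
      stop_config("k = ", k, " exceeds number of samples (", ncol(v), ")")
    keep <- rowSums(!is.na(v)) >= k
  } else {
    if (is.null(design)) stop_config("per-group mode requires a design")
    design <- check_design(mat, design)
    grp <- split(design$sample_id, design[[group_col]])
    if (!is.null(groups)) {
      bad <- setdiff(groups, names(grp))
      if (length(bad))
        stop_config("unknown group level(s): ", paste(bad, collapse = ", "))
      grp <- grp[groups]
    }
    sizes <- lengths(grp)
    if (any(k > sizes))
      stop_config("k = ", k, " exceeds size of group(s): ",
                  paste(names(grp)[k > sizes], collapse = ", "))
    per_group <- vapply(grp, function(ids)
      rowSums(!is.na(v[, ids, drop = FALSE])) >= k,
      logical(nrow(v)))
    if (!is.matrix(per_group))
      per_group <- matrix(per_group, nrow = nrow(v))
    keep <- apply(per_group, 1L, all)
  }
  out <- mat[keep, ]
  n_removed <- sum(!keep)
  message(sprintf("filter_min_valid(%s, k=%d): removed %d of %d rows",
                  mode, k, n_removed, nrow(v)))
  attr(out, "n_removed") <- n_removed
  out
}

#' Impute missing values from a down-shifted normal distribution
#'
#' Replaces missing log2 intensities with draws from a normal distribution
#' whose center is shifted below the observed mean, modeling the fact that
#' unquantified proteins in label-free MS tend to be low-abundance
#' (left-censored missingness). For a sample with observed mean `mu` and
#' standard deviation `sigma`, missing cells are drawn independently from
#' `Normal(mu - shift*sigma, (width*sigma)^2)`. Defaults `width = 0.3`,
#' `shift = 1.8` are the Perseus defaults.
#'
#' Moments are computed per sample from observed values only (the Perseus
#' convention); `scope = "whole-matrix"` pools all observed values instead.
#' Each sample draws from its own sub-seed derived via [derive_seed()], so
#' removing or reordering samples leaves the other samples' draws unchanged.
#'
#' @param mat a log2-scale [intensity_matrix()].
#' @param width spread of the imputation distribution, as a multiple of the
#'   observed standard deviation (> 0).
#' @param shift downward shift of its center, as a multiple of the observed
#'   standard deviation (>= 0).
#' @param seed master seed for the imputation draws.
#' @param scope `"per-sample"` (default) or `"whole-matrix"` moments.
#' @return the matrix with no missing cells and the imputed mask set.
#' @export
impute_downshift <- function(mat, width = 0.3, shift = 1.8, seed = 1L,
                             scope = c("per-sample", "whole-matrix")) {
  scope <- match.arg(scope)
  stopifnot(inherits(mat, "intensity_matrix"))
  if (im_scale(mat) != "log2")
    stop_config("impute_downshift expects a log2-scale matrix")
  if (width <= 0) stop_config("width must be > 0")
  if (shift < 0) stop_config("shift must be >= 0")
  v <- im_values(mat)
  imp <- im_imputed(mat)
  if (!anyNA(v)) return(mat)

  if (scope == "whole-matrix") {
    mu_all <- mean(v, na.rm = TRUE)
    sd_all <- stats::sd(as.vector(v), na.rm = TRUE)
    if (sum(!is.na(v)) < 2L)
      stop_config("fewer than 2 observed values in matrix")
  }
  thin <- colSums(!is.na(v)) < 2L
  if (scope == "per-sample" && any(thin))
    stop_config("sample(s) with < 2 observed values (sd undefined): ",
                paste(colnames(v)[thin], collapse = ", "))

  for (j in seq_len(ncol(v))) {
    miss <- which(is.na(v[, j]))
    if (!length(miss)) next
    if (scope == "per-sample") {
      mu <- mean(v[, j], na.rm = TRUE)
      sdev <- stats::sd(v[, j], na.rm = TRUE)
    } else {
      mu <- mu_all
      sdev <- sd_all
    }
    set.seed(derive_seed(seed, paste0("impute/", colnames(v)[j])))
    v[miss, j] <- stats::rnorm(length(miss), mean = mu - shift * sdev,
                               sd = width * sdev)
    imp[miss, j] <- TRUE
  }
  message(sprintf("impute_downshift: filled %d missing cells", sum(imp)))
  intensity_matrix(v, scale = "log2", imputed = imp)
}

#' Normalize protein abundances to the bait (TurboID) level per sample
#'
#' The biotin ligase itself is quantified in every labeled sample; its level
#' tracks per-region differences in ligase expression and labeling
#' efficiency. Normalization subtracts, per sample, the difference between
#' that sample's bait log2 value and a common reference, so the bait row
#' becomes constant across normalized samples and every protein's
#' within-sample differences are preserved exactly (on the linear scale this
#' is division by the bait intensity ratio).
#'
#' Samples where the bait was not quantified (typically control genotypes
#' that do not express the ligase) are exempted and left untouched, with a
#' warning naming them; comparisons mixing normalized and exempt samples
#' should be interpreted accordingly.
#'
#' @param mat a log2-scale [intensity_matrix()] (post-imputation for the
#'   in-scope samples).
#' @param meta protein metadata with an `is_bait` column; exactly one bait
#'   row must be present in the matrix.
#' @param reference `"grand-mean"` (default: mean bait level over the
#'   normalized samples) or `"fixed-value"` with `value` supplied.
#' @param value reference log2 bait level when `reference = "fixed-value"`.
#' @param samples optional character vector restricting which samples are
#'   normalized (default: all samples with a quantified bait value).
#' @return the normalized matrix, with attribute `bait_exempt` listing
#'   samples left unnormalized.
#' @export
normalize_to_bait <- function(mat, meta,
                              reference = c("grand-mean", "fixed-value"),
                              value = NULL, samples = NULL) {
  reference <- match.arg(reference)
  stopifnot(inherits(mat, "intensity_matrix"))
  if (im_scale(mat) != "log2")
    stop_config("normalize_to_bait expects a log2-scale matrix")
  v <- im_values(mat)
  bait_ids <- meta$protein_group_id[meta$is_bait]
  bait_ids <- intersect(bait_ids, rownames(v))
  if (length(bait_ids) != 1L)
    stop_config("matrix must contain exactly one bait row; found ",
                length(bait_ids))
  b <- v[bait_ids, ]

  scope <- samples %||% colnames(v)[!is.na(b)]
  bad <- setdiff(scope, colnames(v))
  if (length(bad))
    stop_config("unknown sample(s): ", paste(bad, collapse = ", "))
  miss_b <- scope[is.na(b[scope])]
  if (length(miss_b))
    stop_config("bait not quantified in sample(s) to normalize: ",
                paste(miss_b, collapse = ", "))
  exempt <- setdiff(colnames(v), scope)
  if (length(exempt))
    warning("samples without bait left unnormalized: ",
            paste(exempt, collapse = ", "))

  r <- if (reference == "grand-mean") mean(b[scope]) else {
    if (is.null(value)) stop_config("fixed-value reference requires `value`")
    value
  }
  v[, scope] <- sweep(v[, scope, drop = FALSE], 2L, b[scope] - r, `-`)
  out <- intensity_matrix(v, scale = "log2", imputed = im_imputed(mat))
  attr(out, "bait_exempt") <- exempt
  attr(out, "bait_reference") <- r
  out
}
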