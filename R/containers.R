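# Core data containers: intensity matrices, sample designs, protein metadata.
# Plain matrices and data frames with light S3 wrappers, in the style of
# limma's EList: values are a numeric matrix (proteins x samples) with NA for
# missing, plus a scale tag and an imputation mask.

#' Construct an intensity matrix
#'
#' Holds protein-group quantifications as a proteins x samples numeric matrix.
#' Missing values are `NA`; the missingness mask is therefore implicit. A
#' `scale` tag records whether values are raw (linear) intensities or log2
#' transformed, and an `imputed` logical matrix marks cells that were filled
#' by [impute_downshift()].
#'
#' @param values numeric matrix with unique row names (protein group ids) and
#'   unique column names (sample ids). `NA` encodes missing.
#' @param scale `"linear"` or `"log2"`.
#' @param imputed optional logical matrix of the same dimensions; `TRUE` cells
#'   must hold a (non-missing) value.
#' @return an object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, scale = c("linear", "log2"),
                             imputed = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_format("`values` must have row and column names")
  if (anyDuplicated(rownames(values)))
    stop_format("duplicate protein identifiers: ",
                paste(unique(rownames(values)[duplicated(rownames(values))]),
                      collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_format("duplicate sample identifiers")
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  stopifnot(identical(dim(imputed), dim(values)))
  if (any(imputed & is.na(values)))
    stop_format("imputed mask marks cells that are still missing")
  structure(list(values = values, scale = scale, imputed = imputed),
            class = "intensity_matrix")
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
dimnames.intensity_matrix <- function(x) dimnames(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  missing: %d cells, imputed: %d cells\n",
              sum(is.na(x$values)), sum(x$imputed)))
  invisible(x)
}

#' Extract the value matrix of an intensity matrix
#' @param x an `intensity_matrix`.
#' @return numeric matrix with `NA` for missing cells.
#' @export
im_values <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  x$values
}

#' @rdname im_values
#' @export
im_scale <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  x$scale
}

#' @rdname im_values
#' @export
im_imputed <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  x$imputed
}

#' @rdname im_values
#' @export
im_missing <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  is.na(x$values)
}

# Subset rows/columns keeping masks congruent.
#' @export
`[.intensity_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  intensity_matrix(x$values[i, j, drop = FALSE], scale = x$scale,
                   imputed = x$imputed[i, j, drop = FALSE])
}

#' Construct and validate a sample design table
#'
#' One row per sample column of the intensity matrix. `genotype` separates
#' biotin-ligase-expressing ("labeled") animals from controls; `driver` is
#' the Cre driver (cell type); `region` the dissected brain region.
#'
#' @param sample_id unique sample identifiers matching matrix columns.
#' @param genotype `"labeled"` or `"control"` per sample.
#' @param region brain region label per sample (e.g. CTX, HIP, ST, PM, CB).
#' @param mouse_id animal identifier (technical replicates share it).
#' @param tech_rep technical replicate index within mouse/region.
#' @param driver optional Cre driver label (hSyn, Camk2a, Aldh1l1, none).
#' @return a `data.frame` of class `sample_design`.
#' @export
sample_design <- function(sample_id, genotype, region, mouse_id,
                          tech_rep = 1L, driver = "none") {
  d <- data.frame(sample_id = as.character(sample_id),
                  genotype = as.character(genotype),
                  driver = as.character(driver),
                  region = as.character(region),
                  mouse_id = as.character(mouse_id),
                  tech_rep = as.integer(tech_rep),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id))
    stop_format("duplicate sample_id in design")
  bad <- setdiff(unique(d$genotype), c("labeled", "control"))
  if (length(bad))
    stop_format("genotype must be 'labeled' or 'control', got: ",
                paste(bad, collapse = ", "))
  class(d) <- c("sample_design", "data.frame")
  d
}

# Every matrix column must have exactly one design row; silent subsetting is
# never performed.
check_design <- function(mat, design) {
  cols <- colnames(im_values(mat))
  missing_rows <- setdiff(cols, design$sample_id)
  if (length(missing_rows))
    stop_format("samples missing from design: ",
                paste(missing_rows, collapse = ", "))
  design[match(cols, design$sample_id), , drop = FALSE]
}

#' Select sample ids from a design by field values
#'
#' Convenience selector used by the enrichment and regional stages, e.g.
#' `select_samples(design, genotype = "labeled", region = "CB")`.
#'
#' @param design a [sample_design()] table.
#' @param ... named filters; each name must be a design column and each value
#'   a vector of admissible levels.
#' @return character vector of matching sample ids.
#' @export
select_samples <- function(design, ...) {
  filters <- list(...)
  keep <- rep(TRUE, nrow(design))
  for (nm in names(filters)) {
    if (!nm %in% names(design))
      stop_config("no design column named '", nm, "'")
    keep <- keep & design[[nm]] %in% filters[[nm]]
  }
  design$sample_id[keep]
}
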