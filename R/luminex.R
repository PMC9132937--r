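# Multiplex bead immunoassay (Luminex) processing. Two assay modes exist:
# the standard sandwich assay reads total analyte via a biotinylated
# detection antibody, while the adapted assay omits that antibody so the
# streptavidin fluorophore reports only analytes biotinylated in vivo, i.e.
# the cell-type-derived pool.

#' Construct a Luminex plate
#'
#' @param fluorescence numeric matrix, analytes in rows, samples in columns;
#'   median fluorescence intensities, non-negative.
#' @param mode `"standard"` or `"adapted"`.
#' @param panel optional panel label (e.g. `"cytokine-32"`, `"MAPK"`,
#'   `"Akt-mTOR"`).
#' @return an object of class `luminex_plate`.
#' @export
luminex_plate <- function(fluorescence, mode = c("standard", "adapted"),
                          panel = NA_character_) {
  mode <- match.arg(mode)
  if (!is.matrix(fluorescence) || !is.numeric(fluorescence))
    stop_format("fluorescence must be a numeric matrix")
  if (is.null(rownames(fluorescence)))
    stop_format("fluorescence needs analyte row names")
  if (any(fluorescence < 0, na.rm = TRUE))
    stop_format("negative fluorescence values")
  structure(list(fluorescence = fluorescence, mode = mode, panel = panel),
            class = "luminex_plate")
}

#' @export
print.luminex_plate <- function(x, ...) {
  cat(sprintf("luminex_plate [%s]: %d analytes x %d samples\n", x$mode,
              nrow(x$fluorescence), ncol(x$fluorescence)))
  invisible(x)
}

lp_values <- function(x) {
  stopifnot(inherits(x, "luminex_plate"))
  x$fluorescence
}

#' Subtract assay background per analyte
#'
#' Subtracts the blank (background) fluorescence per analyte and clips
#' negative results to zero (fluorescence cannot be negative); the number of
#' clipped cells is reported and attached as attribute `n_clipped`.
#'
#' @param plate a [luminex_plate()].
#' @param blank named numeric vector of blank levels per analyte, or a
#'   single value applied to all analytes.
#' @return the background-subtracted plate.
#' @export
subtract_background <- function(plate, blank) {
  v <- lp_values(plate)
  if (length(blank) == 1L && is.null(names(blank)))
    blank <- stats::setNames(rep(blank, nrow(v)), rownames(v))
  miss <- setdiff(rownames(v), names(blank))
  if (length(miss))
    stop_config("no blank level for analyte(s): ",
                paste(miss, collapse = ", "))
  out <- v - blank[rownames(v)]
  n_clipped <- sum(out < 0)
  if (n_clipped)
    message(sprintf("subtract_background: clipped %d negative cell(s) to 0",
                    n_clipped))
  out[out < 0] <- 0
  res <- luminex_plate(out, mode = plate$mode, panel = plate$panel)
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Cell-type-derived fraction of each analyte
#'
#' Ratio of the adapted (streptavidin-only readout, biotinylated pool) to
#' the standard (total) assay signal per analyte, background-subtracted
#' inputs assumed. A fraction of at least 0.5 calls the analyte
#' predominantly cell-type-derived; below 0.5 its predominant origin is
#' other cell types. Samples with zero standard signal give an undefined
#' fraction and are excluded from the per-analyte summary (counted in
#' `n_undefined`).
#'
#' @param standard_plate,adapted_plate background-subtracted
#'   [luminex_plate()]s with identical analytes and samples.
#' @return data.frame per analyte: mean `fraction`, `predominant_origin`
#'   (`"cell-type"` / `"non-cell-type"`), `n_samples`, `n_undefined`; the
#'   full per-sample fraction matrix is attached as attribute `fractions`.
#' @export
neuron_derived_fraction <- function(standard_plate, adapted_plate) {
  s <- lp_values(standard_plate)
  a <- lp_values(adapted_plate)
  if (!identical(rownames(s), rownames(a)))
    stop_config("analyte sets differ between plates")
  if (!identical(colnames(s), colnames(a)))
    stop_config("sample sets differ between plates")
  frac <- a / s
  frac[s <= 0] <- NA_real_
  mean_frac <- rowMeans(frac, na.rm = TRUE)
  mean_frac[rowSums(!is.na(frac)) == 0] <- NA_real_
  out <- data.frame(
    analyte = rownames(s),
    fraction = unname(mean_frac),
    predominant_origin = ifelse(is.na(mean_frac), NA_character_,
                                ifelse(mean_frac >= 0.5, "cell-type",
                                       "non-cell-type")),
    n_samples = ncol(s),
    n_undefined = unname(rowSums(is.na(frac))),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fractions") <- frac
  out
}

#' Control-subtract and bait-normalize adapted assay signal
#'
#' The adapted assay read on control (non-expressing) animals measures
#' endogenous-biotin background; it is subtracted from the labeled-animal
#' adapted signal per analyte and region, negatives clipped to zero. The
#' difference is then divided by the relative bait (ligase) abundance of the
#' region, taken from the MS pipeline on the linear intensity scale, to
#' correct for per-region differences in ligase expression. The result is
#' the regional cell-type-derived analyte level used for clustering and
#' heatmaps.
#'
#' @param adapted_labeled,adapted_control numeric matrices (or
#'   [luminex_plate()]s), analytes x regions, background handling already
#'   applied; regions must match.
#' @param bait_rel_abundance named numeric vector of relative bait abundance
#'   per region (linear scale, > 0).
#' @return numeric matrix of normalized values (analytes x regions) with
#'   attribute `n_clipped`.
#' @export
normalize_adapted <- function(adapted_labeled, adapted_control,
                              bait_rel_abundance) {
  L <- if (inherits(adapted_labeled, "luminex_plate"))
    lp_values(adapted_labeled) else adapted_labeled
  C <- if (inherits(adapted_control, "luminex_plate"))
    lp_values(adapted_control) else adapted_control
  if (!identical(dim(L), dim(C)) || !identical(rownames(L), rownames(C)) ||
      !identical(colnames(L), colnames(C)))
    stop_config("labeled and control matrices must match in analytes and ",
                "regions")
  regions <- colnames(L)
  if (is.null(regions)) stop_config("matrices need region column names")
  miss <- setdiff(regions, names(bait_rel_abundance))
  if (length(miss))
    stop_config("no bait abundance for region(s): ",
                paste(miss, collapse = ", "))
  if (any(bait_rel_abundance[regions] <= 0))
    stop_config("bait abundance must be > 0")
  d <- L - C
  n_clipped <- sum(d < 0)
  if (n_clipped)
    message(sprintf("normalize_adapted: clipped %d negative cell(s) to 0",
                    n_clipped))
  d[d < 0] <- 0
  out <- sweep(d, 2L, bait_rel_abundance[regions], `/`)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Avidin-blocking control check
#'
#' In the blocking control, biotinylated epitopes are saturated with
#' monomeric avidin before the streptavidin readout, which should abolish
#' the adapted signal. This check computes the per-analyte residual fraction
#' (blocked / unblocked signal) and passes the dataset when the median
#' residual is at most `tolerance`.
#'
#' @param adapted_blocked,adapted_unblocked paired [luminex_plate()]s or
#'   matrices with identical analytes.
#' @param tolerance maximum acceptable median residual fraction (default
#'   0.1).
#' @return list with `residuals` (per analyte), `median_residual`, `pass`.
#' @export
blocking_control_check <- function(adapted_blocked, adapted_unblocked,
                                   tolerance = 0.1) {
  B <- if (inherits(adapted_blocked, "luminex_plate"))
    lp_values(adapted_blocked) else adapted_blocked
  U <- if (inherits(adapted_unblocked, "luminex_plate"))
    lp_values(adapted_unblocked) else adapted_unblocked
  if (!identical(rownames(B), rownames(U)))
    stop_config("analyte sets differ between blocked and unblocked plates")
  r <- rowMeans(B) / rowMeans(U)
  r[rowMeans(U) <= 0] <- NA_real_
  med <- stats::median(r, na.rm = TRUE)
  list(residuals = r, median_residual = med,
       pass = !is.na(med) && med <= tolerance)
}
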