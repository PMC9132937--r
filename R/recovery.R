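# Recovery scoring: compare downstream calls against the planted truth of a
# synthetic dataset.

#' Score recovery of planted effects
#'
#' Compares enrichment calls or regional signature assignments against the
#' ground truth recorded by [generate_ms_dataset()]. The bait and
#' endogenous-biotin proteins are excluded from the positive set by
#' definition (they are planted structure, not cell-type enrichment), on
#' both the call and the truth side.
#'
#' For enrichment calls (a classified `enrichment_table`, or a character
#' vector of called identifiers) the metrics are sensitivity
#' (`TP / n_true`), specificity (`TN / n_null`), and the empirical false
#' discovery rate (`FP / n_called`). An empty call set gives sensitivity 0
#' and an undefined FDR (`NA` with `fdr_defined = FALSE`); an empty truth
#' set gives an undefined sensitivity, flagged rather than reported as 0.
#'
#' For a `regional_signature_set` the metrics additionally report how many
#' truly regional proteins were assigned to the correct region
#' (`n_correct_region`); a truth region counts as correct when it belongs to
#' the merged region group the protein was assigned to.
#'
#' @param truth a `synth_truth` object.
#' @param calls a classified `enrichment_table`, a character vector of
#'   called protein ids, or a `regional_signature_set`.
#' @param universe optional character vector of the protein ids that were
#'   actually tested (defaults to the truth's full protein set); needed for
#'   specificity after row filtering.
#' @return list of class `recovery_metrics`.
#' @export
score_recovery <- function(truth, calls, universe = NULL) {
  stopifnot(inherits(truth, "synth_truth"))
  excl <- c(truth$bait_id, truth$endogenous_ids)

  if (inherits(calls, "regional_signature_set")) {
    asn <- calls$assignment
    asn <- asn[!asn$protein_group_id %in% excl, , drop = FALSE]
    tmap <- truth$regional_map
    in_truth <- asn$protein_group_id %in% names(tmap)
    correct <- vapply(which(in_truth), function(i) {
      grp <- calls$region_groups[[asn$region[i]]]
      tmap[[asn$protein_group_id[i]]] %in% grp
    }, logical(1))
    n_true <- length(tmap)
    res <- list(
      kind = "regional",
      n_true = n_true,
      n_called = nrow(asn),
      n_correct_region = sum(correct),
      n_misassigned = sum(!correct),
      n_false = sum(!in_truth),
      sensitivity = if (n_true > 0) sum(correct) / n_true else NA_real_,
      sensitivity_defined = n_true > 0)
    return(structure(res, class = "recovery_metrics"))
  }

  called <- if (is.character(calls)) calls else {
    if (!"class" %in% names(calls))
      stop_config("enrichment table must be classified first")
    calls$protein_group_id[calls$class == "enriched_a"]
  }
  ids <- universe %||% rownames(truth$true_means)
  ids <- setdiff(ids, excl)
  called <- setdiff(intersect(called, ids), excl)
  pos <- intersect(truth$enriched_ids, ids)
  neg <- setdiff(ids, pos)

  tp <- length(intersect(called, pos))
  fp <- length(setdiff(called, pos))
  tn <- length(setdiff(neg, called))

  structure(list(
    kind = "enrichment",
    n_true = length(pos), n_called = length(called),
    tp = tp, fp = fp,
    sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
    sensitivity_defined = length(pos) > 0,
    specificity = if (length(neg)) tn / length(neg) else NA_real_,
    fdr = if (length(called)) fp / length(called) else NA_real_,
    fdr_defined = length(called) > 0), class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("recovery_metrics [", x$kind, "]\n", sep = "")
  if (x$kind == "enrichment") {
    cat(sprintf("  sensitivity: %s  specificity: %s  FDR: %s\n",
                format(x$sensitivity, digits = 3),
                format(x$specificity, digits = 3),
                if (x$fdr_defined) format(x$fdr, digits = 3)
                else "undefined"))
  } else {
    cat(sprintf("  %d/%d regional proteins in correct region (%d wrong, %d false)\n",
                x$n_correct_region, x$n_true, x$n_misassigned, x$n_false))
  }
  invisible(x)
}
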