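# Over-representation analysis of a hit list against gene-set collections:
# exact hypergeometric upper-tail p together with a finite-population-
# corrected normal-approximation Z-score; the enriched flag follows the
# Z > 1.96 rule.

#' Over-representation test of a hit list against one gene set
#'
#' With background size `N`, term size `K` (term intersected with the
#' background), hit-list size `n` (hits within the background) and overlap
#' `k`, reports the exact hypergeometric upper-tail probability
#' `P(X >= k)` and the Z-score
#'
#' `z = (k - nK/N) / sqrt(n (K/N)(1 - K/N) (N - n)/(N - 1))`
#'
#' i.e. the overlap standardized by the hypergeometric mean and the
#' finite-population-corrected variance. A gene set is flagged `enriched`
#' when `z > z_threshold` (default 1.96, the two-sided 5% normal point).
#'
#' Symbols are case-folded before any set operation; duplicate hits are
#' removed; hits absent from the background are dropped with a warning
#' reporting their count.
#'
#' @param hits character vector of hit gene symbols.
#' @param background character vector of background gene symbols.
#' @param term character vector of gene-set symbols.
#' @param z_threshold Z cut-off for the enriched flag.
#' @return one-row data.frame with `k`, `n`, `K`, `N`, `p_one_sided`,
#'   `z_score`, `enriched`.
#' @export
ora_test <- function(hits, background, term, z_threshold = 1.96) {
  background <- unique(fold_symbols(background))
  if (!length(background)) stop_config("empty background")
  hits <- unique(fold_symbols(hits))
  outside <- setdiff(hits, background)
  if (length(outside)) {
    warning(sprintf("%d hit symbol(s) not in background; dropped",
                    length(outside)))
    hits <- intersect(hits, background)
  }
  if (!length(hits)) stop_config("no hits remain within the background")
  term <- intersect(unique(fold_symbols(term)), background)

  N <- length(background)
  n <- length(hits)
  K <- length(term)
  k <- length(intersect(hits, term))

  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  varK <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
  z <- if (varK > 0) (k - expected) / sqrt(varK) else NA_real_
  data.frame(k = k, n = n, K = K, N = N, p_one_sided = p, z_score = z,
             enriched = !is.na(z) && z > z_threshold)
}

#' Run over-representation analysis over a term collection
#'
#' Applies [ora_test()] to every gene set of a collection (e.g. from
#' [read_gmt()]) and returns one row per term, sorted by descending Z-score.
#' Terms whose Z is undefined (zero hypergeometric variance, e.g. a term
#' covering the whole background) are retained with `z_score = NA`, flagged
#' not enriched, and sorted last.
#'
#' @param hits,background character vectors of gene symbols.
#' @param terms a `term_collection` (named list of symbol vectors).
#' @param z_threshold Z cut-off for the enriched flag (default 1.96).
#' @param criterion `"z"` (default: enriched when `z > z_threshold`) or
#'   `"fisher"` (enriched when the exact one-sided p is at most
#'   `p_threshold`). The two agree asymptotically but can differ for small
#'   terms.
#' @param p_threshold p cut-off used by the `"fisher"` criterion.
#' @return data.frame of class `ora_table` with one row per term.
#' @export
run_ora <- function(hits, background, terms, z_threshold = 1.96,
                    criterion = c("z", "fisher"), p_threshold = 0.05) {
  criterion <- match.arg(criterion)
  if (!length(terms)) {
    warning("empty term collection")
    out <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(),
                      p_one_sided = numeric(), z_score = numeric(),
                      enriched = logical())
    class(out) <- c("ora_table", "data.frame")
    return(out)
  }
  rows <- lapply(names(terms), function(tm) {
    r <- suppressWarnings(ora_test(hits, background, terms[[tm]],
                                   z_threshold = z_threshold))
    cbind(term = tm, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # Re-warn once about out-of-background hits rather than per term.
  outside <- setdiff(unique(fold_symbols(hits)),
                     unique(fold_symbols(background)))
  if (length(outside))
    warning(sprintf("%d hit symbol(s) not in background; dropped",
                    length(outside)))
  if (criterion == "fisher") {
    out$enriched <- out$p_one_sided <= p_threshold
  }
  out <- out[order(-out$z_score, out$p_one_sided, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_table", "data.frame")
  out
}

#' Z-score matrix for several hit lists over one term collection
#'
#' Convenience wrapper producing the terms x lists matrix of enrichment
#' Z-scores used for pathway heatmaps (one column per protein list, e.g. per
#' regional signature).
#'
#' @param hit_lists named list of character vectors of gene symbols.
#' @param background background symbols.
#' @param terms a `term_collection`.
#' @return numeric matrix, terms in rows, hit lists in columns.
#' @export
ora_z_matrix <- function(hit_lists, background, terms) {
  stopifnot(length(names(hit_lists)) == length(hit_lists))
  cols <- lapply(hit_lists, function(h) {
    tab <- suppressWarnings(run_ora(h, background, terms))
    stats::setNames(tab$z_score, tab$term)[names(terms)]
  })
  m <- do.call(cbind, cols)
  rownames(m) <- names(terms)
  m
}
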