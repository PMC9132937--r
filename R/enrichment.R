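# Two-group differential enrichment: per-protein unpaired t-tests with
# fold-change / p-value classification (the volcano-plot computation).

#' Per-protein two-group t-test
#'
#' Computes, for every protein row, the log2 fold change (mean of group A
#' minus mean of group B), the unpaired two-sided t statistic and its
#' unadjusted p value. The pooled-variance Student test is the default (the
#' Perseus convention); Welch's unequal-variance test is available.
#'
#' Degenerate variance is handled explicitly: zero pooled variance with equal
#' means yields `t = 0, p = 1`; zero variance with unequal means yields a
#' machine-minimum p value with the `degenerate` flag set.
#'
#' @param mat a fully observed log2-scale [intensity_matrix()]
#'   (post-imputation).
#' @param group_a,group_b character vectors of sample ids (see
#'   [select_samples()]); each group needs at least 2 samples.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return a data.frame of class `enrichment_table` with columns
#'   `protein_group_id`, `log2_fc`, `t_stat`, `p_value`, `n_a`, `n_b`,
#'   `degenerate`.
#' @export
two_group_test <- function(mat, group_a, group_b,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(mat, "intensity_matrix"))
  v <- im_values(mat)
  if (!length(group_a) || !length(group_b))
    stop_config("empty group selector")
  bad <- setdiff(c(group_a, group_b), colnames(v))
  if (length(bad))
    stop_config("unknown sample(s): ", paste(bad, collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_config("each group needs at least 2 samples")
  A <- v[, group_a, drop = FALSE]
  B <- v[, group_b, drop = FALSE]
  if (anyNA(A) || anyNA(B))
    stop_config("matrix must be fully observed in the tested samples; ",
                "impute first")
  na <- ncol(A)
  nb <- ncol(B)
  ma <- rowMeans(A)
  mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  d <- ma - mb

  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(d))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }

  t_stat <- d / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se == 0
  zero_eq <- degenerate & d == 0
  zero_ne <- degenerate & d != 0
  t_stat[zero_eq] <- 0
  p[zero_eq] <- 1
  t_stat[zero_ne] <- sign(d[zero_ne]) * Inf
  p[zero_ne] <- .Machine$double.xmin

  out <- data.frame(protein_group_id = rownames(v), log2_fc = d,
                    t_stat = t_stat, p_value = p, n_a = na, n_b = nb,
                    degenerate = degenerate, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Classify proteins as enriched by fold-change and p-value thresholds
#'
#' A protein is `enriched_a` when its fold change is at least
#' `fc_threshold`-fold toward group A (`log2_fc >= log2(fc_threshold)`) AND
#' `p_value <= p_threshold`; symmetrically `enriched_b`; otherwise `ns`.
#' Boundary equality counts as passing on both thresholds.
#'
#' @param table an `enrichment_table` from [two_group_test()].
#' @param fc_threshold linear fold-change threshold (> 1); default 2.
#' @param p_threshold unadjusted p-value threshold in (0, 1]; default 0.05.
#' @param adjust if `TRUE`, append a Benjamini-Hochberg `p_adjust` column
#'   (informational; classification always uses the unadjusted p).
#' @return the table with a `class` column added.
#' @export
classify_enrichment <- function(table, fc_threshold = 2, p_threshold = 0.05,
                                adjust = FALSE) {
  if (fc_threshold <= 1) stop_config("fc_threshold must be > 1")
  if (p_threshold <= 0 || p_threshold > 1)
    stop_config("p_threshold must be in (0, 1]")
  lfc <- log2(fc_threshold)
  cls <- rep("ns", nrow(table))
  sig <- table$p_value <= p_threshold
  cls[sig & table$log2_fc >= lfc] <- "enriched_a"
  cls[sig & table$log2_fc <= -lfc] <- "enriched_b"
  table$class <- cls
  if (adjust) table$p_adjust <- stats::p.adjust(table$p_value, "BH")
  class(table) <- c("enrichment_table", "data.frame")
  table
}

#' Export a classified enrichment table and volcano plot
#'
#' Writes the table sorted by ascending p value as TSV and, optionally, a
#' volcano plot (-log10 p vs log2 fold change, colored by class). P values
#' of zero (degenerate-variance convention) are plotted at a cap of
#' `-log10 p = 320` and the cap is reported.
#'
#' @param table a classified `enrichment_table`.
#' @param path_tsv output TSV path (`NULL` to skip).
#' @param path_plot output plot path, png or pdf (`NULL` to skip).
#' @param labels protein ids to annotate with text on the plot.
#' @return the ggplot object, invisibly.
#' @export
volcano_export <- function(table, path_tsv = NULL, path_plot = NULL,
                           labels = character()) {
  if (!"class" %in% names(table))
    stop_config("table must be classified first (classify_enrichment)")
  ord <- order(table$p_value)
  tab <- table[ord, , drop = FALSE]
  if (!is.null(path_tsv))
    utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  cap <- 320
  nlp <- -log10(pmax(tab$p_value, 10^(-cap)))
  if (any(tab$p_value < 10^(-cap)))
    message(sprintf("volcano_export: -log10 p capped at %d", cap))
  df <- data.frame(log2_fc = tab$log2_fc, neg_log10_p = nlp,
                   class = tab$class, id = tab$protein_group_id)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = log2_fc, y = neg_log10_p,
                                         color = class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(enriched_a = "#E69F00",
                                           enriched_b = "#0072B2",
                                           ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_bw()
  if (length(labels)) {
    sel <- df[df$id %in% labels, , drop = FALSE]
    gg <- gg + ggplot2::geom_text(data = sel, ggplot2::aes(label = id),
                                  size = 2.5, vjust = -0.6,
                                  show.legend = FALSE)
  }
  if (!is.null(path_plot))
    suppressMessages(ggplot2::ggsave(path_plot, gg, width = 6, height = 5))
  invisible(gg)
}
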