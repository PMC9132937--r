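# Reading and writing protein-group quantification tables (MaxQuant
# proteinGroups.txt dialect and the package's canonical TSV), sample designs,
# and GMT gene-set files; flagging of reverse/contaminant/bait/endogenous
# entries.

#' Dialect describing a protein-group table layout
#'
#' The default matches MaxQuant `proteinGroups.txt`: per-sample columns named
#' `"Intensity <sample>"`, `+`-marked `Reverse` and `Potential contaminant`
#' columns, and semicolon-separated identifier lists. Any tab-separated table
#' can be ingested by adjusting the column patterns.
#'
#' @param intensity_prefix prefix of per-sample intensity columns.
#' @param id_col column holding the protein-group identifier.
#' @param gene_col column holding gene symbols (may be absent in the file).
#' @param reverse_col,contaminant_col marker columns; a cell equal to
#'   `marker` flags the row. Absent columns mean no rows flagged.
#' @param marker the flag character, `"+"` by MaxQuant convention.
#' @param bait_identifiers identifiers (matched case-insensitively as
#'   substrings against the protein-group id and gene symbol) that mark the
#'   biotin-ligase bait entry. Default covers TurboID/V5/BirA-derived tags.
#' @param endogenous_symbols gene symbols of endogenously biotinylated
#'   carboxylases that bind streptavidin in all samples.
#' @return a list of class `pg_dialect`.
#' @export
pg_dialect <- function(intensity_prefix = "Intensity ",
                       id_col = "Protein IDs",
                       gene_col = "Gene names",
                       reverse_col = "Reverse",
                       contaminant_col = "Potential contaminant",
                       marker = "+",
                       bait_identifiers = c("TurboID", "V5", "BirA"),
                       endogenous_symbols = c("Pc", "Pcx", "Acaca", "Acacb",
                                              "Mccc1", "Mccc2", "Pcca",
                                              "Pccb")) {
  structure(list(intensity_prefix = intensity_prefix, id_col = id_col,
                 gene_col = gene_col, reverse_col = reverse_col,
                 contaminant_col = contaminant_col, marker = marker,
                 bait_identifiers = bait_identifiers,
                 endogenous_symbols = endogenous_symbols),
            class = "pg_dialect")
}

#' Read a protein-group intensity table
#'
#' Parses a MaxQuant-style tab-separated table into a linear-scale
#' [intensity_matrix()] plus per-protein metadata. Intensity zeros are
#' converted to missing (`NA`), following the label-free quantification
#' convention that an unquantified protein is reported as 0.
#'
#' @param path path to the tab-separated file.
#' @param dialect a [pg_dialect()].
#' @return a list with elements `matrix` (linear-scale `intensity_matrix`)
#'   and `meta` (data.frame with columns `protein_group_id`, `gene_symbol`,
#'   `gene_symbols_full`, `is_reverse`, `is_contaminant`, `is_bait`,
#'   `is_endogenous_biotin`).
#' @export
read_protein_groups <- function(path, dialect = pg_dialect()) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  int_cols <- grep(paste0("^", dialect$intensity_prefix, "."),
                   names(tab), value = TRUE)
  if (!length(int_cols))
    stop_format("no intensity columns matching prefix '",
                dialect$intensity_prefix, "' in ", path)
  if (!dialect$id_col %in% names(tab))
    stop_format("identifier column '", dialect$id_col, "' not found in ",
                path)
  ids <- as.character(tab[[dialect$id_col]])
  if (anyDuplicated(ids))
    stop_format("duplicate protein identifiers in ", path, ": ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))

  values <- as.matrix(tab[, int_cols, drop = FALSE])
  storage.mode(values) <- "double"
  values[values == 0] <- NA_real_
  rownames(values) <- ids
  colnames(values) <- sub(paste0("^", dialect$intensity_prefix), "",
                          int_cols)

  flag_col <- function(col) {
    if (col %in% names(tab)) {
      !is.na(tab[[col]]) & tab[[col]] == dialect$marker
    } else rep(FALSE, nrow(tab))
  }
  genes_full <- if (dialect$gene_col %in% names(tab)) {
    as.character(tab[[dialect$gene_col]])
  } else rep("", nrow(tab))
  genes_full[is.na(genes_full)] <- ""

  bait_pat <- paste(dialect$bait_identifiers, collapse = "|")
  is_bait <- grepl(bait_pat, ids, ignore.case = TRUE) |
    grepl(bait_pat, genes_full, ignore.case = TRUE)
  if (sum(is_bait) > 1)
    stop_format("more than one bait entry matched: ",
                paste(ids[is_bait], collapse = ", "))

  meta <- data.frame(
    protein_group_id = ids,
    gene_symbol = first_symbol(genes_full),
    gene_symbols_full = genes_full,
    is_reverse = flag_col(dialect$reverse_col),
    is_contaminant = flag_col(dialect$contaminant_col),
    is_bait = is_bait,
    is_endogenous_biotin =
      fold_symbols(first_symbol(genes_full)) %in%
        fold_symbols(dialect$endogenous_symbols) & !is_bait,
    stringsAsFactors = FALSE
  )
  if (any(meta$is_reverse & meta$is_bait))
    stop_format("bait entry flagged as reverse hit; inputs inconsistent")
  list(matrix = intensity_matrix(values, scale = "linear"), meta = meta)
}

#' Write a protein-group matrix in the canonical dialect
#'
#' Emits a tab-separated table that [read_protein_groups()] reads back
#' unchanged (round-trip guaranteed on the canonical dialect): identifier and
#' gene columns, `+`-marked flag columns, and one `Intensity <sample>` column
#' per sample with missing cells written as 0.
#'
#' @param mat a linear-scale [intensity_matrix()].
#' @param meta protein metadata as returned by [read_protein_groups()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(mat, meta, path) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (im_scale(mat) != "linear")
    stop_config("write_protein_groups expects a linear-scale matrix")
  v <- im_values(mat)
  meta <- meta[match(rownames(v), meta$protein_group_id), , drop = FALSE]
  out <- data.frame(`Protein IDs` = meta$protein_group_id,
                    `Gene names` = meta$gene_symbols_full,
                    Reverse = ifelse(meta$is_reverse, "+", ""),
                    `Potential contaminant` = ifelse(meta$is_contaminant,
                                                     "+", ""),
                    check.names = FALSE, stringsAsFactors = FALSE)
  vi <- v
  vi[is.na(vi)] <- 0
  colnames(vi) <- paste0("Intensity ", colnames(v))
  out <- cbind(out, as.data.frame(vi, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV or CSV file with columns `sample_id`, `genotype`,
#'   `region`, `mouse_id` and optionally `tech_rep`, `driver`.
#' @return a [sample_design()] table.
#' @export
read_sample_design <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "region", "mouse_id")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_format("design file lacks columns: ", paste(miss, collapse = ", "))
  sample_design(d$sample_id, d$genotype, d$region, d$mouse_id,
                tech_rep = d$tech_rep %||% 1L,
                driver = d$driver %||% "none")
}

#' Write a sample design table
#' @param design a [sample_design()] table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drop reverse-database and contaminant entries
#'
#' Removes rows flagged as reverse hits or potential contaminants. The bait
#' row is always retained, even if the upstream search flagged it (a common
#' artifact when the ligase tag matches a contaminant database entry); a
#' warning is emitted in that case.
#'
#' @param mat an [intensity_matrix()].
#' @param meta matching protein metadata.
#' @param drop_reverse,drop_contaminant which flag classes to remove.
#' @return list with filtered `matrix`, `meta`, and a `removed` character
#'   vector of dropped identifiers.
#' @export
filter_flagged <- function(mat, meta, drop_reverse = TRUE,
                           drop_contaminant = TRUE) {
  meta <- meta[match(rownames(im_values(mat)), meta$protein_group_id), ,
               drop = FALSE]
  drop <- (drop_reverse & meta$is_reverse) |
    (drop_contaminant & meta$is_contaminant)
  if (any(drop & meta$is_bait)) {
    warning("bait entry carried a reverse/contaminant flag; retained anyway")
    drop <- drop & !meta$is_bait
  }
  removed <- meta$protein_group_id[drop]
  if (length(removed))
    message(sprintf("filter_flagged: removed %d of %d rows", length(removed),
                    nrow(meta)))
  list(matrix = mat[!drop, ], meta = meta[!drop, , drop = FALSE],
       removed = removed)
}

#' Log2-transform a linear-scale intensity matrix
#'
#' @param mat a linear-scale [intensity_matrix()]; all present values must be
#'   strictly positive.
#' @return the matrix on log2 scale; missing cells stay missing.
#' @export
log2_transform <- function(mat) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (im_scale(mat) != "linear")
    stop_config("matrix is already on ", im_scale(mat), " scale")
  v <- im_values(mat)
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_format("nonpositive intensities at: ",
                paste(sprintf("[%s, %s]", rownames(v)[bad[, 1]],
                              colnames(v)[bad[, 2]]), collapse = "; "))
  intensity_matrix(log2(v), scale = "log2", imputed = im_imputed(mat))
}

#' Back-transform a log2 matrix to linear intensities
#' @param mat a log2-scale [intensity_matrix()].
#' @return the matrix on linear scale.
#' @export
delog2_transform <- function(mat) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (im_scale(mat) != "log2")
    stop_config("matrix is not on log2 scale")
  intensity_matrix(2^im_values(mat), scale = "linear",
                   imputed = im_imputed(mat))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term<TAB>description<TAB>symbol1<TAB>symbol2...`. Symbols are upper-cased
#' so mouse and human symbol casings compare equal, and deduplicated within a
#' term. Terms with no symbols are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors (class `term_collection`), with
#'   a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop_format("malformed GMT line(s) ", paste(short, collapse = ", "),
                " in ", path, " (fewer than 2 fields)")
  terms <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    syms <- unique(fold_symbols(f[-(1:2)]))
    syms[nzchar(syms)]
  })
  names(sets) <- terms
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sprintf("dropped %d empty term(s): %s", sum(empty),
                    paste(terms[empty], collapse = ", ")))
    sets <- sets[!empty]
    descs <- descs[!empty]
  }
  structure(sets, descriptions = stats::setNames(descs, names(sets)),
            class = c("term_collection", "list"))
}

#' Read a background symbol list (one symbol per line)
#' @param path text file, one gene symbol per line.
#' @return character vector of unique upper-cased symbols.
#' @export
read_background <- function(path) {
  syms <- unique(fold_symbols(readLines(path, warn = FALSE)))
  syms[nzchar(syms)]
}
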