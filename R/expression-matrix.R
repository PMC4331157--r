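#' Log2 expression matrices
#'
#' Container for an already-normalized log2 microarray intensity matrix
#' (probesets x samples) with per-sample binary group labels and a
#' probeset-to-gene-symbol map.  Symbols may be `NA` for unannotated
#' probesets.  Intensities must be complete (no missing values); on typical
#' gcrma-style normalized chips they fall roughly in [2, 15] log2 units.
#'
#' @param log2_intensity numeric matrix, probesets in rows, samples in
#'   columns, no `NA`s.
#' @param group_labels character vector, one per sample, two distinct values.
#' @param gene_symbol character vector of gene symbols aligned to the
#'   probeset rows; `NA` allowed.
#' @param probeset_ids,sample_ids optional identifiers overriding dimnames.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(log2_intensity, group_labels,
                              gene_symbol = NULL,
                              probeset_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(log2_intensity) || !is.numeric(log2_intensity))
    stop("'log2_intensity' must be a numeric matrix (probesets x samples)")
  if (!is.null(probeset_ids)) rownames(log2_intensity) <- probeset_ids
  if (!is.null(sample_ids)) colnames(log2_intensity) <- sample_ids
  if (is.null(rownames(log2_intensity)))
    stop("probeset ids are required (rownames)")
  if (is.null(colnames(log2_intensity)))
    colnames(log2_intensity) <- paste0("sample", seq_len(ncol(log2_intensity)))
  if (anyDuplicated(rownames(log2_intensity)))
    stop("duplicated probeset id: ",
         rownames(log2_intensity)[duplicated(rownames(log2_intensity))][1L])
  if (anyNA(log2_intensity) || any(!is.finite(log2_intensity)))
    stop("missing or non-finite intensities are not allowed")
  if (length(group_labels) != ncol(log2_intensity))
    stop("'group_labels' must have one entry per sample")
  group_labels <- as.character(group_labels)
  if (length(unique(group_labels)) != 2L)
    stop("exactly two groups are required")
  if (is.null(gene_symbol))
    gene_symbol <- rep(NA_character_, nrow(log2_intensity))
  if (length(gene_symbol) != nrow(log2_intensity))
    stop("'gene_symbol' must be aligned to probeset rows")
  gene_symbol <- as.character(gene_symbol)
  names(gene_symbol) <- rownames(log2_intensity)
  structure(
    list(log2_intensity = log2_intensity, group_labels = group_labels,
         gene_symbol = gene_symbol),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$group_labels)
  cat("Expression matrix: ", nrow(x$log2_intensity), " probesets x ",
      ncol(x$log2_intensity), " samples\n",
      "  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      "  annotated probesets: ", sum(!is.na(x$gene_symbol)), "/",
      length(x$gene_symbol), "\n",
      "  log2 range: [", round(min(x$log2_intensity), 2), ", ",
      round(max(x$log2_intensity), 2), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$log2_intensity)

#' Read / write an expression matrix as TSV
#'
#' Tab-separated with columns `probeset_id`, `gene_symbol`, then one numeric
#' column per sample.  Group labels travel in a header comment line
#' `#groups: <label>,<label>,...` aligned with the sample columns.
#'
#' @param path file path.
#' @return `read_expression_matrix()` returns an [expression_matrix()];
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#groups:"))
    stop("expression matrix format error: missing '#groups:' header line")
  groups <- strsplit(sub("^#groups:\\s*", "", first), ",", fixed = TRUE)[[1L]]
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("probeset_id", "gene_symbol")
  if (!all(need %in% names(df)))
    stop("expression matrix format error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  samples <- setdiff(names(df), need)
  m <- as.matrix(df[samples])
  if (!is.numeric(m))
    stop("expression matrix format error: non-numeric intensity")
  rownames(m) <- df$probeset_id
  if (length(groups) != ncol(m))
    stop("expression matrix format error: #groups length ", length(groups),
         " does not match ", ncol(m), " sample columns")
  expression_matrix(m, group_labels = groups, gene_symbol = df$gene_symbol)
}

#' @rdname read_expression_matrix
#' @param x an [expression_matrix()].
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#groups: ", paste(x$group_labels, collapse = ",")), con)
  df <- data.frame(probeset_id = rownames(x$log2_intensity),
                   gene_symbol = x$gene_symbol,
                   x$log2_intensity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a result table as TSV
#'
#' Serializes the `$table` component of any of the package's fitted result
#' objects ([mir_differential()], [mrna_differential()], [mir_roc()],
#' [integrate_mir_mrna()] components) with its column order preserved.
#'
#' @param result a result object with a `table` data-frame component, or a
#'   plain data frame.
#' @param path output file path.
#' @export
write_result_table <- function(result, path) {
  df <- if (is.data.frame(result)) result else result$table
  if (!is.data.frame(df))
    stop("'result' has no tabular component to write")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
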