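#' Cycle-threshold (CT) tables
#'
#' A `ct_table` holds raw qPCR cycle-threshold values for a panel of miRNA
#' assays measured on a set of samples, together with a binary group label
#' per sample and the name of the endogenous-control assay used for
#' normalization (typically the small nuclear RNA U6).  Undetermined wells
#' (no amplification within the run) are stored as `NA`; they are distinct
#' from censored wells (CT above the detection limit), which keep their raw
#' value here and are truncated downstream by [truncate_ct()].
#'
#' @param ct numeric matrix of CT values (cycles), samples in rows, assays in
#'   columns; `NA` marks an undetermined well.  Row and column names are used
#'   as sample and assay identifiers when `sample_ids`/`assay_ids` are not
#'   given.
#' @param group_labels character vector, one label per sample; exactly two
#'   distinct labels must be present.
#' @param control_assay_id name of the endogenous-control assay, default
#'   `"U6"`; must be one of the assay columns.
#' @param sample_ids,assay_ids optional identifier vectors overriding the
#'   dimnames of `ct`.
#'
#' @return An object of class `ct_table`: a list with elements `ct`
#'   (samples x assays numeric matrix), `group_labels`, `control_assay_id`.
#' @examples
#' ct <- matrix(c(20, 24, 21, 25, 20.5, 23), nrow = 3, byrow = TRUE,
#'              dimnames = list(paste0("s", 1:3), c("U6", "miR-1")))
#' tab <- ct_table(ct, group_labels = c("MPM", "MPM", "BAPE"))
#' tab
#' @export
ct_table <- function(ct, group_labels, control_assay_id = "U6",
                     sample_ids = NULL, assay_ids = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric matrix (samples x assays)")
  if (!is.null(sample_ids)) rownames(ct) <- sample_ids
  if (!is.null(assay_ids)) colnames(ct) <- assay_ids
  if (is.null(rownames(ct))) rownames(ct) <- paste0("sample", seq_len(nrow(ct)))
  if (is.null(colnames(ct))) stop("assay names are required (colnames of 'ct')")
  if (anyDuplicated(colnames(ct)))
    stop("duplicated assay id: ", colnames(ct)[duplicated(colnames(ct))][1L])
  if (anyDuplicated(rownames(ct)))
    stop("duplicated sample id: ", rownames(ct)[duplicated(rownames(ct))][1L])
  if (length(group_labels) != nrow(ct))
    stop("'group_labels' must have one entry per sample (", nrow(ct), ")")
  group_labels <- as.character(group_labels)
  lev <- unique(group_labels)
  if (length(lev) != 2L)
    stop("exactly two groups are required, found: ",
         paste(lev, collapse = ", "))
  if (!control_assay_id %in% colnames(ct))
    stop("control assay '", control_assay_id, "' not found among assays")
  bad <- which(!is.na(ct) & (!is.finite(ct) | ct <= 0))
  if (length(bad))
    stop("CT values must be finite and positive; offending well at row ",
         row(ct)[bad[1L]], ", column ", col(ct)[bad[1L]])
  structure(
    list(ct = ct, group_labels = group_labels,
         control_assay_id = control_assay_id),
    class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  tab <- table(x$group_labels)
  cat("CT table: ", nrow(x$ct), " samples x ", ncol(x$ct), " assays\n",
      "  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      "  control assay: ", x$control_assay_id, "\n",
      "  undetermined wells: ", sum(is.na(x$ct)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$ct)

#' Read / write a CT table as CSV
#'
#' The on-disk format is a comma-separated file with one row per sample:
#' a `sample_id` column, a `group` column, and one numeric column per assay.
#' Empty cells denote undetermined wells and are read back as `NA`.
#'
#' @param path file path.
#' @param control_assay_id endogenous-control assay name expected among the
#'   assay columns (default `"U6"`).
#' @return `read_ct_table()` returns a [ct_table()]; `write_ct_table()`
#'   returns `path` invisibly.
#' @export
read_ct_table <- function(path, control_assay_id = "U6") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("CT table format error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  assays <- setdiff(names(df), need)
  if (!control_assay_id %in% assays)
    stop("CT table format error: no '", control_assay_id,
         "' control assay column in ", path)
  ct <- as.matrix(df[assays])
  if (!is.numeric(ct))
    stop("CT table format error: non-numeric CT values")
  rownames(ct) <- df$sample_id
  ct_table(ct, group_labels = df$group, control_assay_id = control_assay_id)
}

#' @rdname read_ct_table
#' @param x a [ct_table()].
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  df <- data.frame(sample_id = rownames(x$ct), group = x$group_labels,
                   x$ct, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
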