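#' Gene-set collections and the GMT format
#'
#' A `gene_set_collection` is a named list of character vectors of gene
#' symbols, tagged with a `kind`: `"pathway"` for canonical-pathway
#' collections (MSigDB c2.cp style) or `"mir_target"` for miRNA-target
#' collections (c3 style) in which each set name identifies one miRNA.
#'
#' @param sets named list of character vectors; duplicates within a set are
#'   removed.
#' @param kind `"pathway"` or `"mir_target"`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, kind = c("pathway", "mir_target")) {
  kind <- match.arg(kind)
  if (length(sets) && is.null(names(sets)))
    stop("gene sets must be named")
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    if (any(!nzchar(s)) || anyNA(s))
      stop("set members must be non-empty strings")
    s
  })
  structure(list(sets = sets, kind = kind), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("Gene set collection (", x$kind, "): ", length(x$sets), " sets, ",
      length(unique(unlist(x$sets, use.names = FALSE))), " distinct genes\n",
      sep = "")
  if (length(sizes))
    cat("  set sizes: min ", min(sizes), ", median ",
        stats::median(sizes), ", max ", max(sizes), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read / write GMT gene-set files
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`.  The description field is ignored on
#' read and written back as `"na"`.  Duplicate members within a line are
#' deduplicated.
#'
#' @param path file path.
#' @param kind collection kind, see [gene_set_collection()].
#' @return `read_gmt()` returns a [gene_set_collection()]; `write_gmt()`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path, kind = c("pathway", "mir_target")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT format error: empty file ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("GMT format error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets)))
    stop("GMT format error: duplicated set name '",
         names(sets)[duplicated(names(sets))][1L], "'")
  gene_set_collection(sets, kind = kind)
}

#' @rdname read_gmt
#' @param x a [gene_set_collection()].
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(seq_along(x$sets), function(i) {
    paste(c(names(x$sets)[i], "na", x$sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Normalize a miRNA assay name for target-set matching
#'
#' TaqMan assay names (`hsa-miR-19a`) and MSigDB c3 target-set names differ
#' in convention; matching strips a leading species prefix (`hsa-`) and
#' lowercases.
#'
#' @param x character vector of miRNA names.
#' @return normalized names.
#' @export
normalize_mir_name <- function(x) {
  tolower(sub("^hsa-", "", x))
}
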