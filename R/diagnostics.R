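#' Area under the ROC curve for a delta-CT biomarker
#'
#' Orientation: low delta-CT means high expression, so a sample is
#' classified as case when its delta-CT falls at or below the cutoff.  The
#' AUC is the Mann-Whitney probability that a random case sample scores more
#' case-like (lower) than a random reference sample, with ties counting one
#' half:
#' `AUC = (#\{case_i < ref_j\} + 0.5 * #\{case_i = ref_j\}) / (n_case * n_ref)`.
#'
#' @param scores_case,scores_ref numeric delta-CT values for the two groups;
#'   both non-empty, no `NA`.
#' @return AUC in [0, 1].
#' @examples
#' auc(c(1, 2), c(3, 4))  # perfect separation
#' @export
auc <- function(scores_case, scores_ref) {
  if (!length(scores_case) || !length(scores_ref))
    stop("both groups must be non-empty")
  if (anyNA(scores_case) || anyNA(scores_ref))
    stop("NA scores are not allowed")
  cmp <- outer(scores_case, scores_ref, "<")
  ties <- outer(scores_case, scores_ref, "==")
  (sum(cmp) + 0.5 * sum(ties)) / (length(scores_case) * length(scores_ref))
}

# empirical ROC polyline from (0,0) to (1,1); x = 1 - specificity,
# y = sensitivity, one vertex per distinct pooled score
.roc_points <- function(scores_case, scores_ref) {
  cuts <- sort(unique(c(scores_case, scores_ref)))
  x <- c(0, vapply(cuts, function(c) mean(scores_ref <= c), numeric(1L)))
  y <- c(0, vapply(cuts, function(c) mean(scores_case <= c), numeric(1L)))
  cbind(fpr = x, sensitivity = y)
}

#' Youden-optimal cutoff for a delta-CT biomarker
#'
#' Candidate cutoffs are the midpoints between adjacent distinct pooled
#' values plus -Inf and +Inf, so a reported cutoff need not coincide with an
#' observed value.  The returned cutoff maximizes Youden's
#' J = sensitivity + specificity - 1, where sensitivity is the fraction of
#' case samples at or below the cutoff and specificity the fraction of
#' reference samples above it.  Ties in J are broken toward higher
#' specificity, then toward the lower cutoff.
#'
#' @inheritParams auc
#' @return A list with `cutoff` (cycles), `sensitivity` and `specificity`
#'   (both percentages in [0, 100]).
#' @export
select_cutoff <- function(scores_case, scores_ref) {
  if (!length(scores_case) || !length(scores_ref))
    stop("both groups must be non-empty")
  pooled <- sort(unique(c(scores_case, scores_ref)))
  cand <- c(-Inf, if (length(pooled) > 1L)
    (pooled[-1L] + pooled[-length(pooled)]) / 2, Inf)
  sens <- vapply(cand, function(c) mean(scores_case <= c), numeric(1L))
  spec <- vapply(cand, function(c) mean(scores_ref > c), numeric(1L))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[order(-spec[best], cand[best])][1L]
  list(cutoff = cand[best], sensitivity = 100 * sens[best],
       specificity = 100 * spec[best])
}

#' ROC evaluation of each miRNA as a single diagnostic marker
#'
#' Computes, per assay, the AUC of its per-sample delta-CT values for
#' discriminating case from reference samples, the Youden-optimal cutoff,
#' and the sensitivity/specificity realized at that cutoff.  Assays with
#' missing wells use their complete observations; assays with an empty
#' group are skipped with `NA`.
#'
#' @param x a [ct_table()] or a fitted [mir_differential()] object (whose
#'   normalized delta-CT values are reused).
#' @param config a [meso_config()].
#' @param assays optional character vector restricting the evaluation.
#' @return An object of class `mir_roc` with a `table` data frame (`assay`,
#'   `auc`, `cutoff`, `sensitivity`, `specificity`) and a `curves` list of
#'   ROC polylines.
#' @export
mir_roc <- function(x, config = meso_config(), assays = NULL) {
  dct <- if (inherits(x, "mir_de")) x$delta_ct
         else if (inherits(x, "ct_table")) delta_ct(x, config$ct_max)
         else stop("'x' must be a ct_table or mir_de object")
  g <- .group_split(dct$group_labels, config)
  d <- dct$delta_ct
  if (is.null(assays)) assays <- colnames(d)
  res <- lapply(assays, function(a) {
    sc <- d[g$case, a]; sr <- d[g$ref, a]
    sc <- sc[!is.na(sc)]; sr <- sr[!is.na(sr)]
    if (!length(sc) || !length(sr))
      return(list(row = data.frame(assay = a, auc = NA_real_,
                                   cutoff = NA_real_, sensitivity = NA_real_,
                                   specificity = NA_real_,
                                   stringsAsFactors = FALSE),
                  curve = NULL))
    cut <- select_cutoff(sc, sr)
    list(row = data.frame(assay = a, auc = auc(sc, sr), cutoff = cut$cutoff,
                          sensitivity = cut$sensitivity,
                          specificity = cut$specificity,
                          stringsAsFactors = FALSE),
         curve = .roc_points(sc, sr))
  })
  tab <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(tab) <- NULL
  curves <- lapply(res, `[[`, "curve")
  names(curves) <- assays
  structure(list(table = tab, curves = curves, config = config),
            class = "mir_roc")
}

#' @export
print.mir_roc <- function(x, ...) {
  cat("Per-miRNA ROC analysis: ", nrow(x$table), " assays\n", sep = "")
  top <- x$table[order(-x$table$auc), ]
  print(utils::head(top, 10L), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot ROC curves
#'
#' @param x a [mir_roc()] result.
#' @param assays assays to draw (default: up to 6 with the highest AUC).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mir_roc <- function(x, assays = NULL, ...) {
  if (is.null(assays)) {
    ok <- x$table[!is.na(x$table$auc), ]
    assays <- utils::head(ok$assay[order(-ok$auc)], 6L)
  }
  graphics::plot(c(0, 1), c(0, 1), type = "n",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  for (i in seq_along(assays)) {
    cv <- x$curves[[assays[i]]]
    if (!is.null(cv)) graphics::lines(cv[, 1L], cv[, 2L], col = i, lwd = 2)
  }
  graphics::legend("bottomright", legend = assays, col = seq_along(assays),
                   lwd = 2, cex = 0.8, bty = "n")
  invisible(x)
}
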