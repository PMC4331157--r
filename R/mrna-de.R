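#' Variance-floored signal-to-noise ratio
#'
#' The standardized group difference used to rank probesets:
#' `SNR = (m_case - m_ref) / (s_case + s_ref)` where for each group
#' `s = max(0.4 * m, sd)` — a spread floored at 40% of the group mean, which
#' guards against probesets whose tiny variance would otherwise produce
#' explosive ratios.  Positive SNR indicates overexpression in the case
#' group.  Log2 intensities are assumed positive (normalized chips sit
#' roughly in [2, 15]), so the floor is well defined.
#'
#' @param values_case,values_ref numeric log2 intensities, at least two per
#'   group.
#' @return SNR (dimensionless); `NaN` with a warning if both spreads vanish.
#' @examples
#' snr(rnorm(18, 7, 1), rnorm(6, 5, 1))
#' @export
snr <- function(values_case, values_ref) {
  if (length(values_case) < 2L || length(values_ref) < 2L)
    stop("need >= 2 values per group")
  m1 <- mean(values_case); m2 <- mean(values_ref)
  s1 <- max(0.4 * m1, stats::sd(values_case))
  s2 <- max(0.4 * m2, stats::sd(values_ref))
  if (s1 + s2 == 0) {
    warning("zero spread in both groups; SNR undefined")
    return(NaN)
  }
  (m1 - m2) / (s1 + s2)
}

#' Differential mRNA expression by floored SNR with q-value reporting rules
#'
#' Per probeset: group means and standard deviations, the floored
#' signal-to-noise ratio ([snr()]), a two-sided t-test, Storey q-values
#' across all probesets, and fold change `2^(m_case - m_ref)`.  Two boolean
#' selections are attached:
#' \itemize{
#'   \item `reported_up`: q below `mrna_q_max`, positive SNR, and case-group
#'     mean above the `mrna_mean_floor` expression floor (intensities below
#'     ~3.5 log2 are unreliable on these chips); these are the probesets a
#'     report would list, ranked by descending SNR;
#'   \item `integration_selected`: SNR above `integration_snr_min` and
#'     nominal p below `integration_p_max`; this looser list feeds the
#'     integrated pathway analysis.
#' }
#' Downregulated probesets (negative SNR) are computed and kept in the table
#' but never selected by either rule.
#'
#' @param x an [expression_matrix()].
#' @param config a [meso_config()].
#' @return An object of class `mrna_de` with a `table` data frame
#'   (`probeset_id`, `gene_symbol`, `q_value`, `snr`, `mean_ref`,
#'   `mean_case`, `fold_change`, `p_value`, `sd_case`, `sd_ref`,
#'   `s_case`, `s_ref`, `reported_up`, `integration_selected`), sorted by
#'   descending SNR, plus `pi0` and `config`.
#' @export
mrna_differential <- function(x, config = meso_config()) {
  stopifnot(inherits(x, "expression_matrix"))
  g <- .group_split(x$group_labels, config)
  m <- x$log2_intensity
  tt <- .row_t_test(m, g$case, g$ref, welch = config$welch)
  s_case <- pmax(0.4 * tt$mean_case, tt$sd_case)
  s_ref <- pmax(0.4 * tt$mean_ref, tt$sd_ref)
  snr_v <- (tt$mean_case - tt$mean_ref) / (s_case + s_ref)
  qf <- qvalues(tt$p)
  fc <- 2^(tt$mean_case - tt$mean_ref)
  reported_up <- qf$q_values < config$mrna_q_max & snr_v > 0 &
    tt$mean_case > config$mrna_mean_floor
  integration_selected <- snr_v > config$integration_snr_min &
    tt$p < config$integration_p_max
  tab <- data.frame(
    probeset_id = rownames(m),
    gene_symbol = unname(x$gene_symbol),
    q_value = qf$q_values, snr = unname(snr_v),
    mean_ref = unname(tt$mean_ref), mean_case = unname(tt$mean_case),
    fold_change = unname(fc), p_value = unname(tt$p),
    sd_case = unname(tt$sd_case), sd_ref = unname(tt$sd_ref),
    s_case = unname(s_case), s_ref = unname(s_ref),
    reported_up = unname(reported_up),
    integration_selected = unname(integration_selected),
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$snr), ]
  rownames(tab) <- NULL
  structure(list(table = tab, pi0 = qf$pi0, config = config),
            class = "mrna_de")
}

#' @export
print.mrna_de <- function(x, ...) {
  tab <- x$table
  cat("Differential mRNA expression (floored SNR): ", nrow(tab),
      " probesets\n", sep = "")
  cat("  reported up (q<", x$config$mrna_q_max, ", mean>",
      x$config$mrna_mean_floor, "): ", sum(tab$reported_up), "\n", sep = "")
  cat("  integration list (SNR>", x$config$integration_snr_min, ", P<",
      x$config$integration_p_max, "): ", sum(tab$integration_selected),
      "\n  pi0 = ", signif(x$pi0, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mrna_de <- function(object, n = 15L, ...) {
  tab <- object$table
  up <- tab[tab$reported_up, c("probeset_id", "gene_symbol", "q_value",
                               "snr", "mean_ref", "mean_case",
                               "fold_change")]
  cat("Top reported overexpressed probesets (by SNR):\n")
  print(utils::head(up, n), row.names = FALSE, digits = 3)
  invisible(object)
}

#' Unique gene symbols behind a probeset selection
#'
#' Collapses a probeset-level selection to the distinct gene symbols it
#' represents; unannotated probesets (symbol `NA`) are dropped and counted.
#'
#' @param de a fitted [mrna_differential()] object.
#' @param selector `"reported_up"` or `"integration_selected"`.
#' @return Character vector of distinct symbols with attribute
#'   `"n_unannotated"` (selected probesets without a symbol).
#' @export
unique_gene_list <- function(de, selector = c("integration_selected",
                                              "reported_up")) {
  stopifnot(inherits(de, "mrna_de"))
  selector <- match.arg(selector)
  sel <- de$table[de$table[[selector]], "gene_symbol"]
  genes <- unique(sel[!is.na(sel)])
  attr(genes, "n_unannotated") <- sum(is.na(sel))
  genes
}
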