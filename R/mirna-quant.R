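#' Truncate CT values at the detection limit
#'
#' qPCR cycle-threshold values above the detection limit are unreliable:
#' they are set to the limit (censored) rather than dropped, so that weakly
#' expressed assays still contribute bounded values to group means and
#' tests.  Missing (undetermined) wells stay missing.
#'
#' @param ct numeric vector or matrix of CT values; `NA` allowed.
#' @param limit detection limit in cycles (default 35).
#' @return `ct` with values above `limit` set to `limit`; a logical
#'   `"censored"` attribute of the same shape marks wells where truncation
#'   fired.
#' @examples
#' truncate_ct(c(28.4, 35, 37.2, NA))
#' @export
truncate_ct <- function(ct, limit = 35) {
  censored <- !is.na(ct) & ct > limit
  out <- pmin(ct, limit)
  attributes(out) <- attributes(ct)
  attr(out, "censored") <- censored
  out
}

#' Per-sample delta-CT normalization
#'
#' Subtracts each sample's endogenous-control CT from every assay CT in the
#' same sample, after truncating both at the detection limit.  Low delta-CT
#' means high expression.  Group means of these per-sample delta-CT values
#' equal the difference of group-mean CTs, so downstream group summaries
#' agree with the classical "average assay CT minus average control CT"
#' formulation.
#'
#' @param x a [ct_table()].
#' @param ct_max detection limit in cycles.
#' @return A list with `delta_ct` (samples x assays matrix, control column
#'   removed), `censored` (logical matrix, same shape, truncation flags for
#'   the assay well), `group_labels`, and `control_ct` (per-sample truncated
#'   control values).
#' @export
delta_ct <- function(x, ct_max = 35) {
  stopifnot(inherits(x, "ct_table"))
  tr <- truncate_ct(x$ct, ct_max)
  cens <- attr(tr, "censored")
  ctrl <- tr[, x$control_assay_id]
  if (anyNA(ctrl))
    stop("control assay undetected in sample '",
         rownames(x$ct)[which(is.na(ctrl))[1L]], "'")
  keep <- setdiff(colnames(x$ct), x$control_assay_id)
  d <- tr[, keep, drop = FALSE] - ctrl
  list(delta_ct = d, censored = cens[, keep, drop = FALSE],
       group_labels = x$group_labels, control_ct = ctrl)
}

#' Fold change from group-mean delta-CT values
#'
#' The comparative-CT fold change: with the reference-group mean delta-CT as
#' calibrator, delta-delta-CT = mean_case - mean_ref and the relative
#' expression of the case group is `2^-(mean_case - mean_ref)`.  Values
#' above 1 indicate upregulation in the case group (lower delta-CT = more
#' template).
#'
#' @param mean_delta_ct_case,mean_delta_ct_ref group-mean delta-CT values
#'   (cycles); vectorized.
#' @return Fold change (dimensionless, positive).
#' @examples
#' fold_change(7.06, 9.54)  # 5.58-fold up in the case group
#' @export
fold_change <- function(mean_delta_ct_case, mean_delta_ct_ref) {
  2^-(mean_delta_ct_case - mean_delta_ct_ref)
}

#' Differential miRNA expression by the comparative-CT method
#'
#' Runs the full per-assay quantification: CT truncation at the detection
#' limit, per-sample delta-CT normalization to the endogenous control,
#' two-sided t-test between case and reference delta-CT values, Storey
#' q-values across the tested assays, comparative-CT fold changes, and the
#' reporting filters:
#' \itemize{
#'   \item `excluded`: the assay amplified in no sample at all;
#'   \item `up`: q-value below `mir_q_max`, fold change above 1, and at most
#'     `mir_detect_fail_max` censored (CT above limit) wells in the case
#'     group — heavily censored assays are never reported as upregulated
#'     however small their q;
#'   \item `down`: nominal p below `downreg_p_max` and fold change below 1
#'     (this looser rule only feeds the miR-target side of the integrated
#'     analysis);
#'   \item `ns`: everything else.
#' }
#' Assays with fewer than two usable wells in either group are flagged
#' `testable = FALSE` (p and q are `NA`, call stays `ns`) rather than
#' silently dropped.
#'
#' @param x a [ct_table()].
#' @param config a [meso_config()].
#' @return An object of class `mir_de` with a `table` data frame (one row
#'   per non-control assay, columns `assay`, `mean_delta_ct_case`,
#'   `mean_delta_ct_ref`, `fold_change`, `p_value`, `q_value`, `call`,
#'   `sd_delta_ct_case`, `sd_delta_ct_ref`, `delta_delta_ct`,
#'   `n_censored_case`, `n_censored_ref`, `n_detected_total`, `testable`),
#'   plus `pi0`, `config`, and the `delta_ct` normalization.
#' @export
mir_differential <- function(x, config = meso_config()) {
  stopifnot(inherits(x, "ct_table"))
  dct <- delta_ct(x, config$ct_max)
  g <- .group_split(dct$group_labels, config)
  d <- dct$delta_ct
  assays <- colnames(d)
  n_assay <- length(assays)

  raw <- x$ct[, assays, drop = FALSE]
  n_detected <- colSums(!is.na(raw))
  n_cens_case <- colSums(dct$censored[g$case, , drop = FALSE] &
                           !is.na(raw[g$case, , drop = FALSE]))
  n_cens_ref <- colSums(dct$censored[g$ref, , drop = FALSE] &
                          !is.na(raw[g$ref, , drop = FALSE]))

  mean_case <- colMeans(d[g$case, , drop = FALSE], na.rm = TRUE)
  mean_ref <- colMeans(d[g$ref, , drop = FALSE], na.rm = TRUE)
  sd_case <- apply(d[g$case, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  sd_ref <- apply(d[g$ref, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)

  usable_case <- colSums(!is.na(d[g$case, , drop = FALSE]))
  usable_ref <- colSums(!is.na(d[g$ref, , drop = FALSE]))
  excluded <- n_detected == 0L
  testable <- !excluded & usable_case >= 2L & usable_ref >= 2L

  p <- rep(NA_real_, n_assay)
  for (i in which(testable)) {
    xc <- d[g$case, i]; xr <- d[g$ref, i]
    xc <- xc[!is.na(xc)]; xr <- xr[!is.na(xr)]
    if (stats::sd(xc) == 0 && stats::sd(xr) == 0) {
      # degenerate zero-variance assay: no evidence if the constants agree,
      # an infinite t-statistic (p -> 0) if they differ
      p[i] <- as.numeric(mean(xc) == mean(xr))
    } else {
      p[i] <- stats::t.test(xc, xr, var.equal = !config$welch)$p.value
    }
  }

  q <- rep(NA_real_, n_assay)
  pi0 <- NA_real_
  if (any(testable)) {
    qf <- qvalues(p[testable])
    q[testable] <- qf$q_values
    pi0 <- qf$pi0
  }

  ddct <- mean_case - mean_ref
  fc <- fold_change(mean_case, mean_ref)

  call <- rep("ns", n_assay)
  call[testable & q < config$mir_q_max & fc > 1 &
         n_cens_case <= config$mir_detect_fail_max] <- "up"
  call[testable & call == "ns" & p < config$downreg_p_max & fc < 1] <- "down"
  call[excluded] <- "excluded"
  fc[excluded] <- NA_real_
  ddct[excluded] <- NA_real_

  tab <- data.frame(
    assay = assays,
    mean_delta_ct_case = unname(mean_case),
    mean_delta_ct_ref = unname(mean_ref),
    fold_change = unname(fc),
    p_value = p, q_value = q, call = call,
    sd_delta_ct_case = unname(sd_case), sd_delta_ct_ref = unname(sd_ref),
    delta_delta_ct = unname(ddct),
    n_censored_case = unname(n_cens_case),
    n_censored_ref = unname(n_cens_ref),
    n_detected_total = unname(n_detected),
    testable = unname(testable),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(table = tab, pi0 = pi0, delta_ct = dct, config = config),
            class = "mir_de")
}

#' @export
print.mir_de <- function(x, ...) {
  tab <- x$table
  cat("Differential miRNA expression (comparative CT): ", nrow(tab),
      " assays\n", sep = "")
  cat("  calls: up=", sum(tab$call == "up"), ", down=",
      sum(tab$call == "down"), ", ns=", sum(tab$call == "ns"),
      ", excluded=", sum(tab$call == "excluded"), "\n", sep = "")
  if (!is.na(x$pi0)) cat("  pi0 = ", signif(x$pi0, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mir_de <- function(object, ...) {
  tab <- object$table
  up <- tab[tab$call == "up", ]
  up <- up[order(up$q_value, -up$fold_change), ]
  cat("Upregulated miRNAs (q < ", object$config$mir_q_max, "):\n", sep = "")
  if (nrow(up)) {
    print(up[, c("assay", "mean_delta_ct_case", "mean_delta_ct_ref",
                 "fold_change", "q_value")],
          row.names = FALSE, digits = 4)
  } else cat("  none\n")
  down <- tab[tab$call == "down", ]
  cat("Downregulated miRNAs (P < ", object$config$downreg_p_max, "): ",
      if (nrow(down)) paste(down$assay, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(object)
}
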