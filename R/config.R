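#' Analysis configuration
#'
#' Bundles every threshold the pipeline applies, so that the reporting rules
#' are explicit and the same object can drive all stages.  Defaults are the
#' study conditions: CT detection limit 35 cycles, miR reporting at q < 0.05
#' with at most 3 censored case samples, mRNA reporting at q < 0.01 above a
#' 3.5 log2 expression floor, integration feeding list at SNR > 0.2 and
#' nominal P < 0.01, downregulated-miR rule at nominal P < 0.05, and MGSA
#' pathway selection at posterior estimate >= 0.4.
#'
#' @param ct_max CT detection limit (cycles); values above are truncated.
#' @param mir_q_max q-value cutoff for calling a miR upregulated.
#' @param mir_detect_fail_max maximum number of censored (CT > `ct_max`)
#'   case-group wells tolerated for an "up" call.
#' @param mrna_q_max q-value cutoff for reporting an overexpressed probeset.
#' @param mrna_mean_floor minimum case-group mean log2 intensity for
#'   reporting.
#' @param integration_snr_min,integration_p_max SNR and nominal-P cutoffs
#'   selecting probesets fed into the integrated pathway analysis.
#' @param downreg_p_max nominal-P cutoff for calling a miR downregulated
#'   (feeds target collection).
#' @param mgsa_estimate_min posterior activation threshold for selecting a
#'   pathway.
#' @param case_label,ref_label group labels treated as case and reference.
#' @param welch use Welch's t-test instead of the classical pooled-variance
#'   Student t-test.
#' @param intersection_rule which overexpression rule defines the
#'   overexpressed-gene / miR-target intersection table:
#'   `"integration_selected"` (SNR/nominal-P feeding list, default) or
#'   `"reported_up"`.
#' @return A list of class `meso_config`.
#' @export
meso_config <- function(ct_max = 35, mir_q_max = 0.05,
                        mir_detect_fail_max = 3, mrna_q_max = 0.01,
                        mrna_mean_floor = 3.5, integration_snr_min = 0.2,
                        integration_p_max = 0.01, downreg_p_max = 0.05,
                        mgsa_estimate_min = 0.4,
                        case_label = "MPM", ref_label = "BAPE",
                        welch = FALSE,
                        intersection_rule = c("integration_selected",
                                              "reported_up")) {
  intersection_rule <- match.arg(intersection_rule)
  cfg <- list(ct_max = ct_max, mir_q_max = mir_q_max,
              mir_detect_fail_max = mir_detect_fail_max,
              mrna_q_max = mrna_q_max, mrna_mean_floor = mrna_mean_floor,
              integration_snr_min = integration_snr_min,
              integration_p_max = integration_p_max,
              downreg_p_max = downreg_p_max,
              mgsa_estimate_min = mgsa_estimate_min,
              case_label = case_label, ref_label = ref_label,
              welch = isTRUE(welch), intersection_rule = intersection_rule)
  num <- unlist(cfg[1:9])
  if (any(!is.finite(num))) stop("all thresholds must be finite")
  class(cfg) <- "meso_config"
  cfg
}

#' @export
print.meso_config <- function(x, ...) {
  cat("Analysis configuration (case='", x$case_label, "' vs ref='",
      x$ref_label, "'):\n", sep = "")
  cat("  CT limit ", x$ct_max, "; miR up: q<", x$mir_q_max, ", <=",
      x$mir_detect_fail_max, " censored case wells; miR down: P<",
      x$downreg_p_max, "\n", sep = "")
  cat("  mRNA report: q<", x$mrna_q_max, ", case mean>", x$mrna_mean_floor,
      "; integration: SNR>", x$integration_snr_min, " & P<",
      x$integration_p_max, "\n", sep = "")
  cat("  MGSA selection: estimate>=", x$mgsa_estimate_min,
      "; t-test: ", if (x$welch) "Welch" else "Student (pooled)", "\n",
      sep = "")
  invisible(x)
}

# split sample indices into case / reference using config labels;
# labels not matching either config label are an error.
.group_split <- function(labels, config) {
  lev <- unique(labels)
  if (!config$case_label %in% lev || !config$ref_label %in% lev) {
    # arbitrary binary labels: fall back to declared order if exactly two
    if (length(lev) == 2L)
      stop("group labels (", paste(lev, collapse = ", "),
           ") do not match config case='", config$case_label, "'/ref='",
           config$ref_label, "'; set case_label/ref_label in meso_config()")
    stop("expected exactly two group labels")
  }
  list(case = which(labels == config$case_label),
       ref = which(labels == config$ref_label))
}
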