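#' Simulation parameters for the two-group study design
#'
#' Defaults emulate an unbalanced case/reference pleural cohort: 18 case
#' (MPM) vs 6 reference (BAPE) samples; a 96-assay miRNA qPCR panel with 11
#' planted upregulated and 5 planted downregulated assays, Gaussian CT noise
#' and a 35-cycle detection limit; a 2000-probeset log2 expression matrix in
#' the [2, 15] range with 40 planted overexpressed probesets (log2 effect
#' 3.5); and gene-set collections with one planted active pathway at 80%
#' enrichment.
#'
#' @param n_case,n_ref group sizes.
#' @param n_mirs number of miRNA assays (control excluded).
#' @param n_up_mirs,n_down_mirs planted up/downregulated assay counts.
#' @param control_ct_mean,control_ct_sd endogenous-control CT distribution
#'   (cycles).
#' @param ct_noise_sd per-well CT noise (cycles).
#' @param effect_shift_ct planted shift magnitude (cycles): upregulated
#'   assays are shifted by `-effect_shift_ct` in the case group,
#'   downregulated ones by `+effect_shift_ct`.
#' @param ct_baseline_range range of per-assay baseline mean CT (cycles);
#'   down-shifted assays can exceed the detection limit, exercising
#'   censoring.
#' @param censor_limit detection limit (cycles); used downstream, raw
#'   simulated values are not truncated.
#' @param missing_fraction fraction of wells set to undetermined.
#' @param n_probesets,n_de expression matrix size and number of planted
#'   overexpressed probesets.
#' @param log2_effect planted case-group elevation (log2 units, must be
#'   >= 0: the generator plants overexpression only).
#' @param expr_noise_sd per-observation expression noise (log2 units).
#' @param baseline_log2_range range of probeset baseline means.
#' @param de_baseline_range baseline range for planted probesets (kept low
#'   so the elevated case mean stays inside `baseline_log2_range`).
#' @param n_genes size of the gene-symbol pool (smaller than `n_probesets`
#'   so some symbols recur across probesets).
#' @param na_symbol_fraction fraction of probesets with no annotation.
#' @param n_pathways,n_active_pathways pathway collection size and planted
#'   active count.
#' @param pathway_size_range pathway sizes (genes).
#' @param enrichment_fraction fraction of an active pathway drawn from
#'   planted signal genes.
#' @param targets_per_mir size of each downregulated miR's target set.
#' @param planted_targets_per_mir planted overexpressed genes included in
#'   each downregulated miR's target set (makes the
#'   overexpressed-and-targeted intersection non-empty by construction).
#' @param seed integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_case = 18L, n_ref = 6L,
                       n_mirs = 96L, n_up_mirs = 11L, n_down_mirs = 5L,
                       control_ct_mean = 20, control_ct_sd = 0.25,
                       ct_noise_sd = 0.5, effect_shift_ct = 3,
                       ct_baseline_range = c(24, 33),
                       censor_limit = 35, missing_fraction = 0.01,
                       n_probesets = 2000L, n_de = 40L,
                       log2_effect = 3.5, expr_noise_sd = 0.7,
                       baseline_log2_range = c(2, 15),
                       de_baseline_range = c(3, 4.5),
                       n_genes = 1600L, na_symbol_fraction = 0.15,
                       n_pathways = 10L, n_active_pathways = 1L,
                       pathway_size_range = c(20, 60),
                       enrichment_fraction = 0.8,
                       targets_per_mir = 100L,
                       planted_targets_per_mir = 3L,
                       seed = 1L) {
  p <- as.list(environment())
  counts <- c(p$n_case, p$n_ref, p$n_mirs, p$n_probesets, p$n_genes,
              p$n_pathways)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (p$n_case + p$n_ref < 3L)
    stop("fewer than 3 samples: group comparisons are undefined")
  if (p$log2_effect < 0)
    stop("'log2_effect' must be >= 0: the generator plants overexpression only")
  if (p$censor_limit <= 0) stop("'censor_limit' must be positive")
  if (!is.finite(p$effect_shift_ct)) stop("effect sizes must be finite")
  if (p$n_up_mirs + p$n_down_mirs > p$n_mirs)
    stop("more planted miRs than assays")
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters: ", x$n_case, " case vs ", x$n_ref,
      " reference samples\n",
      "  miRNA panel: ", x$n_mirs, " assays (", x$n_up_mirs, " up / ",
      x$n_down_mirs, " down planted, shift ", x$effect_shift_ct,
      " cycles, noise sd ", x$ct_noise_sd, ")\n",
      "  expression: ", x$n_probesets, " probesets (", x$n_de,
      " planted, log2 effect ", x$log2_effect, ", noise sd ",
      x$expr_noise_sd, ")\n",
      "  pathways: ", x$n_pathways, " (", x$n_active_pathways,
      " active, ", 100 * x$enrichment_fraction, "% enriched)\n", sep = "")
  invisible(x)
}

.sim_gene_pool <- function(params) {
  sprintf("GENE%04d", seq_len(params$n_genes))
}

#' Simulate a CT table with planted differential miRNAs
#'
#' Draws per-well CT values: a per-assay baseline mean (uniform over
#' `ct_baseline_range`), Gaussian per-well noise, a tightly controlled
#' endogenous-control assay, and group shifts of `-effect_shift_ct`
#' (upregulated: case amplifies earlier) or `+effect_shift_ct`
#' (downregulated) cycles in the case group for the planted assays.  Raw
#' values above the detection limit are left untruncated — truncation is the
#' analysis's job — and a small fraction of wells is set undetermined.
#'
#' @param params a [sim_params()].
#' @return A list with `table` (a [ct_table()]) and `truth` (list with
#'   `upregulated_mirs`, `downregulated_mirs`).
#' @export
simulate_ct_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_case + params$n_ref
  groups <- c(rep("MPM", params$n_case), rep("BAPE", params$n_ref))
  assays <- sprintf("miR-%03d", seq_len(params$n_mirs))
  shift <- if (params$effect_shift_ct == 0) 0L else
    params$n_up_mirs + params$n_down_mirs
  up <- if (params$effect_shift_ct == 0) character(0) else
    assays[seq_len(params$n_up_mirs)]
  down <- if (params$effect_shift_ct == 0) character(0) else
    assays[params$n_up_mirs + seq_len(params$n_down_mirs)]

  baseline <- stats::runif(params$n_mirs, params$ct_baseline_range[1L],
                           params$ct_baseline_range[2L])
  ct <- matrix(stats::rnorm(n * params$n_mirs,
                            mean = rep(baseline, each = n),
                            sd = params$ct_noise_sd),
               nrow = n, dimnames = list(
                 sprintf("S%02d", seq_len(n)), assays))
  case_idx <- seq_len(params$n_case)
  ct[case_idx, up] <- ct[case_idx, up] - params$effect_shift_ct
  ct[case_idx, down] <- ct[case_idx, down] + params$effect_shift_ct
  ct[ct <= 0.5] <- 0.5  # CT is a positive cycle count

  if (params$missing_fraction > 0) {
    nmiss <- round(params$missing_fraction * length(ct))
    if (nmiss > 0) ct[sample(length(ct), nmiss)] <- NA
  }
  ctrl <- stats::rnorm(n, params$control_ct_mean, params$control_ct_sd)
  ct <- cbind(U6 = ctrl, ct)

  list(table = ct_table(ct, group_labels = groups, control_assay_id = "U6"),
       truth = list(upregulated_mirs = up, downregulated_mirs = down))
}

#' Simulate a log2 expression matrix with planted overexpression
#'
#' Per-probeset baseline means are uniform over `baseline_log2_range`;
#' planted probesets start from a low baseline (`de_baseline_range`) and are
#' elevated by `log2_effect` in the case group.  Observations get Gaussian
#' noise and are clamped to stay within the plausible normalized-intensity
#' range.  Gene symbols are drawn from a pool smaller than the probeset
#' count (so symbols can recur) and a configurable fraction is `NA`.
#'
#' @param params a [sim_params()].
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`
#'   (list with `de_probesets` and `de_genes`).
#' @export
simulate_expression_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  n <- params$n_case + params$n_ref
  groups <- c(rep("MPM", params$n_case), rep("BAPE", params$n_ref))
  ids <- sprintf("PS%05d_at", seq_len(params$n_probesets))
  n_de <- if (params$log2_effect == 0) 0L else params$n_de
  de <- if (n_de > 0) ids[seq_len(n_de)] else character(0)

  baseline <- stats::runif(params$n_probesets,
                           params$baseline_log2_range[1L],
                           params$baseline_log2_range[2L])
  if (n_de > 0)
    baseline[seq_len(n_de)] <- stats::runif(n_de,
                                            params$de_baseline_range[1L],
                                            params$de_baseline_range[2L])
  m <- matrix(stats::rnorm(params$n_probesets * n,
                           mean = baseline, sd = params$expr_noise_sd),
              nrow = params$n_probesets,
              dimnames = list(ids, sprintf("S%02d", seq_len(n))))
  if (n_de > 0)
    m[seq_len(n_de), seq_len(params$n_case)] <-
      m[seq_len(n_de), seq_len(params$n_case)] + params$log2_effect
  rng <- params$baseline_log2_range
  m[m < rng[1L]] <- rng[1L]
  m[m > rng[2L]] <- rng[2L]

  pool <- .sim_gene_pool(params)
  sym <- sample(pool, params$n_probesets, replace = TRUE)
  sym[sample(params$n_probesets,
             round(params$na_symbol_fraction * params$n_probesets))] <- NA
  # planted probesets keep distinct, annotated symbols so truth is clean
  if (n_de > 0) sym[seq_len(n_de)] <- pool[seq_len(n_de)]

  em <- expression_matrix(m, group_labels = groups, gene_symbol = sym)
  list(matrix = em,
       truth = list(de_probesets = de,
                    de_genes = unique(sym[seq_len(n_de)])))
}

#' Simulate pathway and miR-target gene-set collections
#'
#' Builds a canonical-pathway collection in which `n_active_pathways` sets
#' are enriched (a configurable fraction of their members drawn from the
#' planted signal genes) while the rest are uniform draws from the gene
#' universe, plus a miR-target collection with one target set per planted
#' downregulated miRNA, each seeded with a few planted overexpressed genes
#' so the overexpressed-and-targeted intersection is non-empty by
#' construction.
#'
#' @param params a [sim_params()].
#' @param truth combined truth list carrying `de_genes` and
#'   `downregulated_mirs` (from the two generators above).
#' @return A list with `pathways`, `mir_targets` (both
#'   [gene_set_collection()]) and `truth` extended with `active_pathways`
#'   and `target_links`.
#' @export
simulate_gene_sets <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 2L)
  pool <- .sim_gene_pool(params)
  signal <- truth$de_genes
  sizes <- sample(params$pathway_size_range[1L]:params$pathway_size_range[2L],
                  params$n_pathways, replace = TRUE)
  if (max(sizes) > length(pool))
    stop("pathway size exceeds the gene universe")
  active <- if (params$n_active_pathways > 0 && length(signal))
    sprintf("PATHWAY_%02d", seq_len(params$n_active_pathways)) else character(0)
  sets <- lapply(seq_len(params$n_pathways), function(i) {
    size <- sizes[i]
    if (i <= length(active)) {
      n_sig <- min(round(params$enrichment_fraction * size), length(signal))
      c(sample(signal, n_sig),
        sample(setdiff(pool, signal), size - n_sig))
    } else {
      sample(pool, size)
    }
  })
  names(sets) <- sprintf("PATHWAY_%02d", seq_len(params$n_pathways))
  pathways <- gene_set_collection(sets, kind = "pathway")

  down <- truth$downregulated_mirs
  tsets <- list()
  links <- list()
  if (length(down)) {
    for (mir in down) {
      planted <- sample(signal, min(params$planted_targets_per_mir,
                                    length(signal)))
      rest <- sample(setdiff(pool, planted),
                     max(params$targets_per_mir - length(planted), 0L))
      tsets[[mir]] <- c(planted, rest)
      links[[mir]] <- planted
    }
  }
  mir_targets <- gene_set_collection(tsets, kind = "mir_target")
  truth$active_pathways <- active
  truth$target_links <- links
  list(pathways = pathways, mir_targets = mir_targets, truth = truth)
}

#' Simulate a complete linked study
#'
#' Convenience wrapper running [simulate_ct_dataset()],
#' [simulate_expression_dataset()] and [simulate_gene_sets()] with one
#' shared parameter set, returning all inputs the integrated pipeline needs
#' together with the combined ground truth.
#'
#' @param params a [sim_params()].
#' @return A list with `ct`, `expr`, `pathways`, `mir_targets`, `truth`.
#' @export
simulate_study <- function(params = sim_params()) {
  a <- simulate_ct_dataset(params)
  b <- simulate_expression_dataset(params)
  truth <- c(a$truth, b$truth)
  g <- simulate_gene_sets(params, truth)
  list(ct = a$table, expr = b$matrix, pathways = g$pathways,
       mir_targets = g$mir_targets, truth = g$truth)
}
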