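#' Union of target genes of downregulated miRNAs
#'
#' Collects the target sets of every miRNA called `down` by
#' [mir_differential()] and returns their deduplicated union.  Assay names
#' and target-set names are matched after [normalize_mir_name()]
#' normalization; downregulated miRNAs without a target set are counted in
#' the `"n_without_targets"` attribute.
#'
#' @param mir_de a fitted [mir_differential()] object.
#' @param targets a miR-target [gene_set_collection()].
#' @return Character vector of target gene symbols (possibly empty) with
#'   attributes `"down_mirs"` and `"n_without_targets"`.
#' @export
collect_mir_targets <- function(mir_de, targets) {
  stopifnot(inherits(mir_de, "mir_de"),
            inherits(targets, "gene_set_collection"))
  down <- mir_de$table$assay[mir_de$table$call == "down"]
  key <- normalize_mir_name(names(targets$sets))
  hit <- match(normalize_mir_name(down), key)
  genes <- unique(unlist(targets$sets[hit[!is.na(hit)]], use.names = FALSE))
  if (is.null(genes)) genes <- character(0)
  attr(genes, "down_mirs") <- down
  attr(genes, "n_without_targets") <- sum(is.na(hit))
  genes
}

#' Combined study gene set for pathway analysis
#'
#' The study set is the union of overexpressed genes and targets of
#' downregulated miRNAs, restricted to the population (the universe of
#' genes covered by the pathway collection).  The number of combined genes
#' that mapped into the population is reported.
#'
#' @param up_genes character vector of overexpressed gene symbols.
#' @param mir_target_genes character vector of downregulated-miR target
#'   symbols.
#' @param population gene universe (union of pathway members).
#' @return Character vector (the study set) with attribute
#'   `"mapped_count"`.
#' @export
build_study_set <- function(up_genes, mir_target_genes, population) {
  if (!length(population)) stop("empty population")
  combined <- unique(c(up_genes, mir_target_genes))
  study <- intersect(combined, population)
  attr(study, "mapped_count") <- length(study)
  study
}

#' Integrated miRNA-mRNA pathway analysis
#'
#' The full integration stage: collect targets of downregulated miRNAs,
#' combine them with the overexpressed genes into a study set, score every
#' canonical pathway with [mgsa()], tabulate per-pathway gene counts,
#' build the overexpressed-and-targeted gene intersection table, and list
#' genes recurring across the selected pathways.
#'
#' @param mir_de a fitted [mir_differential()] object.
#' @param mrna_de a fitted [mrna_differential()] object.
#' @param pathways canonical-pathway [gene_set_collection()]; its member
#'   union defines the population.
#' @param targets miR-target [gene_set_collection()].
#' @param config a [meso_config()]; `intersection_rule` picks which
#'   overexpression rule feeds the intersection table.
#' @param ... passed to [mgsa()] (hyperparameters, method, `n_steps`,
#'   `seed`).
#' @return An object of class `meso_integration` with components:
#'   \describe{
#'     \item{table}{per-pathway data frame: `pathway`, `in_population`,
#'       `in_study_set`, `estimate`, `n_mrna` (overexpressed genes in the
#'       pathway), `n_mir_target` (down-miR targets in the pathway),
#'       `n_both`, `selected`; sorted by descending estimate.}
#'     \item{intersection}{genes overexpressed and targeted by >= 1
#'       downregulated miRNA: per-miRNA membership flags, representative
#'       probeset (max |SNR| per symbol), p, fold change; sorted by
#'       descending fold change.}
#'     \item{multi_pathway_genes}{genes in more than one selected pathway.}
#'     \item{mgsa}{the underlying [mgsa()] fit.}
#'   }
#' @export
integrate_mir_mrna <- function(mir_de, mrna_de, pathways, targets,
                               config = meso_config(), ...) {
  stopifnot(inherits(mir_de, "mir_de"), inherits(mrna_de, "mrna_de"),
            inherits(pathways, "gene_set_collection"))
  population <- sort(unique(unlist(pathways$sets, use.names = FALSE)))
  up_genes <- unique_gene_list(mrna_de, "integration_selected")
  target_genes <- collect_mir_targets(mir_de, targets)
  study <- build_study_set(up_genes, target_genes, population)

  fit <- mgsa(pathways, study_set = study, population = population, ...)

  up_in_pop <- intersect(up_genes, population)
  tg_in_pop <- intersect(target_genes, population)
  tab <- fit$table
  n_mrna <- vapply(pathways$sets, function(s) sum(s %in% up_in_pop),
                   integer(1L))
  n_tgt <- vapply(pathways$sets, function(s) sum(s %in% tg_in_pop),
                  integer(1L))
  n_both <- vapply(pathways$sets,
                   function(s) sum(s %in% up_in_pop & s %in% tg_in_pop),
                   integer(1L))
  out <- data.frame(pathway = tab$set, in_population = tab$in_population,
                    in_study_set = tab$in_study_set, estimate = tab$estimate,
                    n_mrna = unname(n_mrna), n_mir_target = unname(n_tgt),
                    n_both = unname(n_both),
                    selected = tab$estimate >= config$mgsa_estimate_min,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$estimate), ]
  rownames(out) <- NULL

  inter <- intersect_overexpressed_targets(mrna_de, mir_de, targets, config)
  mp <- multi_pathway_genes(out, pathways)

  structure(list(table = out, intersection = inter,
                 multi_pathway_genes = mp, mgsa = fit,
                 study_set = study, up_genes = up_genes,
                 target_genes = target_genes, config = config),
            class = "meso_integration")
}

#' Overexpressed genes that are targets of downregulated miRNAs
#'
#' Cross-references the overexpressed genes (by the configured rule) with
#' the target sets of downregulated miRNAs.  Probeset-level results are
#' collapsed to one representative probeset per symbol (maximum |SNR|); one
#' logical column per downregulated miRNA flags target membership.  Rows
#' are sorted by descending fold change.
#'
#' @param mrna_de a fitted [mrna_differential()] object.
#' @param mir_de a fitted [mir_differential()] object.
#' @param targets a miR-target [gene_set_collection()].
#' @param config a [meso_config()].
#' @return Data frame with columns `gene`, one `target_<miR>` flag per
#'   downregulated miRNA, `probeset_id`, `p_value`, `fold_change`.
#' @export
intersect_overexpressed_targets <- function(mrna_de, mir_de, targets,
                                            config = meso_config()) {
  stopifnot(inherits(mrna_de, "mrna_de"), inherits(mir_de, "mir_de"))
  rule <- config$intersection_rule
  tab <- mrna_de$table[mrna_de$table[[rule]] & !is.na(mrna_de$table$gene_symbol), ]
  down <- mir_de$table$assay[mir_de$table$call == "down"]
  key <- normalize_mir_name(names(targets$sets))
  tsets <- lapply(down, function(m) {
    i <- match(normalize_mir_name(m), key)
    if (is.na(i)) character(0) else targets$sets[[i]]
  })
  names(tsets) <- down
  targeted <- unique(unlist(tsets, use.names = FALSE))
  tab <- tab[tab$gene_symbol %in% targeted, ]
  if (!nrow(tab)) {
    out <- data.frame(gene = character(0), probeset_id = character(0),
                      p_value = numeric(0), fold_change = numeric(0),
                      stringsAsFactors = FALSE)
    for (m in down) out[[sprintf("target_%s", m)]] <- logical(0)
    return(out[c("gene", sprintf("target_%s", down),
                 "probeset_id", "p_value", "fold_change")])
  }
  # one representative probeset per symbol: maximum |SNR|
  tab <- tab[order(-abs(tab$snr)), ]
  tab <- tab[!duplicated(tab$gene_symbol), ]
  out <- data.frame(gene = tab$gene_symbol, stringsAsFactors = FALSE)
  for (m in down)
    out[[paste0("target_", m)]] <- out$gene %in% tsets[[m]]
  out$probeset_id <- tab$probeset_id
  out$p_value <- tab$p_value
  out$fold_change <- tab$fold_change
  out <- out[order(-out$fold_change), ]
  rownames(out) <- NULL
  out
}

#' Genes recurring across selected pathways
#'
#' @param result the per-pathway table of a [integrate_mir_mrna()] fit (or
#'   the fit itself).
#' @param pathways the canonical-pathway [gene_set_collection()] the table
#'   was scored against.
#' @param min_pathways minimum number of selected pathways a gene must
#'   appear in (default 2).
#' @return Named integer vector (gene -> pathway count), sorted
#'   descending.
#' @export
multi_pathway_genes <- function(result, pathways, min_pathways = 2L) {
  if (inherits(result, "meso_integration")) result <- result$table
  sel <- result$pathway[result$selected]
  if (!length(sel)) return(integer(0))
  members <- unlist(pathways$sets[sel], use.names = FALSE)
  counts <- table(members)
  counts <- counts[counts >= min_pathways]
  sort(stats::setNames(as.integer(counts), names(counts)),
       decreasing = TRUE)
}

#' @export
print.meso_integration <- function(x, ...) {
  cat("Integrated miRNA-mRNA pathway analysis\n",
      "  study set: ", length(x$study_set), " genes (",
      length(x$up_genes), " overexpressed + ",
      length(x$target_genes), " miR targets, mapped to population)\n",
      "  selected pathways (estimate >= ", x$config$mgsa_estimate_min,
      "): ", sum(x$table$selected), " of ", nrow(x$table), "\n", sep = "")
  print(utils::head(x$table, 10L), row.names = FALSE, digits = 3)
  cat("Overexpressed-and-targeted genes: ", nrow(x$intersection), "\n",
      sep = "")
  invisible(x)
}
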