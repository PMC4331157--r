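make_small_study <- function(seed = 1L, ...) {
  simulate_study(sim_params(n_probesets = 400L, n_de = 20L, n_genes = 600L,
                            targets_per_mir = 40L, seed = seed, ...))
}

fit_pipeline <- function(sim, n_steps = 5e4, seed = 1L) {
  md <- mir_differential(sim$ct)
  ed <- mrna_differential(sim$expr)
  integrate_mir_mrna(md, ed, sim$pathways, sim$mir_targets,
                     n_steps = n_steps, seed = seed)
}

test_that("collect_mir_targets unions and deduplicates down-miR targets", {
  sim <- make_small_study(seed = 31L)
  md <- mir_differential(sim$ct)
  genes <- collect_mir_targets(md, sim$mir_targets)
  down <- md$table$assay[md$table$call == "down"]
  manual <- unique(unlist(sim$mir_targets$sets[down], use.names = FALSE))
  expect_setequal(as.character(genes), manual)
  expect_true(all(sim$truth$downregulated_mirs %in% down))

  # no down calls -> empty union
  cfg <- meso_config(downreg_p_max = 0)
  md0 <- mir_differential(sim$ct, cfg)
  expect_length(collect_mir_targets(md0, sim$mir_targets), 0)
})

test_that("build_study_set intersects with the population and counts mapping", {
  s <- build_study_set("A", "B", population = c("A", "C"))
  expect_equal(as.character(s), "A")
  expect_equal(attr(s, "mapped_count"), 1L)
  s <- build_study_set(c("A", "B"), c("C", "D"), population = LETTERS[1:4])
  expect_length(s, 4L)
  expect_error(build_study_set("A", "B", character(0)), "population")
  set.seed(32)
  for (r in 1:20) {
    up <- sample(LETTERS, 5); tg <- sample(LETTERS, 8)
    pop <- sample(LETTERS, 12)
    s <- build_study_set(up, tg, pop)
    expect_lte(attr(s, "mapped_count"), length(unique(c(up, tg))))
  }
})

test_that("per-pathway count identities hold on random and synthetic runs", {
  for (s in c(33L, 34L)) {
    sim <- make_small_study(seed = s)
    fit <- fit_pipeline(sim, seed = s)
    tab <- fit$table
    expect_true(all(tab$n_both <= pmin(tab$n_mrna, tab$n_mir_target)))
    expect_true(all(tab$in_study_set <= tab$in_population))
    expect_true(all(tab$n_mrna + tab$n_mir_target - tab$n_both <=
                      tab$in_study_set))
    expect_true(all(diff(tab$estimate) <= 1e-12))  # Table-4 style ordering
  }
})

test_that("a pathway disjoint from the study set carries zero counts", {
  sim <- make_small_study(seed = 35L)
  md <- mir_differential(sim$ct)
  ed <- mrna_differential(sim$expr)
  # add a pathway of genes certain to be outside the study set
  extra <- gene_set_collection(
    c(sim$pathways$sets, list(DISJOINT = paste0("XZ", 1:15))),
    kind = "pathway")
  fit <- integrate_mir_mrna(md, ed, extra, sim$mir_targets,
                            n_steps = 3e4, seed = 35L)
  row <- fit$table[fit$table$pathway == "DISJOINT", ]
  expect_equal(row$in_study_set, 0L)
  expect_equal(row$n_mrna + row$n_mir_target + row$n_both, 0L)
})

test_that("the intersection table equals the planted truth on synthetic data", {
  sim <- make_small_study(seed = 36L)
  fit <- fit_pipeline(sim, seed = 36L)
  inter <- fit$intersection
  # oracle: overexpressed genes (selection rule) that any down-miR targets
  md <- mir_differential(sim$ct)
  ed <- mrna_differential(sim$expr)
  up <- unique_gene_list(ed, "integration_selected")
  down <- md$table$assay[md$table$call == "down"]
  targeted <- unique(unlist(sim$mir_targets$sets[down], use.names = FALSE))
  expect_setequal(inter$gene, intersect(up, targeted))
  # planted links are all recovered (targets seeded from planted DE genes)
  planted <- intersect(unique(unlist(sim$truth$target_links)),
                       sim$truth$de_genes)
  expect_true(all(planted %in% inter$gene))
  # rows sorted by fold change, flags reproduce set membership
  expect_true(all(diff(inter$fold_change) <= 1e-12))
  for (m in down) {
    flag <- inter[[paste0("target_", m)]]
    expect_equal(flag, inter$gene %in% sim$mir_targets$sets[[m]])
  }
})

test_that("an overexpressed but untargeted gene is absent from the table", {
  sim <- make_small_study(seed = 37L)
  md <- mir_differential(sim$ct)
  ed <- mrna_differential(sim$expr)
  inter <- intersect_overexpressed_targets(ed, md, sim$mir_targets)
  up <- unique_gene_list(ed, "integration_selected")
  down <- md$table$assay[md$table$call == "down"]
  targeted <- unique(unlist(sim$mir_targets$sets[down], use.names = FALSE))
  untargeted <- setdiff(up, targeted)
  expect_gt(length(untargeted), 0)
  expect_false(any(untargeted %in% inter$gene))
})

test_that("multi-pathway gene counts equal a brute-force recount", {
  sim <- make_small_study(seed = 38L, n_active_pathways = 3L)
  fit <- fit_pipeline(sim, seed = 38L)
  mp <- multi_pathway_genes(fit, sim$pathways)
  sel <- fit$table$pathway[fit$table$selected]
  pool <- unique(unlist(sim$pathways$sets[sel], use.names = FALSE))
  manual <- vapply(pool, function(g)
    sum(vapply(sim$pathways$sets[sel], function(s) g %in% s, logical(1L))),
    integer(1L))
  manual <- manual[manual >= 2]
  expect_setequal(names(mp), names(manual))
  expect_equal(mp[names(manual)], manual[names(manual)])
  # a gene in exactly one selected pathway is excluded
  singles <- names(manual)[manual == 1]
  expect_false(any(singles %in% names(mp)))
})

test_that("removing all down miRs reduces the study set to mRNA genes", {
  sim <- make_small_study(seed = 39L)
  md <- mir_differential(sim$ct, meso_config(downreg_p_max = 0))
  ed <- mrna_differential(sim$expr)
  fit <- integrate_mir_mrna(md, ed, sim$pathways, sim$mir_targets,
                            n_steps = 3e4, seed = 39L)
  pop <- sort(unique(unlist(sim$pathways$sets, use.names = FALSE)))
  expect_setequal(fit$study_set,
                  intersect(unique_gene_list(ed, "integration_selected"), pop))
})

test_that("planted active pathways outrank inactive ones end to end", {
  wins <- vapply(1:60, function(s) {
    sim <- simulate_study(sim_params(seed = 9000L + s))
    fit <- fit_pipeline(sim, n_steps = 3e4, seed = s)
    tab <- fit$table
    act <- sim$truth$active_pathways
    min(tab$estimate[tab$pathway %in% act]) >
      max(tab$estimate[!tab$pathway %in% act])
  }, logical(1L))
  expect_gte(mean(wins), 0.9)
})
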