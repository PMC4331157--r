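test_that("CT truncation censors at the detection limit", {
  out <- truncate_ct(c(28.4, 35, 37.2, NA))
  expect_equal(as.numeric(out), c(28.4, 35, 35, NA))
  expect_equal(attr(out, "censored"), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("per-sample delta-CT subtracts the sample's own control", {
  tab <- make_ct(list("miR-a" = c(24, 23, 27.5)),
                 groups = labels_mpm(2, 1),
                 control = c(20, 19.5, 20.5))
  d <- delta_ct(tab)
  expect_equal(unname(d$delta_ct[, "miR-a"]), c(4, 3.5, 7))

  tab$ct[2, "U6"] <- NA
  expect_error(delta_ct(tab), "s02")
})

test_that("missing assay wells give missing delta-CT values", {
  tab <- make_ct(list("miR-a" = c(24, NA, 27)), labels_mpm(2, 1))
  d <- delta_ct(tab)
  expect_true(is.na(d$delta_ct[2, "miR-a"]))
})

test_that("group mean of per-sample dCT equals difference of group means when control is flat", {
  # with a constant control the two normalization granularities coincide
  set.seed(7)
  ct <- matrix(rnorm(24 * 5, 27, 2), 24,
               dimnames = list(NULL, paste0("miR-", 1:5)))
  tab <- make_ct(asplit(ct, 2), labels_mpm(18, 6), control = rep(20, 24))
  d <- delta_ct(tab)$delta_ct
  for (a in colnames(d)) {
    lhs <- mean(d[1:18, a])
    rhs <- mean(truncate_ct(ct[1:18, a])) - 20
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("fold change is the comparative-CT ratio with its symmetries", {
  expect_equal(round(fold_change(7.06, 9.54), 2), 5.58)
  expect_equal(round(fold_change(8.85, 12.65), 2), 13.93)
  expect_equal(fold_change(5, 5), 1)
  set.seed(3)
  a <- rnorm(20, 8); b <- rnorm(20, 10)
  expect_equal(fold_change(a, b) * fold_change(b, a), rep(1, 20),
               tolerance = 1e-9)
})

test_that("label swap negates ddCT, inverts fold change, keeps p-values", {
  sim <- simulate_ct_dataset(sim_params(n_mirs = 20L, seed = 8L,
                                        missing_fraction = 0))
  fit1 <- mir_differential(sim$table)
  swapped <- sim$table
  swapped$group_labels <- ifelse(swapped$group_labels == "MPM", "BAPE", "MPM")
  fit2 <- mir_differential(swapped)
  expect_equal(fit1$table$delta_delta_ct, -fit2$table$delta_delta_ct,
               tolerance = 1e-9)
  expect_equal(fit1$table$fold_change, 1 / fit2$table$fold_change,
               tolerance = 1e-9)
  expect_equal(fit1$table$p_value, fit2$table$p_value, tolerance = 1e-9)
})

test_that("exclusion and censoring filters fire as specified", {
  # undetected in all samples -> excluded
  tab <- make_ct(list("miR-dead" = rep(NA_real_, 6),
                      "miR-ok" = c(24, 24.5, 23.8, 28, 28.2, 27.9)),
                 labels_mpm(3, 3))
  fit <- suppressWarnings(mir_differential(tab))  # single-p pi0 fallback
  expect_equal(fit$table$call[fit$table$assay == "miR-dead"], "excluded")
  expect_true(is.na(fit$table$fold_change[fit$table$assay == "miR-dead"]))

  # >3 censored case wells block the "up" call however strong the signal
  nc <- 18; nr <- 6
  case_vals <- c(rep(36.5, 4), rep(25, nc - 4))  # 4 censored case wells
  tab2 <- make_ct(list("miR-cens" = c(case_vals, rep(34, nr))),
                  labels_mpm(nc, nr))
  fit2 <- suppressWarnings(mir_differential(tab2))
  row <- fit2$table[fit2$table$assay == "miR-cens", ]
  expect_equal(row$n_censored_case, 4)
  expect_gt(row$fold_change, 1)
  expect_true(row$call != "up")
})

test_that("identical groups give p = 1 and an ns call", {
  tab <- make_ct(list("miR-flat" = rep(25, 8)), labels_mpm(4, 4))
  fit <- suppressWarnings(mir_differential(tab))  # single-p pi0 fallback
  expect_equal(fit$table$p_value, 1)
  expect_equal(fit$table$call, "ns")
})

test_that("groups with fewer than two usable wells are flagged untestable", {
  tab <- make_ct(list("miR-a" = c(24, NA, NA, 28, 29, 28.5),
                      "miR-b" = c(24, 25, 23, 28, 29, 28.5)),
                 labels_mpm(3, 3))
  fit <- suppressWarnings(mir_differential(tab))  # single-p pi0 fallback
  row <- fit$table[fit$table$assay == "miR-a", ]
  expect_false(row$testable)
  expect_true(is.na(row$p_value))
  expect_equal(row$call, "ns")
  expect_true(fit$table$testable[fit$table$assay == "miR-b"])
})

test_that("planted shifts are detected and agree with a permutation oracle", {
  sim <- simulate_ct_dataset(sim_params(seed = 12L, missing_fraction = 0))
  fit <- mir_differential(sim$table)
  up_called <- fit$table$assay[fit$table$call == "up"]
  expect_true(all(sim$truth$upregulated_mirs %in% up_called))

  # permutation oracle on a subset of assays: rejection at alpha = 0.05
  # agrees with the t-test for >= 95% of them
  d <- fit$delta_ct$delta_ct
  labs <- fit$delta_ct$group_labels
  set.seed(99)
  assays <- sample(colnames(d), 40)
  agree <- vapply(assays, function(a) {
    obs <- abs(mean(d[labs == "MPM", a]) - mean(d[labs == "BAPE", a]))
    perm <- replicate(400, {
      pl <- sample(labs)
      abs(mean(d[pl == "MPM", a]) - mean(d[pl == "BAPE", a]))
    })
    p_perm <- (1 + sum(perm >= obs)) / 401
    p_t <- fit$table$p_value[fit$table$assay == a]
    (p_perm < 0.05) == (p_t < 0.05)
  }, logical(1L))
  expect_gte(mean(agree), 0.95)
})

test_that("censoring-filter violations never reach the up list (random tables)", {
  set.seed(17)
  for (r in 1:20) {
    nc <- 10; nr <- 4
    wells <- lapply(1:8, function(i) {
      v <- rnorm(nc + nr, runif(1, 26, 36), 1.5)
      pmax(v, 1)
    })
    names(wells) <- paste0("miR-", 1:8)
    fit <- mir_differential(make_ct(wells, labels_mpm(nc, nr)))
    bad <- fit$table$n_censored_case > 3
    expect_false(any(fit$table$call[bad] == "up"))
  }
})

test_that("type-I error of the per-assay test is near nominal on null data", {
  p_all <- unlist(lapply(1:60, function(r) {
    sim <- simulate_ct_dataset(sim_params(n_mirs = 40L, effect_shift_ct = 0,
                                          seed = 1000L + r,
                                          missing_fraction = 0))
    mir_differential(sim$table)$table$p_value
  }))
  expect_lte(mean(p_all < 0.05), 0.07)
})
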