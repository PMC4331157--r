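# independent oracle: direct summation over all activation vectors,
# written without the package's incremental Gray-code machinery
brute_mgsa <- function(sets, study, pop, alpha, beta, p) {
  K <- length(sets)
  G <- length(pop)
  obs <- pop %in% study
  states <- expand.grid(rep(list(0:1), K))
  w <- apply(states, 1, function(a) {
    act <- which(a == 1)
    hidden <- pop %in% unlist(sets[act])
    lik <- prod(ifelse(hidden,
                       ifelse(obs, 1 - beta, beta),
                       ifelse(obs, alpha, 1 - alpha)))
    lik * p^sum(a) * (1 - p)^(K - sum(a))
  })
  vapply(seq_len(K), function(k) sum(w[states[[k]] == 1]) / sum(w),
         numeric(1L))
}

test_that("enumeration matches a brute-force posterior on hand-set models", {
  # one set covering the whole population, fully observed study set:
  # two states, posterior strongly favours active
  pop <- paste0("g", 1:6)
  fit <- mgsa(list(T1 = pop), study_set = pop, population = pop,
              alpha = 0.1, beta = 0.1, p = 0.5, method = "enumerate")
  manual <- (0.9^6) / (0.9^6 + 0.1^6)   # (1-beta)^G vs alpha^G at p = 0.5
  expect_equal(fit$table$estimate, manual, tolerance = 1e-12)
  expect_gt(fit$table$estimate, 0.5)

  # two competing sets: the one matching the study set must win
  sets <- list(T1 = c("g1", "g2"), T2 = "g3")
  fit <- mgsa(sets, study_set = c("g1", "g2"), population = paste0("g", 1:3),
              alpha = 0.1, beta = 0.1, p = 0.5, method = "enumerate")
  oracle <- brute_mgsa(sets, c("g1", "g2"), paste0("g", 1:3), 0.1, 0.1, 0.5)
  expect_equal(fit$table$estimate, oracle, tolerance = 1e-12)
  expect_gt(fit$table$estimate[1], fit$table$estimate[2])

  # empty study set with a tiny prior: no evidence, prior-dominated
  fit <- mgsa(sets, study_set = character(0), population = paste0("g", 1:3),
              alpha = 0.1, beta = 0.1, p = 0.01, method = "enumerate")
  expect_true(all(fit$table$estimate <= 0.5))
})

test_that("enumeration matches brute force on random models", {
  set.seed(23)
  for (r in 1:15) {
    K <- sample(2:7, 1); G <- sample(10:40, 1)
    pop <- paste0("g", 1:G)
    sets <- setNames(lapply(1:K, function(i) sample(pop, sample(3:8, 1))),
                     paste0("S", 1:K))
    study <- sample(pop, sample(2:min(15, G), 1))
    a <- runif(1, 0.05, 0.4); b <- runif(1, 0.05, 0.4)
    p <- runif(1, 0.05, 0.5)
    fit <- mgsa(sets, study, population = pop, alpha = a, beta = b, p = p,
                method = "enumerate")
    expect_equal(fit$table$estimate, brute_mgsa(sets, study, pop, a, b, p),
                 tolerance = 1e-10)
  }
})

test_that("MCMC agrees with enumeration within Monte-Carlo tolerance", {
  set.seed(24)
  for (r in 1:8) {
    K <- sample(3:12, 1); G <- sample(30:100, 1)
    pop <- paste0("g", 1:G)
    sets <- setNames(lapply(1:K, function(i) sample(pop, sample(4:12, 1))),
                     paste0("S", 1:K))
    study <- sample(pop, sample(4:25, 1))
    a <- runif(1, 0.05, 0.3); b <- runif(1, 0.05, 0.3)
    p <- runif(1, 0.05, 0.3)
    e <- mgsa(sets, study, population = pop, alpha = a, beta = b, p = p,
              method = "enumerate")
    m <- mgsa(sets, study, population = pop, alpha = a, beta = b, p = p,
              method = "mcmc", n_steps = 1e6, seed = 100 + r)
    expect_lt(max(abs(e$table$estimate - m$table$estimate)), 0.03)
  }
})

test_that("gridded hyperparameters are marginalized consistently", {
  set.seed(25)
  pop <- paste0("g", 1:60)
  sets <- setNames(lapply(1:6, function(i) sample(pop, 10)), paste0("S", 1:6))
  study <- c(sets$S1[1:8], sample(setdiff(pop, sets$S1), 4))
  grids <- list(alpha = c(0.05, 0.15, 0.3), beta = c(0.1, 0.25),
                p = c(0.1, 0.2, 0.3))
  e <- mgsa(sets, study, population = pop, alpha = grids$alpha,
            beta = grids$beta, p = grids$p, method = "enumerate")
  m <- mgsa(sets, study, population = pop, alpha = grids$alpha,
            beta = grids$beta, p = grids$p, method = "mcmc",
            n_steps = 2e6, seed = 77)
  expect_lt(max(abs(e$table$estimate - m$table$estimate)), 0.03)
  expect_lt(abs(e$diagnostics$p_mean - m$diagnostics$p_mean), 0.02)
  # the set generating the study signal should score highest
  expect_equal(which.max(e$table$estimate), 1L)
})

test_that("MCMC is deterministic under a fixed seed", {
  pop <- paste0("g", 1:50)
  set.seed(26)
  sets <- setNames(lapply(1:5, function(i) sample(pop, 8)), paste0("S", 1:5))
  study <- sample(pop, 10)
  f1 <- mgsa(sets, study, population = pop, alpha = 0.1, beta = 0.2,
             p = 0.2, method = "mcmc", n_steps = 1e5, seed = 42)
  f2 <- mgsa(sets, study, population = pop, alpha = 0.1, beta = 0.2,
             p = 0.2, method = "mcmc", n_steps = 1e5, seed = 42)
  expect_identical(f1$table$estimate, f2$table$estimate)
})

test_that("permuting set labels permutes estimates identically", {
  set.seed(27)
  pop <- paste0("g", 1:40)
  sets <- setNames(lapply(1:6, function(i) sample(pop, 7)), paste0("S", 1:6))
  study <- sample(pop, 12)
  f1 <- mgsa(sets, study, population = pop, alpha = 0.1, beta = 0.2, p = 0.2,
             method = "enumerate")
  perm <- c(4, 2, 6, 1, 3, 5)
  f2 <- mgsa(sets[perm], study, population = pop, alpha = 0.1, beta = 0.2,
             p = 0.2, method = "enumerate")
  expect_equal(f2$table$estimate, f1$table$estimate[perm], tolerance = 1e-10)
})

test_that("growing a set's overlap with the study set cannot hurt it", {
  set.seed(28)
  pop <- paste0("g", 1:50)
  others <- setNames(lapply(1:4, function(i) sample(pop, 8)),
                     paste0("S", 1:4))
  study <- sample(pop, 15)
  est <- vapply(c(2, 5, 8), function(k) {
    focal <- c(sample(study, k), sample(setdiff(pop, study), 8 - k))
    fit <- mgsa(c(list(F = focal), others), study, population = pop,
                alpha = 0.1, beta = 0.2, p = 0.2, method = "enumerate")
    fit$table$estimate[1]
  }, numeric(1L))
  expect_true(all(diff(est) >= -1e-9))
})

test_that("study genes outside the population are dropped with a count", {
  pop <- paste0("g", 1:10)
  fit <- mgsa(list(S = pop[1:5]), study_set = c(pop[1:3], "absent1", "absent2"),
              population = pop, alpha = 0.1, beta = 0.2, p = 0.3,
              method = "enumerate")
  expect_equal(fit$n_dropped_study_genes, 2L)
  expect_length(fit$study_set, 3L)
})

test_that("enumeration refuses oversized state spaces", {
  pop <- paste0("g", 1:30)
  sets <- setNames(lapply(1:21, function(i) sample(pop, 3)),
                   paste0("S", 1:21))
  expect_error(mgsa(sets, pop[1:5], population = pop, alpha = 0.1,
                    beta = 0.1, p = 0.1, method = "enumerate"),
               "at most 20")
})

test_that("a planted active pathway is recovered across seeds", {
  recovered <- vapply(1:60, function(s) {
    sim <- simulate_study(sim_params(n_probesets = 300L, n_de = 20L,
                                     n_genes = 400L, seed = 4000L + s))
    study <- unique(c(sim$truth$de_genes,
                      unlist(sim$truth$target_links, use.names = FALSE)))
    pop <- sort(unique(unlist(sim$pathways$sets, use.names = FALSE)))
    fit <- mgsa(sim$pathways, study, population = pop,
                method = "mcmc", n_steps = 5e4, seed = s)
    fit$table$set[which.max(fit$table$estimate)] ==
      sim$truth$active_pathways[1]
  }, logical(1L))
  expect_gte(mean(recovered), 0.95)
})
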