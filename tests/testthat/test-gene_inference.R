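test_that("gene Bayes factor is the mixture product over variants", {
  eta <- c(I = 0.5, II = 0.1)
  # eta = 0 for every class: no risk variants allowed, neutral gene
  expect_equal(gene_bayes_factor(c(2, 3), c("I", "I"), c(I = 0, II = 0)), 1)
  # hand arithmetic: (0.5 + 0.5*2) * (0.5 + 0.5*3) = 1.5 * 2 = 3
  expect_equal(gene_bayes_factor(c(2, 3), c("I", "I"), eta), 3)
  # eta = 1 collapses the mixture onto the variant BF
  expect_equal(gene_bayes_factor(7.3, "I", c(I = 1)), 7.3)
  expect_equal(gene_bayes_factor(numeric(0), character(0), eta), 1)
  expect_error(gene_bayes_factor(2, "X", eta), "no eta")
})

test_that("a flat likelihood is a fixed point of the EM", {
  tab <- data.frame(gene = c("A", "B"), var_class = c("I", "II"),
                    bf = c(1, 1), stringsAsFactors = FALSE)
  fit <- em_fit(tab, init = c(delta = 0.3, eta1 = 0.4, eta2 = 0.2))
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2)
  expect_equal(fit$delta, 0.3)
  expect_equal(unname(fit$eta), c(0.4, 0.2))
  expect_equal(fit$gene_results$lr, c(1, 1))
})

test_that("EM matches the exhaustive grid-search MLE on a 3-gene toy", {
  tab <- toy_bf_tab()
  fit <- em_fit(tab)
  oracle <- grid_search_mixture(tab, c("A", "B", "C"))
  expect_lt(abs(fit$delta - oracle["delta"]), 2e-3)
  expect_lt(abs(fit$eta[["I"]] - oracle["eta1"]), 2e-3)
  expect_lt(abs(fit$eta[["II"]] - oracle["eta2"]), 2e-3)
})

test_that("the log-likelihood trace ascends at every iteration", {
  tab <- toy_bf_tab()
  fit <- em_fit(tab)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  set.seed(5)
  sim <- simulate_dataset(sim_config(n_genes = 150, seed = 5))
  bf <- variant_bf_table(sim$variants, study_p0(), study_priors())
  fit2 <- em_fit(bf, genes = sim$genes$gene)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-10))
  expect_true(all(c(fit2$delta, fit2$eta) >= 0))
  expect_true(all(c(fit2$delta, fit2$eta) <= 1))
})

test_that("estimates are invariant to row order", {
  sim <- simulate_dataset(sim_config(n_genes = 80, seed = 17))
  bf <- variant_bf_table(sim$variants, study_p0(), study_priors())
  fit1 <- em_fit(bf, genes = sim$genes$gene)
  set.seed(1)
  shuffled <- bf[sample(nrow(bf)), ]
  fit2 <- em_fit(shuffled, genes = sim$genes$gene)
  expect_equal(fit1$delta, fit2$delta, tolerance = 1e-12)
  expect_equal(fit1$eta, fit2$eta, tolerance = 1e-12)
})

test_that("genes without variants dilute delta as neutral evidence", {
  tab <- data.frame(gene = c("A", "A"), var_class = "I", bf = c(9, 4),
                    stringsAsFactors = FALSE)
  fit_small <- em_fit(tab, genes = c("A", "B"))
  fit_large <- em_fit(tab, genes = c("A", "B", "C", "D", "E", "F"))
  expect_lt(fit_large$delta, fit_small$delta)
  # a variant-free gene sits at the prior: posterior == delta
  gr <- fit_large$gene_results
  expect_equal(gr$lr[gr$gene == "B"], 1)
  expect_equal(gr$posterior[gr$gene == "B"], fit_large$delta)
})

test_that("more case-skewed class-I counts never lower the fitted eta1", {
  # replace a balanced count split by an all-case split for one variant:
  # its BF grows, and the class-I risk-variant proportion must not drop
  p0 <- 0.2
  priors <- study_priors()
  base <- data.frame(
    gene = c("A", "A", "B", "C", "C"),
    var_class = c("I", "I", "I", "II", "I"),
    ac_case = c(1L, 2L, 0L, 1L, 3L),
    ac_control = c(2L, 1L, 2L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  skewed <- base
  skewed$ac_case[1] <- 3L
  skewed$ac_control[1] <- 0L
  f1 <- em_fit(variant_bf_table(base, p0, priors))
  f2 <- em_fit(variant_bf_table(skewed, p0, priors))
  expect_gte(f2$eta[["I"]] - f1$eta[["I"]], -1e-8)
})

test_that("grid-search equivalence holds on further tiny instances", {
  cases <- list(
    data.frame(gene = c("A", "A", "B", "B"), var_class = c("I", "II", "I", "II"),
               bf = c(5, 0.8, 0.3, 2), stringsAsFactors = FALSE),
    data.frame(gene = c("A", "A", "B", "B", "C", "C"),
               var_class = c("I", "I", "II", "II", "I", "II"),
               bf = c(6, 2, 0.5, 1.4, 0.7, 1.2), stringsAsFactors = FALSE)
  )
  for (tab in cases) {
    genes <- sort(unique(tab$gene))
    fit <- em_fit(tab, genes = genes)
    oracle <- grid_search_mixture(tab, genes)
    expect_lt(abs(fit$delta - oracle["delta"]), 2e-3)
    expect_lt(abs(fit$eta[["I"]] - oracle["eta1"]), 2e-3)
    expect_lt(abs(fit$eta[["II"]] - oracle["eta2"]), 2e-3)
  }
})

test_that("a class with only neutral variants has LRT statistic 0, p 0.5", {
  tab <- data.frame(gene = c("A", "A", "B"), var_class = c("I", "I", "II"),
                    bf = c(6, 2, 1), stringsAsFactors = FALSE)
  fit <- em_fit(tab)
  res <- lrt_eta(tab, fit, "II")
  expect_equal(res$stat, 0, tolerance = 1e-6)
  expect_equal(res$p, 0.5, tolerance = 1e-6)
})

test_that("fit_mixture attaches a p-value per class", {
  sim <- simulate_dataset(sim_config(n_genes = 120, seed = 3))
  bf <- variant_bf_table(sim$variants, study_p0(), study_priors())
  fit <- fit_mixture(bf, genes = sim$genes$gene)
  expect_named(fit$eta_pvalues, c("I", "II"))
  expect_true(all(fit$eta_pvalues >= 0 & fit$eta_pvalues <= 0.5))
})

test_that("a strong class-I signal is detected at extreme significance", {
  # mirrors the study conditions at reduced scale; the class-I proportion
  # is high and its boundary LRT should be overwhelming
  sim <- simulate_dataset(sim_config(n_genes = 800, seed = 29))
  bf <- variant_bf_table(sim$variants, study_p0(), study_priors())
  fit <- em_fit(bf, genes = sim$genes$gene)
  res <- lrt_eta(bf, fit, "I", genes = sim$genes$gene)
  expect_lt(res$p, 1e-10)
})
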