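test_that("LRT p-values match chi-squared(1) closed forms", {
  expect_equal(lrt_pvalue(0, 0)$p_value, 1)
  expect_equal(lrt_pvalue(3.841 / 2, 0)$p_value, 0.050, tolerance = 1e-3)
  expect_equal(lrt_pvalue(6.635 / 2, 0)$p_value, 0.010, tolerance = 1e-3)
  # tiny negative LR clipped; beyond slack is a nesting violation
  expect_equal(lrt_pvalue(-1e-10, 0)$lr_stat, 0)
  expect_error(lrt_pvalue(-1, 0), "nested")
})

test_that("Bonferroni thresholds divide alpha by the per-cell-type gene count", {
  res <- data.frame(gene = letters[1:5], cell_type = "microglia",
                    p_value = c(0.001, 0.01, 0.02, 0.5, 0.009))
  out <- bonferroni_calls(res, alpha = 0.05)
  expect_equal(unique(out$threshold), 0.01)
  # strict inequality: p exactly at the threshold is not significant
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # the genome-scale threshold: 0.05 / 17361 genes
  expect_equal(0.05 / 17361, 2.88e-6, tolerance = 1e-3)
})

test_that("gene screening filters an external table or runs a burden LRT", {
  co <- toy_cohort(10L)
  p_tab <- c(A = 0.005, B = 0.02, C = 0.5)
  expect_equal(screen_genes(co, pvalues = p_tab, threshold = 0.01), "A")
  expect_setequal(screen_genes(co, pvalues = p_tab, threshold = 1.0),
                  c("A", "B", "C"))
  expect_error(screen_genes(co, pvalues = c(A = 0.5), threshold = 0.01),
               "looser")
  expect_error(screen_genes(co, pvalues = c(A = 0)), "\\(0, 1\\]")
})

test_that("built-in burden screen is calibrated on a null cohort", {
  sim <- quick_sim(n = 500L, M = 60L, p = 30L, seed = 21, h2 = 0.2)
  null_cohort <- sim$truth$cohort
  set.seed(33)
  null_cohort$Y <- matrix(rbinom(length(null_cohort$Y), 1, 0.5),
                          nrow(null_cohort$Y))  # sever genotype link
  res <- gruyere_gene_test(null_cohort,
                           lapply(sim$synth$gene_data, function(gd) {
                             gd$Z <- matrix(0, ncol(gd$G), 0L); gd
                           }), tau = 1)
  # ~1% of null genes at p < 0.01: with 60 genes expect 0-4 survivors
  expect_lte(sum(res$p_value < 0.01), 4L)
})

test_that("per-gene ML fit matches an independent Newton-Raphson oracle", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 300L
    X <- cbind(1, matrix(runif(n * 2), n))
    score <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 * score - 0.2))
    fit <- gruyere:::logistic_irls(cbind(X, s = score), y)
    oracle <- nr_logistic(cbind(X, score), y)
    expect_equal(unname(fit$coef), oracle$coef, tolerance = 1e-6)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("per-gene test recovers a planted gene effect and flags separation", {
  sim <- quick_sim(n = 1200L, M = 4L, p = 50L, seed = 6, h2 = 0.25)
  truth <- sim$truth
  res <- gruyere_gene_test(truth$cohort, sim$synth$gene_data,
                           tau = if (truth$include_intercept_tau) truth$tau
                                 else c(0, truth$tau))
  ok <- !res$flagged
  expect_true(any(ok))
  expect_true(all(abs(res$w_g[ok] - truth$w[ok]) <= 3 * res$se[ok] + 1e-3))
  # separation: a perfectly separating score is flagged, not an error
  n <- 60L
  y <- rep(c(0, 1), each = n / 2)
  gd_sep <- list(g = list(G = matrix(y * 2, n, 1),
                          Z = matrix(1, 1, 1), maf = 0.04))
  co <- cohort_data(sprintf("S%03d", 1:n), y,
                    matrix(runif(n), n, dimnames = list(NULL, "c1")))
  out <- gruyere_gene_test(co, gd_sep, tau = c(0.5, 0.5))
  expect_true(out$flagged)
  expect_true(is.na(out$p_value))
})

test_that("joint fit is reproducible, shrinks a null annotation, and agrees
           with the per-gene ML fit on shared genes", {
  spec <- cohort_spec(n = 800L, M = 6L, variants_per_gene = 40L,
                      c_covariates = 4L, q_annotations = 4L)
  synth <- generate_cohort(spec, seed = 31)
  params <- draw_sim_params(synth, seed = 31)
  params$tau <- c(0.3, 0.3, 0.3, 0.1, 0)   # anno4 truly carries no weight
  truth <- simulate_phenotypes(synth, params = params, seed = 31,
                               heritability_target = 0.25)
  gd <- synth$gene_data
  fit1 <- gruyere(truth$cohort, gd, epochs = 150L, seed = 77)
  fit2 <- gruyere(truth$cohort, gd, epochs = 150L, seed = 77)
  expect_identical(fit1$tau, fit2$tau)
  expect_false(identical(fit1$tau,
                         gruyere(truth$cohort, gd, epochs = 150L,
                                 seed = 78)$tau))
  # tau on the simplex
  expect_equal(sum(fit1$tau), 1, tolerance = 1e-8)
  expect_true(all(fit1$tau >= 0))
  # the dead annotation receives less than uniform mass
  q1 <- length(fit1$tau)
  expect_lt(fit1$tau[["anno4"]], 1 / q1)
  # per-gene ML w_g within 2 posterior sds of the joint posterior mean
  res <- gruyere_gene_test(truth$cohort, gd, tau = fit1$tau)
  ok <- !res$flagged
  expect_true(mean(abs(res$w_g[ok] - fit1$w[ok]) <=
                     2 * fit1$w_sd[ok] + 0.05) >= 0.8)
})

test_that("ELBO trace is finite and generally increasing", {
  sim <- quick_sim(n = 400L, M = 4L, p = 30L, seed = 41, h2 = 0.2)
  fit <- gruyere(sim$truth$cohort, sim$synth$gene_data, epochs = 120L,
                 seed = 2)
  expect_true(all(is.finite(fit$elbo_trace)))
  first <- mean(fit$elbo_trace[1:10])
  last <- mean(fit$elbo_trace[111:120])
  expect_gt(last, first)
})
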