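test_that("synthetic genotypes match their MAFs and the spectrum is capped", {
  spec <- cohort_spec(n = 1000L, M = 10L, variants_per_gene = 50L)
  synth <- generate_cohort(spec, seed = 2)
  mafs <- unlist(lapply(synth$gene_data, `[[`, "maf"))
  expect_true(all(mafs <= 0.05 & mafs > 0))
  # moment check: mean dosage ~ 2 * MAF within a binomial CI
  for (g in synth$gene_data[1:3]) {
    mean_dos <- colMeans(g$G)
    se <- sqrt(2 * g$maf * (1 - g$maf) / spec$n)
    expect_true(all(abs(mean_dos - 2 * g$maf) <= 4 * se + 1e-12))
  }
  # annotations in [0,1]
  expect_true(all(vapply(synth$gene_data,
                         function(g) all(g$Z >= 0 & g$Z <= 1), logical(1))))
  # covariates scaled
  expect_true(all(synth$X >= 0 & synth$X <= 1))
})

test_that("cohort generation is bit-identical under a fixed seed", {
  s1 <- generate_cohort(cohort_spec(n = 100L, M = 3L,
                                    variants_per_gene = 10L), seed = 9)
  s2 <- generate_cohort(cohort_spec(n = 100L, M = 3L,
                                    variants_per_gene = 10L), seed = 9)
  expect_identical(s1$gene_data, s2$gene_data)
  expect_identical(s1$X, s2$X)
})

test_that("null parameters give ~50% cases and zero heritability", {
  synth <- generate_cohort(cohort_spec(n = 2000L, M = 3L,
                                       variants_per_gene = 20L), seed = 4)
  params <- draw_sim_params(synth, seed = 4)
  params$alpha[] <- 0
  params$w[] <- 0
  truth <- simulate_phenotypes(synth, params = params, seed = 4)
  expect_equal(mean(truth$Y), 0.5, tolerance = 0.03)
  expect_equal(truth$heritability, 0)
})

test_that("heritability estimator has the closed-form plug-in behavior", {
  # Var(G beta) = pi^2/3 and Var(X alpha) = 0 -> exactly one half
  synth <- generate_cohort(cohort_spec(n = 500L, M = 2L,
                                       variants_per_gene = 10L), seed = 5)
  params <- draw_sim_params(synth, seed = 5)
  params$alpha[] <- 0
  comp <- gruyere:::eta_components(synth, params)
  target_sd <- sqrt(pi^2 / 3)
  params$w <- params$w * target_sd / apply(comp$eta_gen, 2, sd) /
    abs(params$w) * params$w  # scale each gene's eta_gen to variance pi^2/3
  comp2 <- gruyere:::eta_components(synth, params)
  expect_equal(unname(apply(comp2$eta_gen, 2, var)),
               rep(pi^2 / 3, 2), tolerance = 1e-10)
  expect_equal(as.numeric(estimate_heritability(synth, params)), 0.5)
  # monotone in the gene-effect scale
  params3 <- draw_sim_params(synth, seed = 6)
  h2s <- vapply(c(0.5, 1, 2, 4), function(s) {
    p <- params3; p$w <- p$w * s
    as.numeric(estimate_heritability(synth, p))
  }, numeric(1))
  expect_true(all(diff(h2s) > 0))
})

test_that("heritability targeting and rejection capping work as documented", {
  synth <- generate_cohort(cohort_spec(n = 800L, M = 5L,
                                       variants_per_gene = 30L), seed = 7)
  tr <- simulate_phenotypes(synth, seed = 7, heritability_target = 0.12)
  expect_equal(tr$heritability, 0.12, tolerance = 1e-6)
  # recorded truth reflects the rescaled effects that generated the data
  expect_equal(as.numeric(estimate_heritability(synth, tr)), 0.12,
               tolerance = 1e-6)
  # raw prior draws on this design exceed the cap; the redraw limit errors
  expect_error(simulate_phenotypes(synth, seed = 7, max_redraws = 2L),
               "redraws")
  # fixed truth and seed give identical phenotypes
  tr2 <- simulate_phenotypes(synth, seed = 7, heritability_target = 0.12)
  expect_identical(tr$Y, tr2$Y)
})

test_that("case prevalence responds to an intercept shift", {
  synth <- generate_cohort(cohort_spec(n = 2000L, M = 2L,
                                       variants_per_gene = 10L), seed = 8)
  params <- draw_sim_params(synth, seed = 8)
  params$alpha[] <- 0; params$w[] <- 0
  params$alpha[1, ] <- 2   # intercept row
  tr <- simulate_phenotypes(synth, params = params, seed = 8)
  expect_equal(mean(tr$Y), plogis(2), tolerance = 0.03)
})

test_that("recovery metrics hit the identity, antisymmetry and null cases", {
  sim <- quick_sim(n = 300L, M = 4L, p = 20L, seed = 10, h2 = 0.2)
  truth <- sim$truth
  tau_full <- if (truth$include_intercept_tau) truth$tau else c(0, truth$tau)
  mock_fit <- structure(list(
    genes = names(sim$synth$gene_data),
    alpha = truth$alpha, w = truth$w, tau = tau_full), class = "gruyere_fit")
  rec <- recovery_metrics(truth, mock_fit, sim$synth$gene_data)
  expect_equal(rec$pearson_r, rep(1, 4), tolerance = 1e-12)
  neg_fit <- mock_fit
  neg_fit$alpha <- -truth$alpha; neg_fit$w <- -truth$w
  rec2 <- recovery_metrics(truth, neg_fit, sim$synth$gene_data)
  expect_equal(rec2$pearson_r[rec2$parameter_block %in% c("alpha", "w")],
               c(-1, -1), tolerance = 1e-12)
  # independent random estimates correlate near zero for alpha
  set.seed(1)
  rand_fit <- mock_fit
  rand_fit$alpha <- matrix(rnorm(length(truth$alpha)), nrow(truth$alpha))
  rec3 <- recovery_metrics(truth, rand_fit, sim$synth$gene_data)
  expect_lt(abs(rec3$pearson_r[rec3$parameter_block == "alpha"]), 0.5)
  # constant estimate -> NA
  const_fit <- mock_fit; const_fit$w <- rep(1, length(truth$w))
  rec4 <- recovery_metrics(truth, const_fit, sim$synth$gene_data)
  expect_true(is.na(rec4$pearson_r[rec4$parameter_block == "w"]))
})

test_that("study scaffolding: empty study, failure capture, smoke recovery", {
  expect_equal(nrow(run_simulation_study(n_sims = 0L)), 0L)
  study <- run_simulation_study(
    n_sims = 2L, spec = cohort_spec(n = 500L, M = 5L,
                                    variants_per_gene = 30L,
                                    c_covariates = 3L, q_annotations = 3L),
    seed = 3, heritability_range = c(0.15, 0.30), epochs = 150L)
  ok <- study[is.na(study$error), ]
  expect_equal(length(unique(ok$sim_id)), 2L)
  expect_true(all(ok$heritability >= 0.15 - 1e-6 &
                    ok$heritability <= 0.30 + 1e-6))
  w_r <- ok$pearson_r[ok$parameter_block == "w"]
  expect_true(mean(w_r) > 0.8)
})
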