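#' Specification of a synthetic case-control cohort
#'
#' Defaults describe the desk-scale study used throughout the package:
#' 2,000 samples, 30 genes with 100 rare variants each, 10 correlated
#' covariates, 6 annotations, and per-variant MAFs drawn from a
#' rare-skewed Beta(0.5, 50) truncated at 0.05.
#'
#' @param n Samples.
#' @param M Genes.
#' @param variants_per_gene Rare variants per gene.
#' @param c_covariates Covariates (before the model's intercept).
#' @param q_annotations Annotation columns.
#' @param maf_shape Beta shape parameters of the MAF spectrum.
#' @param maf_max MAF truncation point (default 0.05).
#' @param maf_min Lower truncation avoiding monomorphic variants.
#' @param covariate_rho Equicorrelation of the latent covariate Gaussian.
#' @param annotation_sparsity Probability that an annotation value comes
#'   from the low-score mixture component.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 2000L, M = 30L, variants_per_gene = 100L,
                        c_covariates = 10L, q_annotations = 6L,
                        maf_shape = c(0.5, 50), maf_max = 0.05,
                        maf_min = 0.001, covariate_rho = 0.3,
                        annotation_sparsity = 0.8) {
  stopifnot(n >= 1, M >= 1, variants_per_gene >= 1, c_covariates >= 1,
            q_annotations >= 1, maf_max > maf_min, maf_min > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort (genotypes, covariates, annotations)
#'
#' Draws per-variant MAFs from a truncated rare-skewed Beta, genotypes as
#' Binomial(2, MAF), covariates from an equicorrelated Gaussian min-max
#' scaled to \[0, 1\], and annotations from a two-component Beta mixture
#' producing mostly-low scores with a sparse high-scoring tail.
#' Phenotypes are added separately by [simulate_phenotypes()]. All
#' outputs use the same containers as real data.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the cohort is bit-identical under the same
#'   seed.
#' @return List of class `synthetic_cohort`: `X` (scaled covariates),
#'   `sample_ids`, `gene_data` (per gene `G`, `Z`, `maf`), `spec`,
#'   `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  rng <- local_rng(seed)
  n <- spec$n
  # covariates: equicorrelated latent Gaussian via one shared factor
  shared <- rng$rnorm(n)
  rho <- spec$covariate_rho
  X <- vapply(seq_len(spec$c_covariates), function(k)
    sqrt(rho) * shared + sqrt(1 - rho) * rng$rnorm(n), numeric(n))
  X <- apply(X, 2L, scale01)
  colnames(X) <- paste0("cov", seq_len(spec$c_covariates))
  sample_ids <- sprintf("S%04d", seq_len(n))
  rownames(X) <- sample_ids

  gene_data <- lapply(seq_len(spec$M), function(g) {
    p <- spec$variants_per_gene
    maf <- numeric(p)
    for (j in seq_len(p)) {
      repeat {
        m <- rng$rbeta(1L, spec$maf_shape[1], spec$maf_shape[2])
        if (m >= spec$maf_min && m <= spec$maf_max) break
      }
      maf[j] <- m
    }
    G <- vapply(maf, function(m) rng$rbinom(n, 2L, m), numeric(n))
    # sparse annotation scores: mostly low, occasionally high
    low <- rng$rbeta(p * spec$q_annotations, 1, 20)
    high <- rng$rbeta(p * spec$q_annotations, 5, 2)
    pick <- rng$rbinom(p * spec$q_annotations, 1L,
                       1 - spec$annotation_sparsity)
    Z <- matrix(ifelse(pick == 1L, high, low), p, spec$q_annotations)
    colnames(Z) <- paste0("anno", seq_len(spec$q_annotations))
    list(G = G, Z = Z, maf = maf)
  })
  names(gene_data) <- sprintf("gene%02d", seq_len(spec$M))
  structure(list(X = X, sample_ids = sample_ids, gene_data = gene_data,
                 spec = spec, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$spec$n, "samples,", x$spec$M, "genes x",
      x$spec$variants_per_gene, "variants,", x$spec$c_covariates,
      "covariates,", x$spec$q_annotations, "annotations (seed",
      x$seed, ")\n")
  invisible(x)
}

#' Draw ground-truth model parameters
#'
#' Parameters are drawn from the model priors:
#' `alpha_g ~ Normal(0, 1)`, `w_g ~ Normal(0, 1)` and
#' `tau ~ Dirichlet(1/q)`. In prior-mismatch mode the gene effects come
#' instead from a Gamma(2, 2) law — positive, skewed, and unlike the
#' normal prior used during inference.
#'
#' @param synth A `synthetic_cohort`.
#' @param seed Integer seed.
#' @param include_intercept_tau Draw tau over the (q+1)-simplex with an
#'   intercept component (default TRUE) or over the q annotations only.
#' @param w_mismatch Draw `w_g` from Gamma(2, 2) instead of Normal(0, 1).
#' @return List with `alpha` (c+1 x M, intercept row first), `w` (M),
#'   `tau`.
#' @export
draw_sim_params <- function(synth, seed = 1L, include_intercept_tau = TRUE,
                            w_mismatch = FALSE) {
  rng <- local_rng(seed)
  spec <- synth$spec
  c_all <- spec$c_covariates + 1L          # model intercept included
  alpha <- matrix(rng$rnorm(c_all * spec$M), c_all, spec$M)
  rownames(alpha) <- c("(intercept)", colnames(synth$X))
  colnames(alpha) <- names(synth$gene_data)
  w <- if (w_mismatch) rng$rgamma(spec$M, shape = 2, rate = 2)
       else rng$rnorm(spec$M)
  q <- spec$q_annotations
  K <- if (include_intercept_tau) q + 1L else q
  gam <- rng$rgamma(K, shape = 1 / q, rate = 1)
  # a gamma draw of 0 (possible at tiny shape in double precision) would
  # break the simplex; jitter by the smallest positive double
  tau <- (gam + 1e-300) / sum(gam + 1e-300)
  list(alpha = alpha, w = setNames(w, names(synth$gene_data)), tau = tau,
       include_intercept_tau = include_intercept_tau)
}

# per-gene decomposition of the linear predictor into covariate and
# genetic parts; returns n x M matrices
eta_components <- function(synth, params, beta_maf_shape = c(1, 25)) {
  X1 <- cbind(1, synth$X)
  eta_cov <- X1 %*% params$alpha
  tau_full <- if (params$include_intercept_tau) params$tau
              else c(0, params$tau)
  eta_gen <- vapply(seq_along(synth$gene_data), function(g) {
    gd <- synth$gene_data[[g]]
    s <- variant_scores(maf_weight(gd$maf, beta_maf_shape[1],
                                   beta_maf_shape[2]), gd$Z, tau_full)
    params$w[g] * as.numeric(gd$G %*% s)
  }, numeric(nrow(synth$X)))
  list(eta_cov = eta_cov, eta_gen = eta_gen)
}

#' Liability-scale heritability of a simulated parameter set
#'
#' Per gene, the genetic share of liability variance
#' `Var(G beta) / (Var(X alpha) + Var(G beta) + pi^2 / 3)` (the logistic
#' residual variance is `pi^2/3`); the cohort-level estimate is the mean
#' over genes.
#'
#' @param synth A `synthetic_cohort`.
#' @param params Parameter set from [draw_sim_params()] (or a `sim_truth`).
#' @return The mean heritability, with per-gene values in attribute
#'   `"per_gene"`.
#' @export
estimate_heritability <- function(synth, params) {
  comp <- eta_components(synth, params)
  v_gen <- apply(comp$eta_gen, 2L, var)
  v_cov <- apply(comp$eta_cov, 2L, var)
  tot <- v_gen + v_cov + pi^2 / 3
  h2 <- ifelse(tot == 0, 0, v_gen / tot)
  structure(mean(h2), per_gene = h2)
}

#' Simulate per-gene phenotypes from the model
#'
#' Assembles each gene's linear predictor from the supplied (or freshly
#' drawn) parameters and samples per-gene Bernoulli phenotypes. The
#' estimated liability-scale heritability is controlled in one of two
#' ways: with `heritability_target` set, the gene-effect vector is
#' rescaled by a single constant so the mean heritability hits the
#' target (the *rescaled* effects are recorded as the truth); otherwise
#' parameter sets are rejection-sampled until the estimate falls at or
#' below `heritability_cap` (default 30%), erroring after `max_redraws`.
#'
#' @param synth A `synthetic_cohort`.
#' @param params Optional parameter set from [draw_sim_params()]; drawn
#'   internally when NULL.
#' @param seed Integer seed (phenotype sampling and any redraws).
#' @param include_intercept_tau Effect construction with (`TRUE`,
#'   default) or without the tau intercept component.
#' @param heritability_target Optional target mean heritability.
#' @param heritability_cap Rejection cap (default 0.30).
#' @param max_redraws Redraw limit for rejection sampling (default 100).
#' @param w_mismatch Passed to [draw_sim_params()] for internal draws.
#' @return List of class `sim_truth`: `alpha`, `w`, `tau`, `beta`
#'   (per-gene true variant effects), `Y` (n x M), `heritability`,
#'   `cohort` (a [cohort_data] carrying `Y` and the scaled covariates),
#'   `seed`.
#' @export
simulate_phenotypes <- function(synth, params = NULL, seed = 1L,
                                include_intercept_tau = TRUE,
                                heritability_target = NULL,
                                heritability_cap = 0.30,
                                max_redraws = 100L,
                                w_mismatch = FALSE) {
  rng <- local_rng(seed + 7L)
  draw_seed <- seed
  if (is.null(params))
    params <- draw_sim_params(synth, seed = draw_seed,
                              include_intercept_tau = include_intercept_tau,
                              w_mismatch = w_mismatch)
  if (!is.null(heritability_target)) {
    params <- rescale_to_heritability(synth, params, heritability_target)
  } else {
    tries <- 0L
    while (as.numeric(estimate_heritability(synth, params)) >
           heritability_cap) {
      tries <- tries + 1L
      if (tries > max_redraws)
        stop("heritability cap ", heritability_cap, " unattained after ",
             max_redraws, " redraws; consider heritability_target")
      draw_seed <- draw_seed + 1000L
      params <- draw_sim_params(synth, seed = draw_seed,
                                include_intercept_tau = include_intercept_tau,
                                w_mismatch = w_mismatch)
    }
  }
  comp <- eta_components(synth, params)
  mu <- plogis(comp$eta_cov + comp$eta_gen)
  Y <- matrix(rng$rbinom(length(mu), 1L, as.numeric(mu)),
              nrow(mu), ncol(mu))
  colnames(Y) <- names(synth$gene_data)
  h2 <- estimate_heritability(synth, params)
  tau_full <- if (params$include_intercept_tau) params$tau
              else c(0, params$tau)
  beta <- lapply(seq_along(synth$gene_data), function(g) {
    gd <- synth$gene_data[[g]]
    variant_effect(params$w[g], maf_weight(gd$maf), gd$Z, tau_full)
  })
  names(beta) <- names(synth$gene_data)
  cohort <- cohort_data(sample_ids = synth$sample_ids, Y = Y, X = synth$X,
                        scale_covariates = FALSE)
  structure(list(alpha = params$alpha, w = params$w, tau = params$tau,
                 include_intercept_tau = params$include_intercept_tau,
                 beta = beta, Y = Y,
                 heritability = as.numeric(h2),
                 heritability_per_gene = attr(h2, "per_gene"),
                 cohort = cohort, seed = seed),
            class = "sim_truth")
}

# one global rescaling of the gene effects so that the mean per-gene
# liability variance share equals the target; monotone in the scale, so
# a 1-d root-find suffices
rescale_to_heritability <- function(synth, params, target) {
  stopifnot(target > 0, target < 1)
  comp <- eta_components(synth, params)
  v_gen <- apply(comp$eta_gen, 2L, var)
  v_cov <- apply(comp$eta_cov, 2L, var)
  if (all(v_gen == 0)) stop("all genetic variance components are zero")
  f <- function(cc) mean(cc^2 * v_gen / (cc^2 * v_gen + v_cov + pi^2 / 3)) -
    target
  cc <- stats::uniroot(f, c(1e-8, 1e8), tol = 1e-12)$root
  params$w <- params$w * cc
  params
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$Y), "samples x", ncol(x$Y), "genes;",
      "mean heritability", signif(x$heritability, 3), "\n")
  invisible(x)
}

#' Parameter-recovery correlations
#'
#' Pearson correlation between true and estimated parameters, computed
#' separately for the flattened covariate-coefficient block (alpha), the
#' flattened per-variant effects (beta, reconstructed from the fitted
#' gene effects, MAF weights and annotation simplex), the gene-effect
#' vector (w) and the annotation-weight simplex (tau). A constant vector
#' makes the correlation undefined and yields NA.
#'
#' @param truth A `sim_truth`.
#' @param fit A `gruyere_fit` on the matching genes.
#' @param gene_data The per-gene inputs used in the fit.
#' @return data.frame with columns `parameter_block`, `pearson_r`.
#' @export
recovery_metrics <- function(truth, fit, gene_data) {
  genes <- fit$genes
  stopifnot(all(genes %in% names(truth$beta)))
  w_hat <- setNames(as.numeric(fit$w), genes)
  beta_hat <- unlist(lapply(genes, function(g) {
    gd <- gene_data[[g]]
    variant_effect(w_hat[[g]], maf_weight(gd$maf), gd$Z, fit$tau)
  }), use.names = FALSE)
  beta_true <- unlist(truth$beta[genes], use.names = FALSE)
  tau_true <- if (truth$include_intercept_tau) truth$tau else c(0, truth$tau)
  pairs <- list(
    alpha = cbind(as.numeric(truth$alpha[, genes]), as.numeric(fit$alpha)),
    beta = cbind(beta_true, beta_hat),
    w = cbind(as.numeric(truth$w[genes]), as.numeric(w_hat)),
    tau = cbind(tau_true, fit$tau))
  data.frame(
    parameter_block = names(pairs),
    pearson_r = vapply(pairs, function(m) {
      if (sd(m[, 1]) == 0 || sd(m[, 2]) == 0) return(NA_real_)
      cor(m[, 1], m[, 2])
    }, numeric(1)),
    row.names = NULL)
}

#' Parameter-recovery simulation study
#'
#' Repeats the full generate-simulate-fit-score cycle: draw a synthetic
#' cohort, draw ground-truth parameters, simulate per-gene phenotypes at
#' a heritability sampled from `heritability_range`, run the joint
#' variational fit, and score Pearson recovery per parameter block.
#' Individual simulation failures are recorded and the study continues.
#'
#' @param n_sims Number of simulations (0 returns an empty table).
#' @param spec A [cohort_spec()].
#' @param seed Master seed; per-simulation seeds derive from it.
#' @param heritability_range Mean-heritability band the simulations are
#'   targeted into (default 5–30%).
#' @param prior Inference prior ([gruyere_prior()]).
#' @param w_mismatch Prior-mismatch mode: simulate gene effects from
#'   Gamma(2, 2) while fitting with `prior`.
#' @param epochs,lr Passed to [gruyere()].
#' @return data.frame of class `gruyere_sim_study`: one row per
#'   simulation x parameter block (`sim_id`, `parameter_block`,
#'   `pearson_r`, `heritability`, `seed`, `error`).
#' @export
run_simulation_study <- function(n_sims = 10L, spec = cohort_spec(),
                                 seed = 1L,
                                 heritability_range = c(0.05, 0.30),
                                 prior = gruyere_prior(),
                                 w_mismatch = FALSE,
                                 epochs = 300L, lr = 0.1) {
  empty <- data.frame(sim_id = integer(), parameter_block = character(),
                      pearson_r = numeric(), heritability = numeric(),
                      seed = integer(), error = character())
  if (n_sims == 0L) return(structure(empty, class = c("gruyere_sim_study",
                                                      "data.frame")))
  rng <- local_rng(seed)
  targets <- rng$runif(n_sims, heritability_range[1], heritability_range[2])
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sim_seed <- seed + 131L * i
    rows[[i]] <- tryCatch({
      synth <- generate_cohort(spec, seed = sim_seed)
      truth <- simulate_phenotypes(synth, seed = sim_seed,
                                   heritability_target = targets[i],
                                   w_mismatch = w_mismatch)
      fit <- gruyere(truth$cohort, synth$gene_data, epochs = epochs,
                     lr = lr, seed = sim_seed, prior = prior,
                     train_only = FALSE)
      rec <- recovery_metrics(truth, fit, synth$gene_data)
      data.frame(sim_id = i, parameter_block = rec$parameter_block,
                 pearson_r = rec$pearson_r,
                 heritability = truth$heritability, seed = sim_seed,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(sim_id = i, parameter_block = NA_character_,
                 pearson_r = NA_real_, heritability = NA_real_,
                 seed = sim_seed, error = conditionMessage(e))
    })
  }
  structure(do.call(rbind, rows),
            class = c("gruyere_sim_study", "data.frame"))
}

#' @export
print.gruyere_sim_study <- function(x, ...) {
  ok <- x[is.na(x$error), , drop = FALSE]
  cat("gruyere simulation study:", length(unique(x$sim_id)),
      "simulations (", sum(!is.na(x$error)), "failed )\n")
  if (nrow(ok)) {
    agg <- tapply(ok$pearson_r, ok$parameter_block, mean, na.rm = TRUE)
    cat("mean Pearson R by block:\n")
    print(round(agg[c("alpha", "beta", "w", "tau")], 4))
    cat("heritability range:",
        paste(signif(range(ok$heritability), 3), collapse = " - "), "\n")
  }
  invisible(x)
}
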