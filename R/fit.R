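#' Prior settings for the joint fit
#'
#' Priors: `alpha_g ~ Normal(0, alpha_sd)`, `w_g ~ Normal(0, w_sd)` (or
#' Laplace with scale `w_sd` when `w_prior = "laplace"`), and
#' `tau ~ Dirichlet(conc)` over the (q+1)-simplex (intercept component
#' first). `dirichlet_conc = NULL` uses the sparsity-inducing default
#' `1/q`.
#'
#' @param alpha_sd Prior SD of covariate coefficients (default 1).
#' @param w_sd Prior SD/scale of the gene effect (default 1).
#' @param w_prior `"normal"` (default) or `"laplace"`.
#' @param dirichlet_conc Dirichlet concentration; NULL = `1/q`.
#' @return List of class `gruyere_prior`.
#' @export
gruyere_prior <- function(alpha_sd = 1, w_sd = 1,
                          w_prior = c("normal", "laplace"),
                          dirichlet_conc = NULL) {
  stopifnot(alpha_sd > 0, w_sd > 0)
  structure(list(alpha_sd = alpha_sd, w_sd = w_sd,
                 w_prior = match.arg(w_prior),
                 dirichlet_conc = dirichlet_conc),
            class = "gruyere_prior")
}

#' Assemble per-gene model inputs
#'
#' Slices a genotype block and a global annotation matrix into the
#' per-gene bundles (`G`, `Z`, `maf`) consumed by [gruyere()] and
#' [gruyere_gene_test()].
#'
#' @param block A [genotype_block] (imputed, QC'd).
#' @param gene_sets Named list from [build_gene_sets()].
#' @param Z Global p x q scaled annotation matrix with rownames matching
#'   `block$variant_ids` (or exactly aligned rows).
#' @return Named list: per gene a list with `G`, `Z`, `maf`.
#' @export
assemble_gene_data <- function(block, gene_sets, Z) {
  Z <- as.matrix(Z)
  if (!is.null(rownames(Z))) {
    idx <- match(block$variant_ids, rownames(Z))
    if (anyNA(idx)) stop("annotation matrix misses some block variants")
    Z <- Z[idx, , drop = FALSE]
  } else if (nrow(Z) != length(block$variant_ids)) {
    stop("annotation matrix rows do not align with the genotype block")
  }
  out <- lapply(gene_sets, function(gs) {
    i <- gs$variant_idx
    list(G = block$G[, i, drop = FALSE],
         Z = Z[i, , drop = FALSE],
         maf = block$maf[i])
  })
  names(out) <- names(gene_sets)
  out
}

#' Joint variational fit of annotation weights and gene effects
#'
#' Step 1 of the two-step procedure: fits the full hierarchy of per-gene
#' logistic models jointly over a (typically screened) set of genes by
#' stochastic variational inference, estimating the genome-wide
#' annotation-weight simplex `tau` as a point estimate while
#' approximating the posteriors of per-gene covariate coefficients
#' `alpha_g` and gene effects `w_g` with mean-field normal distributions.
#' Gradients of the evidence lower bound (ELBO) use the
#' reparameterization trick with one Monte Carlo sample per epoch and are
#' followed with the Adam optimizer (learning rate 0.1, 300 epochs by
#' default); posterior standard deviations are estimated from 50 draws of
#' the fitted guide.
#'
#' @param cohort A [cohort_data]; `cohort$Y` may be a vector (shared
#'   phenotype) or an n x M matrix of per-gene phenotypes (simulations).
#' @param gene_data Named list from [assemble_gene_data()] (or the
#'   simulator): per gene `G` (n x p dosages), `Z` (p x q annotations in
#'   \[0, 1\]) and `maf`.
#' @param epochs Training epochs (default 300).
#' @param lr Adam learning rate (default 0.1).
#' @param seed RNG seed; fixing it makes the fit reproducible.
#' @param n_posterior Posterior draws for standard-deviation estimates
#'   (default 50; 0 = use the closed-form guide SDs).
#' @param prior A [gruyere_prior()].
#' @param train_only Restrict to `split == "train"` samples when the
#'   cohort carries a split (default TRUE).
#' @param init `"irls"` (default) warm-starts each gene's variational
#'   means at the per-gene maximum-likelihood solution under a uniform
#'   annotation simplex, which decouples the early joint dynamics of
#'   gene effects and tau; `"zero"` starts all means at zero.
#' @param beta_maf_shape Beta shape parameters of the MAF weight.
#' @return Object of class `gruyere_fit` with elements `tau`, `alpha`
#'   (c x M posterior means), `alpha_sd`, `w`, `w_sd`, `elbo_trace`,
#'   `genes`, `annotation_names`, `config`.
#' @export
gruyere <- function(cohort, gene_data, epochs = 300L, lr = 0.1, seed = 1L,
                    n_posterior = 50L, prior = gruyere_prior(),
                    train_only = TRUE, init = c("irls", "zero"),
                    beta_maf_shape = c(1, 25)) {
  init <- match.arg(init)
  M <- length(gene_data)
  if (M < 2L) stop("joint fit needs at least 2 genes")
  keep <- if (train_only && !is.null(cohort$split)) cohort$split == "train"
          else rep(TRUE, length(cohort$sample_ids))
  X <- cohort$X[keep, , drop = FALSE]
  n <- nrow(X)
  Ymat <- if (is.matrix(cohort$Y)) cohort$Y[keep, , drop = FALSE]
          else matrix(cohort$Y[keep], n, M)
  if (ncol(Ymat) != M) stop("phenotype matrix columns must match genes")
  X <- add_intercept(X)
  c_cov <- ncol(X)
  q <- ncol(gene_data[[1L]]$Z)
  K <- q + 1L                        # tau length: intercept + annotations
  conc <- prior$dirichlet_conc %||% (1 / q)

  # design blocks: A_g tau = G (w_j * (tau0 + Z tau)) for any tau.
  # Each gene's genetic score is standardized to unit variance inside the
  # optimization (scale folded into the gene effect, gradient taken
  # through the normalizer): tau then controls only the *shape* of the
  # per-variant score, removing the curved scale ridge between tau and
  # w_g that otherwise stalls first-order updates.
  A_list <- lapply(gene_data, function(gd) {
    w_j <- maf_weight(gd$maf, beta_maf_shape[1], beta_maf_shape[2])
    cbind(gd$G[keep, , drop = FALSE] %*% w_j,
          gd$G[keep, , drop = FALSE] %*% (w_j * gd$Z))
  })
  C_list <- lapply(A_list, function(A) stats::cov(A))
  score_sd <- function(g, tau)
    sqrt(max(as.numeric(crossprod(tau, C_list[[g]] %*% tau)), 1e-24))

  rng <- local_rng(seed)
  sa2 <- prior$alpha_sd^2
  # variational parameters; with the IRLS warm start the means begin near
  # the per-gene ML solution, so the guide scales start small (0.01) —
  # a wide initial scale biases early tau updates toward low-information
  # directions through the E_q curvature penalty
  init_scale <- if (init == "irls") 0.01 else 0.1
  Ma <- matrix(0, c_cov, M); La <- matrix(log(init_scale), c_cov, M)
  mw <- numeric(M);          lw <- rep(log(init_scale), M)
  phi <- numeric(K)                  # softmax logits for tau
  if (init == "irls") {
    tau_u <- rep(1 / K, K)
    for (g in seq_len(M)) {
      q_u <- as.numeric(A_list[[g]] %*% tau_u) / score_sd(g, tau_u)
      ml <- tryCatch(logistic_irls(cbind(X, q_u), Ymat[, g]),
                     error = function(e) NULL)
      if (!is.null(ml) && !ml$separation) {
        Ma[, g] <- ml$coef[seq_len(c_cov)]
        mw[g] <- ml$coef[c_cov + 1L]
      }
    }
  }
  opt <- adam_state(list(Ma = Ma, La = La, mw = mw, lw = lw, phi = phi), lr)

  elbo_trace <- numeric(epochs)
  worse_run <- 0L
  for (ep in seq_len(epochs)) {
    p <- opt$params
    eps_a <- matrix(rng$rnorm(c_cov * M), c_cov, M)
    eps_w <- rng$rnorm(M)
    Sa <- exp(p$La); Sw <- exp(p$lw)
    A <- p$Ma + Sa * eps_a
    w <- p$mw + Sw * eps_w
    tau <- softmax(p$phi)
    sds <- vapply(seq_len(M), function(g) score_sd(g, tau), numeric(1))
    Q <- vapply(seq_len(M), function(g)
      as.numeric(A_list[[g]] %*% tau) / sds[g], numeric(n))
    eta <- X %*% A + sweep(Q, 2L, w, "*")
    mu <- plogis(eta)
    R <- Ymat - mu
    loglik <- sum(Ymat * eta - softplus(eta))
    logprior <- -0.5 * sum(A^2) / sa2 +
      w_logprior(w, prior) +
      (conc - 1) * sum(log(tau))
    entropy <- sum(p$La) + sum(p$lw)
    elbo <- loglik + logprior + entropy
    if (!is.finite(elbo))
      stop("non-finite ELBO at epoch ", ep, "; check inputs or lower lr")
    elbo_trace[ep] <- elbo
    if (ep > 1L && elbo < elbo_trace[ep - 1L]) {
      worse_run <- worse_run + 1L
      if (worse_run == 50L)
        warning("ELBO has worsened for 50 consecutive epochs (epoch ",
                ep, "): possible divergence")
    } else worse_run <- 0L

    gA <- crossprod(X, R) - A / sa2
    gw <- colSums(Q * R) + w_logprior_grad(w, prior)
    gtau <- (conc - 1) / tau
    for (g in seq_len(M)) {
      qr <- sum(Q[, g] * R[, g])
      gtau <- gtau + (w[g] / sds[g]) *
        (as.numeric(crossprod(A_list[[g]], R[, g])) -
           qr * as.numeric(C_list[[g]] %*% tau) / sds[g])
    }
    grads <- list(Ma = gA,
                  La = gA * (Sa * eps_a) + 1,
                  mw = gw,
                  lw = gw * (Sw * eps_w) + 1,
                  phi = tau * (gtau - sum(tau * gtau)))
    opt <- adam_step(opt, grads)
  }

  p <- opt$params
  tau_hat <- softmax(p$phi)
  names(tau_hat) <- c("(intercept)",
                      colnames(gene_data[[1L]]$Z) %||% paste0("Z", seq_len(q)))
  # undo the internal score standardization: reported gene effects are on
  # the natural scale of w_g * w_j * (tau0 + Z tau)
  sd_hat <- vapply(seq_len(M), function(g) score_sd(g, tau_hat), numeric(1))
  p$mw <- p$mw / sd_hat
  p$lw <- p$lw - log(sd_hat)
  if (n_posterior > 0L) {
    draws_w <- matrix(rng$rnorm(n_posterior * M), n_posterior, M)
    draws_w <- sweep(sweep(draws_w, 2L, exp(p$lw), "*"), 2L, p$mw, "+")
    w_sd <- apply(draws_w, 2L, sd)
    draws_a <- array(rng$rnorm(n_posterior * length(p$Ma)),
                     c(n_posterior, nrow(p$Ma), M))
    alpha_sd <- apply(draws_a, c(2L, 3L), sd) * exp(p$La)
  } else {
    w_sd <- exp(p$lw)
    alpha_sd <- exp(p$La)
  }
  dimnames(p$Ma) <- list(colnames(X), names(gene_data))
  dimnames(alpha_sd) <- dimnames(p$Ma)
  fit <- list(tau = tau_hat,
              alpha = p$Ma, alpha_sd = alpha_sd,
              w = setNames(p$mw, names(gene_data)),
              w_sd = setNames(w_sd, names(gene_data)),
              elbo_trace = elbo_trace,
              genes = names(gene_data),
              annotation_names = names(tau_hat),
              config = list(epochs = epochs, lr = lr, seed = seed,
                            n_posterior = n_posterior, prior = prior,
                            n_samples = n, n_genes = M,
                            beta_maf_shape = beta_maf_shape))
  class(fit) <- "gruyere_fit"
  fit
}

w_logprior <- function(w, prior) {
  switch(prior$w_prior,
         normal = -0.5 * sum(w^2) / prior$w_sd^2,
         laplace = -sum(abs(w)) / prior$w_sd)
}

w_logprior_grad <- function(w, prior) {
  switch(prior$w_prior,
         normal = -w / prior$w_sd^2,
         laplace = -sign(w) / prior$w_sd)
}

# numerically stable log(1 + exp(x))
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

add_intercept <- function(X) {
  constant <- apply(X, 2L, function(col) max(col) == min(col))
  if (any(constant)) return(X)
  cbind(`(intercept)` = 1, X)
}

adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

# ascent step (gradients of the objective being maximized)
adam_step <- function(st, grads) {
  st$t <- st$t + 1L
  for (nm in names(st$params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g^2
    mhat <- st$m[[nm]] / (1 - st$beta1^st$t)
    vhat <- st$v[[nm]] / (1 - st$beta2^st$t)
    st$params[[nm]] <- st$params[[nm]] + st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  st
}

#' @export
print.gruyere_fit <- function(x, ...) {
  cat("gruyere joint fit:", x$config$n_genes, "genes,",
      x$config$n_samples, "samples,", x$config$epochs, "epochs\n")
  cat("annotation weights (tau):\n")
  print(round(x$tau, 4))
  invisible(x)
}

#' @export
summary.gruyere_fit <- function(object, ...) {
  out <- list(tau = object$tau,
              w = data.frame(gene = object$genes, w = object$w,
                             sd = object$w_sd, row.names = NULL),
              elbo_final = object$elbo_trace[length(object$elbo_trace)],
              config = object$config)
  class(out) <- "summary.gruyere_fit"
  out
}

#' @export
print.summary.gruyere_fit <- function(x, ...) {
  cat("gruyere joint fit (", x$config$n_genes, " genes, ",
      x$config$n_samples, " samples)\n", sep = "")
  cat("final ELBO:", format(x$elbo_final, digits = 6), "\n\n")
  cat("annotation weights tau:\n"); print(round(x$tau, 4))
  cat("\ngene effects (head):\n")
  print(head(transform(x$w, w = round(w, 3), sd = round(sd, 3)), 10))
  invisible(x)
}

#' @export
coef.gruyere_fit <- function(object,
                             which = c("tau", "w", "alpha"), ...) {
  switch(match.arg(which),
         tau = object$tau, w = object$w, alpha = object$alpha)
}

#' @export
plot.gruyere_fit <- function(x, ...) {
  plot(seq_along(x$elbo_trace), x$elbo_trace, type = "l",
       xlab = "epoch", ylab = "ELBO (1-sample estimate)",
       main = "gruyere ELBO trace", ...)
  invisible(x)
}

#' Predicted case probabilities per gene
#'
#' Evaluates each gene's fitted logistic model (posterior-mean
#' parameters) on a cohort, returning the n x M matrix of predicted case
#' probabilities.
#'
#' @param object A `gruyere_fit`.
#' @param cohort A [cohort_data].
#' @param gene_data Per-gene inputs aligned with the fit's genes.
#' @param split Optional subset: `"train"`, `"test"` or NULL (all).
#' @param type `"prob"` (default) or `"link"`.
#' @param ... Unused.
#' @return n x M numeric matrix.
#' @export
predict.gruyere_fit <- function(object, cohort, gene_data, split = NULL,
                                type = c("prob", "link"), ...) {
  type <- match.arg(type)
  keep <- if (is.null(split)) rep(TRUE, length(cohort$sample_ids))
          else cohort$split == split
  X <- add_intercept(cohort$X[keep, , drop = FALSE])
  bm <- object$config$beta_maf_shape
  eta <- vapply(object$genes, function(g) {
    gd <- gene_data[[g]]
    s <- variant_scores(maf_weight(gd$maf, bm[1], bm[2]), gd$Z, object$tau)
    as.numeric(X %*% object$alpha[, g] +
                 object$w[g] * (gd$G[keep, , drop = FALSE] %*% s))
  }, numeric(sum(keep)))
  if (type == "link") eta else plogis(eta)
}

#' Simulate phenotypes from a fitted model
#'
#' Draws Bernoulli phenotypes from the fitted per-gene case
#' probabilities.
#'
#' @param object A `gruyere_fit`.
#' @param nsim Number of replicate draws (default 1).
#' @param seed RNG seed.
#' @param cohort,gene_data Data to predict on.
#' @param ... Unused.
#' @return A list of `nsim` n x M binary matrices.
#' @export
simulate.gruyere_fit <- function(object, nsim = 1, seed = 1L,
                                 cohort, gene_data, ...) {
  mu <- predict(object, cohort, gene_data)
  rng <- local_rng(seed)
  lapply(seq_len(nsim), function(i) {
    y <- rng$rbinom(length(mu), 1L, as.numeric(mu))
    matrix(y, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  })
}
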