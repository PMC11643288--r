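# Ridge-stabilized iteratively reweighted least squares for logistic
# regression. The small ridge (default 1e-6) keeps the Fisher information
# invertible under near-separation; separation itself is flagged by a
# large coefficient norm.
logistic_irls <- function(X, y, ridge = 1e-6, max_iter = 50L,
                          tol = 1e-10) {
  X <- as.matrix(X)
  beta <- numeric(ncol(X))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * wt) + diag(ridge, ncol(X))
    score <- crossprod(X, y - mu)
    beta_new <- beta + solve(H, score)
    dev <- -2 * sum(y * eta - softplus(eta))
    if (is.finite(dev) && abs(dev_old - dev) < tol * (abs(dev) + 1)) {
      beta <- as.numeric(beta_new); converged <- TRUE; break
    }
    beta <- as.numeric(beta_new)
    dev_old <- dev
  }
  eta <- as.numeric(X %*% beta)
  ll <- sum(y * eta - softplus(eta))
  H <- crossprod(X, X * pmax(plogis(eta) * (1 - plogis(eta)), 1e-10)) +
    diag(ridge, ncol(X))
  se <- sqrt(diag(solve(H)))
  list(coef = setNames(beta, colnames(X)), se = se, loglik = ll,
       converged = converged, separation = sqrt(sum(beta^2)) > 50)
}

#' Likelihood-ratio p-value for nested logistic models
#'
#' `LR = 2 * (ll_combined - ll_null)` referred to a chi-squared
#' distribution with 1 degree of freedom. Tiny negative LR values (down
#' to `-slack`) arising from finite optimization are clipped to 0; larger
#' violations of nesting are an error.
#'
#' @param ll_combined Log-likelihood of the covariate + genotype model.
#' @param ll_null Log-likelihood of the covariate-only model.
#' @param df Degrees of freedom (default 1).
#' @param slack Numerical slack (default 1e-8).
#' @return List with `lr_stat` and `p_value`.
#' @export
lrt_pvalue <- function(ll_combined, ll_null, df = 1L, slack = 1e-8) {
  lr <- 2 * (ll_combined - ll_null)
  if (lr < -slack)
    stop("combined model log-likelihood below the null beyond numerical ",
         "slack: nested-model violation (LR = ", format(lr), ")")
  lr <- max(lr, 0)
  list(lr_stat = lr, p_value = pchisq(lr, df = df, lower.tail = FALSE))
}

#' Per-gene association tests with tau fixed
#'
#' Step 2 of the procedure: with the annotation-weight simplex fixed,
#' each gene's model collapses to an ordinary logistic regression
#' `logit mu = X alpha_g + w_g * (G s_g)` where
#' `s_gj = w_j (tau0 + sum_k Z_gjk tau_k)` is a fixed per-variant score.
#' Maximum-likelihood fits of the combined and covariate-only models on
#' the same samples give a 1-df likelihood-ratio test per gene.
#' Separation or non-convergence yields a flagged row with NA p-value
#' rather than an error.
#'
#' @param cohort A [cohort_data].
#' @param gene_data Named per-gene list (`G`, `Z`, `maf`).
#' @param tau Fixed simplex of length q + 1 (e.g. `fit$tau`).
#' @param split Optional sample subset ("train"/"test"/NULL = all).
#' @param cell_type Optional label copied to the output.
#' @param beta_maf_shape Beta shape parameters of the MAF weight.
#' @param ridge IRLS ridge (default 1e-6).
#' @return data.frame with one row per gene: `gene`, `cell_type`,
#'   `n_variants`, `w_g`, `se`, `loglik_combined`,
#'   `loglik_covariates_only`, `lr_stat`, `p_value`, `flagged`.
#' @export
gruyere_gene_test <- function(cohort, gene_data, tau, split = NULL,
                              cell_type = NA_character_,
                              beta_maf_shape = c(1, 25), ridge = 1e-6) {
  keep <- if (is.null(split)) rep(TRUE, length(cohort$sample_ids))
          else cohort$split == split
  X <- add_intercept(cohort$X[keep, , drop = FALSE])
  Yall <- cohort$Y
  rows <- lapply(seq_along(gene_data), function(gi) {
    gd <- gene_data[[gi]]
    g <- names(gene_data)[gi]
    y <- if (is.matrix(Yall)) Yall[keep, gi] else Yall[keep]
    s <- variant_scores(maf_weight(gd$maf, beta_maf_shape[1],
                                   beta_maf_shape[2]), gd$Z, tau)
    score <- as.numeric(gd$G[keep, , drop = FALSE] %*% s)
    null_fit <- logistic_irls(X, y, ridge = ridge)
    full_fit <- logistic_irls(cbind(X, gene_score = score), y, ridge = ridge)
    flagged <- full_fit$separation || !full_fit$converged ||
      !null_fit$converged
    if (flagged) {
      lr <- NA_real_; p <- NA_real_
    } else {
      test <- lrt_pvalue(full_fit$loglik, null_fit$loglik)
      lr <- test$lr_stat; p <- test$p_value
    }
    data.frame(gene = g, cell_type = cell_type,
               n_variants = ncol(gd$G),
               w_g = unname(full_fit$coef["gene_score"]),
               se = unname(full_fit$se[length(full_fit$se)]),
               loglik_combined = full_fit$loglik,
               loglik_covariates_only = null_fit$loglik,
               lr_stat = lr, p_value = p, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni significance calls per cell type
#'
#' Threshold `alpha / number of tested genes` within each cell type;
#' genes are called significant at strictly `p < threshold`.
#'
#' @param results data.frame from [gruyere_gene_test()] (columns
#'   `p_value` and optionally `cell_type`).
#' @param alpha Family-wise error target (default 0.05).
#' @return The results with `threshold` and `significant` columns added.
#' @export
bonferroni_calls <- function(results, alpha = 0.05) {
  ct <- if ("cell_type" %in% names(results)) as.character(results$cell_type)
        else rep("all", nrow(results))
  ct[is.na(ct)] <- "all"
  thr <- ave(rep(alpha, nrow(results)), ct,
             FUN = function(a) a / length(a))
  results$threshold <- thr
  results$significant <- !is.na(results$p_value) & results$p_value < thr
  results
}

#' Screen genes for the joint fit
#'
#' Selects potentially trait-relevant genes at a lenient nominal
#' threshold (default p < 0.01), either from a supplied table of external
#' rare-variant test p-values or, when none is given, from a built-in
#' covariate-adjusted burden screen: the MAF-weighted burden score
#' `G w_j` is added to the covariate logistic model and tested by a 1-df
#' LRT.
#'
#' @param cohort A [cohort_data].
#' @param gene_data Named per-gene list (used by the built-in screen).
#' @param pvalues Optional named numeric vector or data.frame
#'   (`gene`, `p_value`) of external per-gene p-values.
#' @param threshold Nominal significance threshold (default 0.01).
#' @param split Sample subset for the built-in screen (default "train"
#'   when the cohort carries a split).
#' @param beta_maf_shape Beta shape parameters of the MAF weight.
#' @return Character vector of screened gene names.
#' @export
screen_genes <- function(cohort, gene_data = NULL, pvalues = NULL,
                         threshold = 0.01, split = NULL,
                         beta_maf_shape = c(1, 25)) {
  if (is.null(pvalues)) {
    if (is.null(gene_data)) stop("supply pvalues or gene_data")
    if (is.null(split) && !is.null(cohort$split)) split <- "train"
    flat_Z <- lapply(gene_data, function(gd) {
      gd$Z <- matrix(0, ncol(gd$G), 0L)   # burden screen ignores annotations
      gd
    })
    res <- gruyere_gene_test(cohort, flat_Z, tau = 1, split = split,
                             beta_maf_shape = beta_maf_shape)
    pvalues <- setNames(res$p_value, res$gene)
  } else if (is.data.frame(pvalues)) {
    pvalues <- setNames(pvalues$p_value, pvalues$gene)
  }
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1)))
    stop("p-values must lie in (0, 1]")
  kept <- names(pvalues)[!is.na(pvalues) & pvalues < threshold]
  if (length(kept) == 0L)
    stop("no genes pass the screen at p < ", threshold,
         "; consider a looser threshold")
  kept
}
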