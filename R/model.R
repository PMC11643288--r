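#' Minor-allele-frequency variant weight
#'
#' Weight for a rare variant as the Beta(1, 25) density evaluated at its
#' observed minor-allele frequency, following the convention of
#' frequency-weighted burden and kernel tests: rarer variants receive
#' larger weights. With the default shape parameters the weight is
#' `25 * (1 - maf)^24`, so `maf_weight(0) == 25` and the weight decreases
#' strictly with MAF.
#'
#' @param maf Numeric vector of minor-allele frequencies in \[0, 0.5\].
#' @param shape1,shape2 Beta density shape parameters (defaults 1 and 25).
#' @return Positive numeric vector of the same length as `maf`.
#' @examples
#' maf_weight(c(0, 0.01, 0.05))
#' @export
maf_weight <- function(maf, shape1 = 1, shape2 = 25) {
  if (any(!is.finite(maf)) || any(maf < 0) || any(maf > 1))
    stop("maf must lie in [0, 1]")
  if (any(maf > 0.5))
    warning("maf > 0.5 supplied; weights assume the minor allele is counted")
  dbeta(maf, shape1, shape2)
}

#' Fixed per-variant genetic score
#'
#' The tau-dependent part of the variant effect:
#' `s_j = w_j * (tau0 + sum_k Z_jk tau_k)`, where `w_j` is the MAF weight.
#' Multiplying by the scalar gene effect `w_g` gives the full per-variant
#' effect `beta_gj`. Keeping the score separate is what lets the per-gene
#' test reduce to a one-column logistic regression once tau is fixed.
#'
#' @param w_j Positive MAF weights, length p.
#' @param Z p x q annotation matrix with entries in \[0, 1\].
#' @param tau Simplex vector of length q + 1; the first element is the
#'   intercept weight `tau0`, the remaining q elements weight the columns
#'   of `Z`.
#' @return Numeric vector of length p.
#' @export
variant_scores <- function(w_j, Z, tau) {
  Z <- as.matrix(Z)
  if (length(tau) != ncol(Z) + 1L)
    stop("length(tau) must equal ncol(Z) + 1 (intercept + annotations)")
  if (length(w_j) != nrow(Z))
    stop("length(w_j) must equal nrow(Z)")
  as.numeric(w_j * (tau[1L] + Z %*% tau[-1L]))
}

#' Per-variant effect sizes
#'
#' `beta_gj = w_g * w_j * (tau0 + sum_k Z_gjk tau_k)`. Linear in `w_g`
#' and in each tau component; whenever `tau0 > 0` every effect shares the
#' sign of `w_g` (annotations are nonnegative), which is the burden-style
#' unidirectionality assumption of the model.
#'
#' @param w_g Scalar gene effect.
#' @param w_j MAF weights, length p.
#' @param Z p x q annotation matrix.
#' @param tau Length q + 1 simplex (intercept first).
#' @return Numeric vector of length p.
#' @export
variant_effect <- function(w_g, w_j, Z, tau) {
  stopifnot(length(w_g) == 1L)
  w_g * variant_scores(w_j, Z, tau)
}

#' Per-gene linear predictor
#'
#' `eta_i = X_i alpha + G_i beta`; the case probability is
#' `plogis(eta)`.
#'
#' @param X n x c covariate matrix.
#' @param alpha Covariate coefficients, length c.
#' @param G n x p dosage matrix.
#' @param beta Per-variant effects, length p.
#' @param gene Optional gene label used in error messages.
#' @return Numeric vector of n logits.
#' @export
linear_predictor <- function(X, alpha, G, beta, gene = NULL) {
  X <- as.matrix(X); G <- as.matrix(G)
  if (ncol(X) != length(alpha)) stop("ncol(X) != length(alpha)")
  if (ncol(G) != length(beta)) stop("ncol(G) != length(beta)")
  eta <- as.numeric(X %*% alpha + G %*% beta)
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor",
         if (!is.null(gene)) paste0(" for gene ", gene) else "")
  eta
}

# softmax with max-shift for numerical stability
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
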