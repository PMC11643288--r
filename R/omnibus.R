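#' Cauchy combination (ACAT) of p-values
#'
#' Combines possibly dependent p-values through the tangent transform:
#' `T = sum(w_i * tan((0.5 - p_i) * pi)) / sum(w_i)` and
#' `p_combined = 0.5 - atan(T) / pi`. For very small components the
#' standard approximation `tan((0.5 - p) pi) ~ 1/(p pi)` is used, and a
#' very large statistic maps back via `p ~ 1/(T pi)`, keeping the result
#' finite and inside (0, 1). A single p-value is returned unchanged.
#'
#' @param p Numeric vector of p-values in (0, 1\]; exact zeros are an
#'   error, exact ones are nudged to `1 - 1e-15` with a warning.
#' @param weights Nonnegative weights, equal by default.
#' @return Combined p-value.
#' @export
acat_combine <- function(p, weights = NULL) {
  if (length(p) == 0L) stop("no p-values to combine")
  if (any(is.na(p))) stop("NA p-values; drop them before combining")
  if (any(p <= 0)) stop("p-value of 0 (or below): Cauchy transform undefined")
  if (any(p > 1)) stop("p-values above 1")
  if (any(p == 1)) {
    warning("p-value(s) of exactly 1 nudged to 1 - 1e-15")
    p[p == 1] <- 1 - 1e-15
  }
  if (is.null(weights)) weights <- rep(1, length(p))
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative and not all zero")
  tiny <- p < 1e-16
  t_terms <- numeric(length(p))
  t_terms[tiny] <- 1 / (p[tiny] * pi)
  t_terms[!tiny] <- tan((0.5 - p[!tiny]) * pi)
  T_stat <- sum(weights * t_terms) / sum(weights)
  if (T_stat > 1e15) return(1 / (T_stat * pi))
  0.5 - atan(T_stat) / pi
}

#' Combine per-gene p-values across methods
#'
#' Builds one omnibus p-value per gene from a set of per-gene p-value
#' tables (e.g. this package's LRT plus external rare-variant tests).
#' Genes absent from a method are combined over the methods that do
#' cover them (logged); genes covered by a single method keep that
#' method's p-value. Bonferroni calls use [bonferroni_calls()].
#'
#' @param tables Named list of per-method tables; each either a named
#'   numeric vector or a data.frame with columns `gene` and `p_value`.
#' @param weights Optional named per-method weights (equal by default).
#' @param alpha Family-wise error target for the calls (default 0.05).
#' @return data.frame: `gene`, `n_methods`, `p_combined`, `threshold`,
#'   `significant`.
#' @export
combine_tables <- function(tables, weights = NULL, alpha = 0.05) {
  stopifnot(length(tables) >= 1L)
  as_vec <- function(tab) {
    if (is.data.frame(tab)) setNames(tab$p_value, tab$gene) else tab
  }
  vecs <- lapply(tables, as_vec)
  genes <- Reduce(union, lapply(vecs, names))
  if (length(genes) == 0L) stop("no genes found in any table")
  covered <- Reduce(intersect, lapply(vecs, names))
  if (length(covered) == 0L && length(vecs) > 1L)
    message("no gene is covered by every method; combining over ",
            "available methods per gene")
  rows <- lapply(genes, function(g) {
    ps <- vapply(vecs, function(v) if (g %in% names(v)) v[[g]] else NA_real_,
                 numeric(1))
    ok <- !is.na(ps)
    wts <- if (is.null(weights)) rep(1, sum(ok)) else weights[names(vecs)][ok]
    data.frame(gene = g, n_methods = sum(ok),
               p_value = acat_combine(ps[ok], wts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- bonferroni_calls(out, alpha = alpha)
  names(out)[names(out) == "p_value"] <- "p_combined"
  out
}
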