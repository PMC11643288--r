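#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUROC: the probability that a randomly chosen case scores
#' above a randomly chosen control, with ties counted half. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param y Binary outcome vector (0/1).
#' @param scores Numeric prediction scores.
#' @return AUROC in \[0, 1\], or NA (with a warning) when only one class
#'   is present.
#' @export
auroc <- function(y, scores) {
  stopifnot(length(y) == length(scores))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("only one class present: AUROC undefined")
    return(NA_real_)
  }
  r <- rank(scores)           # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average predicted probabilities across genes
#'
#' Per-sample arithmetic mean of per-gene predicted case probabilities,
#' the cross-gene ensemble score used for cohort-level prediction.
#'
#' @param mu n x M matrix (or list of per-gene probability vectors).
#' @return Numeric vector of length n.
#' @export
average_gene_predictions <- function(mu) {
  if (is.list(mu) && !is.data.frame(mu)) mu <- do.call(cbind, mu)
  mu <- as.matrix(mu)
  stopifnot(ncol(mu) >= 1L)
  rowMeans(mu)
}

#' Response residuals of the fitted per-gene models
#'
#' `y - mu` per sample and gene, on the requested split.
#'
#' @param object A `gruyere_fit`.
#' @param cohort,gene_data Data to evaluate on.
#' @param split Optional subset ("train"/"test"/NULL = all).
#' @param ... Unused.
#' @return n x M matrix of response residuals.
#' @export
residuals.gruyere_fit <- function(object, cohort, gene_data, split = NULL,
                                  ...) {
  mu <- predict(object, cohort, gene_data, split = split)
  keep <- if (is.null(split)) rep(TRUE, length(cohort$sample_ids))
          else cohort$split == split
  Y <- if (is.matrix(cohort$Y)) cohort$Y[keep, , drop = FALSE]
       else matrix(cohort$Y[keep], sum(keep), ncol(mu))
  Y - mu
}

#' Per-gene and averaged prediction metrics
#'
#' AUROC and accuracy (probability threshold 0.5) per gene and for the
#' cross-gene averaged score, on the requested split(s).
#'
#' @param fit A `gruyere_fit`.
#' @param cohort A [cohort_data] (with a split for train/test rows).
#' @param gene_data Per-gene inputs aligned with the fit.
#' @param splits Splits to evaluate (default both, falling back to "all"
#'   when the cohort has no split).
#' @return data.frame: `gene`, `split`, `auroc`, `accuracy`, `n`.
#' @export
prediction_report <- function(fit, cohort, gene_data,
                              splits = c("train", "test")) {
  if (is.null(cohort$split)) splits <- NA_character_
  rows <- list()
  for (sp in splits) {
    keep <- if (is.na(sp)) rep(TRUE, length(cohort$sample_ids))
            else cohort$split == sp
    mu <- predict(fit, cohort, gene_data,
                  split = if (is.na(sp)) NULL else sp)
    Y <- cohort$Y
    for (g in seq_along(fit$genes)) {
      y <- if (is.matrix(Y)) Y[keep, g] else Y[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = fit$genes[g], split = if (is.na(sp)) "all" else sp,
        auroc = suppressWarnings(auroc(y, mu[, g])),
        accuracy = mean((mu[, g] > 0.5) == y), n = sum(keep))
    }
    y_avg <- if (is.matrix(Y)) rowMeans(Y[keep, , drop = FALSE]) else Y[keep]
    if (all(y_avg %in% c(0, 1))) {
      avg <- average_gene_predictions(mu)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = "averaged", split = if (is.na(sp)) "all" else sp,
        auroc = suppressWarnings(auroc(y_avg, avg)),
        accuracy = mean((avg > 0.5) == y_avg), n = sum(keep))
    }
  }
  do.call(rbind, rows)
}
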