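#' Drop annotation columns with excess missingness
#'
#' Removes raw annotation columns whose missing fraction over the variant
#' universe in scope exceeds `missing_max` (default 5%).
#'
#' @param raw data.frame/matrix of raw annotation values (NA = missing).
#' @param missing_max Maximum tolerated missing fraction (default 0.05).
#' @return The table without the offending columns.
#' @export
drop_sparse_annotations <- function(raw, missing_max = 0.05) {
  raw <- as.data.frame(raw)
  miss <- vapply(raw, function(x) mean(is.na(x)), numeric(1))
  drop <- miss > missing_max
  if (all(drop)) stop("all annotation columns exceed the missingness limit")
  if (any(drop))
    message("dropped annotation(s) at >", 100 * missing_max, "% missing: ",
            paste(names(raw)[drop], collapse = ", "))
  raw[, !drop, drop = FALSE]
}

#' Min-max scale an annotation column to \[0, 1\]
#'
#' Larger scaled values always mean more predicted function: when
#' `higher_is_functional = FALSE` the column orientation is flipped
#' before scaling.
#'
#' @param x Numeric vector with finite min < max.
#' @param higher_is_functional Direction flag (default TRUE).
#' @return Scaled vector in \[0, 1\].
#' @export
minmax_scale <- function(x, higher_is_functional = TRUE) {
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r))) stop("column has no finite values")
  if (r[1] == r[2])
    stop("constant annotation column: remove it rather than scaling")
  if (!higher_is_functional) x <- -x
  r <- range(x, na.rm = TRUE)
  (x - r[1]) / (r[2] - r[1])
}

# rank-1 NMF by multiplicative updates: V (p x m, nonnegative) ~ w h'
nmf_rank1 <- function(V, n_iter = 500L, tol = 1e-6, seed = 1L) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("NMF requires nonnegative input")
  rng <- local_rng(seed)
  w <- rng$runif(nrow(V), 0.1, 1)
  h <- rng$runif(ncol(V), 0.1, 1)
  err_old <- Inf
  for (it in seq_len(n_iter)) {
    h <- h * as.numeric(crossprod(V, w)) / (sum(w^2) * h + 1e-12)
    w <- w * as.numeric(V %*% h) / (sum(h^2) * w + 1e-12)
    err <- sum((V - tcrossprod(w, h))^2)
    if (abs(err_old - err) < tol * (err_old + 1e-12)) break
    err_old <- err
  }
  list(w = w, h = h, sse = sum((V - tcrossprod(w, h))^2), iterations = it)
}

#' Composite annotation score for a category via rank-1 NMF
#'
#' Summarizes a group of related (already scaled, nonnegative) annotation
#' columns into one composite score: the variant-side factor of a rank-1
#' non-negative matrix factorization, min-max rescaled to \[0, 1\].
#' Deterministic under a fixed seed. A single-column category passes
#' through unchanged (after rescale).
#'
#' @param V p x m matrix of nonnegative columns of one category.
#' @param n_iter,tol Multiplicative-update iteration cap and relative
#'   convergence tolerance.
#' @param seed RNG seed for the factor initialization.
#' @return Numeric composite column, length p, in \[0, 1\].
#' @export
nmf_group_score <- function(V, n_iter = 500L, tol = 1e-6, seed = 1L) {
  V <- as.matrix(V)
  if (ncol(V) == 1L) return(minmax_scale(V[, 1L]))
  fac <- nmf_rank1(V, n_iter = n_iter, tol = tol, seed = seed)
  minmax_scale(fac$w)
}

#' Splice-disruption composite: maximum of the four delta scores
#'
#' The splicing category is summarized as the elementwise maximum of the
#' four splice delta scores (acceptor/donor gain/loss), each in \[0, 1\].
#' Missing components are treated as 0 (no predicted disruption) with a
#' message.
#'
#' @param S p x 4 matrix (or data.frame) of splice delta scores.
#' @return Numeric vector of per-variant maxima.
#' @export
splice_max <- function(S) {
  S <- as.matrix(S)
  if (anyNA(S)) {
    message(sum(is.na(S)), " missing splice score(s) treated as 0")
    S[is.na(S)] <- 0
  }
  if (any(S < 0 | S > 1)) stop("splice delta scores must lie in [0, 1]")
  apply(S, 1L, max)
}

#' Aggregate assay delta scores into composite max/min columns
#'
#' Each assay column is Z-scored against supplied background statistics
#' (mean/sd per assay from a large reference variant collection); the
#' per-variant extremes over the trait-enriched assays are then taken and
#' min-max scaled to \[0, 1\]. `max_delta` is the magnitude of the
#' largest positive-direction Z-score (signal gain), `min_delta` the
#' magnitude of the most negative Z-score (signal loss).
#'
#' @param deltas p x a matrix of raw delta scores, columns named by assay.
#' @param enriched_assays Character vector of assay columns to aggregate.
#' @param background_stats data.frame with columns `assay`, `mean`, `sd`.
#' @return data.frame with columns `max_delta`, `min_delta`, both in
#'   \[0, 1\].
#' @export
delta_aggregate <- function(deltas, enriched_assays, background_stats) {
  deltas <- as.matrix(deltas)
  if (length(enriched_assays) == 0L) stop("enriched assay list is empty")
  absent <- setdiff(enriched_assays, colnames(deltas))
  if (length(absent))
    stop("assay(s) absent from delta matrix: ", paste(absent, collapse = ", "))
  bs <- background_stats[match(enriched_assays, background_stats$assay), ]
  if (anyNA(bs$mean) || anyNA(bs$sd))
    stop("background stats missing for some enriched assays")
  Zs <- sweep(sweep(deltas[, enriched_assays, drop = FALSE], 2L, bs$mean),
              2L, bs$sd, "/")
  hi <- apply(Zs, 1L, max)   # most positive Z: predicted signal gain
  lo <- apply(Zs, 1L, min)   # most negative Z: predicted signal loss
  data.frame(max_delta = minmax_scale_or_zero(pmax(hi, 0)),
             min_delta = minmax_scale_or_zero(pmax(-lo, 0)))
}

# constant column (e.g. no variant with signal in that direction) -> zeros
minmax_scale_or_zero <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Assemble the scaled annotation matrix Z
#'
#' Full preprocessing path from a raw per-variant annotation table to the
#' p x q matrix consumed by the model: drop sparse columns, impute the
#' residual missing entries as 0 (least functional), min-max scale each
#' column with its direction flag, then collapse each configured category
#' to one composite column (rank-1 NMF; the splicing category uses the
#' elementwise maximum instead). Columns not assigned to any category are
#' kept as-is after scaling.
#'
#' @param raw data.frame of raw annotations keyed by variant
#'   (`variant_id` column optional; row order is preserved).
#' @param categories Named list: category -> character vector of column
#'   names. A category named `"splicing"` is combined with [splice_max()].
#' @param directions Named logical vector (column -> higher-is-functional
#'   flag); unnamed columns default to TRUE.
#' @param missing_max Column-missingness limit (default 0.05).
#' @param seed Seed for NMF initialization.
#' @return List with `Z` (matrix, entries in \[0, 1\]),
#'   `annotation_names`, and `group_map`.
#' @export
build_annotation_matrix <- function(raw, categories = list(),
                                    directions = NULL, missing_max = 0.05,
                                    seed = 1L) {
  raw <- as.data.frame(raw)
  variant_ids <- raw$variant_id
  raw$variant_id <- NULL
  raw <- drop_sparse_annotations(raw, missing_max)
  n_imputed <- sum(is.na(as.matrix(raw)))
  if (n_imputed > 0) {
    message(n_imputed, " residual missing annotation value(s) imputed as 0")
    raw[is.na(raw)] <- 0
  }
  scaled <- as.data.frame(lapply(names(raw), function(nm) {
    hif <- if (!is.null(directions) && nm %in% names(directions))
      directions[[nm]] else TRUE
    minmax_scale(raw[[nm]], higher_is_functional = hif)
  }))
  names(scaled) <- names(raw)
  group_map <- list()
  out <- list()
  used <- character()
  for (cat_name in names(categories)) {
    cols <- intersect(categories[[cat_name]], names(scaled))
    if (length(cols) == 0L) next
    used <- c(used, cols)
    group_map[[cat_name]] <- cols
    out[[cat_name]] <- if (identical(cat_name, "splicing"))
      splice_max(scaled[, cols, drop = FALSE])
    else nmf_group_score(as.matrix(scaled[, cols, drop = FALSE]), seed = seed)
  }
  for (nm in setdiff(names(scaled), used)) out[[nm]] <- scaled[[nm]]
  Z <- do.call(cbind, out)
  rownames(Z) <- variant_ids
  list(Z = Z, annotation_names = colnames(Z), group_map = group_map)
}

#' Read a raw annotation table keyed by variant id
#'
#' TSV with a `variant_id` column (`chr:pos:ref:alt`) and numeric
#' annotation columns; empty cells are missing.
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_annotation_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  if (!"variant_id" %in% names(tab))
    stop("annotation table needs a variant_id column")
  tab
}

#' Read an annotation category configuration (YAML)
#'
#' Expected layout: a top-level `categories` mapping of category name to
#' a list of raw column names, and an optional `directions` mapping of
#' column name to `true`/`false` (higher-is-functional flag).
#'
#' @param path YAML file path.
#' @return List with elements `categories` and `directions`.
#' @export
read_annotation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(categories = cfg$categories %||% list(),
       directions = unlist(cfg$directions %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
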