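#' Cohort container: phenotypes, covariates, split labels
#'
#' Bundles sample identifiers, a binary phenotype vector (0 = control,
#' 1 = case), a covariate matrix min-max scaled to \[0, 1\], optional
#' ancestry labels, and (after [split_train_test()]) a train/test flag
#' per sample.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param Y Binary phenotype vector (0/1), no missing values. May also be
#'   an n x M matrix of per-gene phenotypes (used by the simulator).
#' @param X n x c numeric covariate matrix; scaled to \[0, 1\] unless
#'   `scale_covariates = FALSE`.
#' @param ancestry Optional character/factor of ancestry labels.
#' @param split Optional character vector with entries "train"/"test".
#' @param scale_covariates Min-max scale each covariate column (default TRUE).
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(sample_ids, Y, X, ancestry = NULL, split = NULL,
                        scale_covariates = TRUE) {
  X <- as.matrix(X)
  n <- length(sample_ids)
  Ym <- if (is.matrix(Y)) Y else matrix(Y, ncol = 1L)
  if (nrow(Ym) != n || nrow(X) != n)
    stop("sample_ids, Y and X imply different sample counts")
  if (anyNA(Ym)) stop("missing phenotypes are not allowed")
  if (!all(Ym %in% c(0, 1))) stop("phenotypes must be 0/1")
  if (scale_covariates) X <- apply(X, 2L, scale01)
  rownames(X) <- sample_ids
  obj <- list(sample_ids = as.character(sample_ids),
              Y = if (ncol(Ym) == 1L) as.numeric(Ym) else Ym,
              X = X,
              ancestry = if (is.null(ancestry)) NULL else as.character(ancestry),
              split = split)
  class(obj) <- "cohort_data"
  obj
}

scale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(rep(0, length(x)))  # constant column -> 0
  (x - r[1]) / (r[2] - r[1])
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", length(x$sample_ids), "samples,",
      ncol(x$X), "covariates\n")
  if (is.matrix(x$Y)) {
    cat("  per-gene phenotypes:", ncol(x$Y), "genes, mean case fraction",
        signif(mean(x$Y), 3), "\n")
  } else {
    cat("  cases:", sum(x$Y), " controls:", sum(1 - x$Y), "\n")
  }
  if (!is.null(x$split))
    cat("  split:", sum(x$split == "train"), "train /",
        sum(x$split == "test"), "test\n")
  invisible(x)
}

#' Read covariate/phenotype table
#'
#' Tab-separated file with a mandatory `sample_id` column, a phenotype
#' column, and any number of numeric covariate columns (min-max scaled on
#' load).
#'
#' @param path Path to a TSV file.
#' @param phenotype_col Name of the 0/1 phenotype column.
#' @param ancestry_col Optional name of an ancestry label column.
#' @return A [cohort_data] object.
#' @export
read_cohort <- function(path, phenotype_col = "phenotype",
                        ancestry_col = NULL) {
  tab <- read.delim(path, check.names = FALSE)
  if (!"sample_id" %in% names(tab)) stop("missing mandatory sample_id column")
  if (!phenotype_col %in% names(tab))
    stop("phenotype column '", phenotype_col, "' not found")
  drop <- c("sample_id", phenotype_col, ancestry_col)
  covars <- tab[, setdiff(names(tab), drop), drop = FALSE]
  if (!all(vapply(covars, is.numeric, logical(1))))
    stop("non-numeric covariate columns present")
  cohort_data(sample_ids = tab$sample_id,
              Y = tab[[phenotype_col]],
              X = as.matrix(covars),
              ancestry = if (!is.null(ancestry_col)) tab[[ancestry_col]])
}

#' Genotype block constructor
#'
#' A block of rare-variant dosages for a set of samples: an n x p matrix
#' in \[0, 2\] (fractional after mean imputation), per-variant positions
#' (1-based VCF convention) and observed minor-allele frequencies.
#'
#' @param variant_ids Character vector, length p.
#' @param positions data.frame with columns contig, pos, ref, alt.
#' @param G n x p dosage matrix (NA allowed before imputation).
#' @param sample_ids Character vector, length n.
#' @param maf Optional per-variant MAF; recomputed from `G` when NULL.
#' @return An object of class `genotype_block`.
#' @export
genotype_block <- function(variant_ids, positions, G, sample_ids,
                           maf = NULL) {
  G <- as.matrix(G)
  stopifnot(length(variant_ids) == ncol(G),
            nrow(positions) == ncol(G),
            length(sample_ids) == nrow(G))
  dimnames(G) <- list(sample_ids, variant_ids)
  if (is.null(maf)) maf <- observed_maf(G)
  obj <- list(variant_ids = as.character(variant_ids),
              positions = positions, G = G,
              sample_ids = as.character(sample_ids), maf = maf)
  class(obj) <- "genotype_block"
  obj
}

#' @export
print.genotype_block <- function(x, ...) {
  cat("genotype_block:", nrow(x$G), "samples x", ncol(x$G), "variants\n")
  cat("  MAF range:", signif(min(x$maf), 3), "-", signif(max(x$maf), 3),
      "; missing entries:", sum(is.na(x$G)), "\n")
  invisible(x)
}

# allele frequency of the counted allele on non-missing calls
observed_maf <- function(G) {
  colMeans(G, na.rm = TRUE) / 2
}

#' Load rare-variant genotypes
#'
#' Reads genotypes from a VCF (v4.x, GT field, via \pkg{vcfR}) or a
#' whitespace-delimited dosage text file (header row of variant ids
#' formatted `contig:pos:ref:alt`, first column `sample_id`, entries in
#' \{0, 1, 2, NA\}). Multiallelic records are dropped; at each site the
#' *minor* allele is counted, so dosages are flipped (`2 - d`) where the
#' ALT allele frequency exceeds 0.5; variants with observed MAF above
#' `maf_max` are removed. MAF is computed on non-missing calls only.
#'
#' @param path File path.
#' @param format `"vcf"` or `"dosage"`.
#' @param maf_max Retain variants with observed MAF \eqn{\le} this value
#'   (default 0.05).
#' @return A [genotype_block].
#' @export
load_genotypes <- function(path, format = c("vcf", "dosage"),
                           maf_max = 0.05) {
  format <- match.arg(format)
  if (format == "vcf") blk <- read_vcf_block(path) else blk <- read_dosage_block(path)
  filter_by_maf(blk, maf_max)
}

read_vcf_block <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unparseable VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  bi <- !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "." & !is.na(fix$ALT)
  n_drop <- sum(!bi)
  if (n_drop > 0)
    message(n_drop, " multiallelic/blank-ALT record(s) dropped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]
  dos <- gt_to_dosage(gt)           # p x n
  positions <- data.frame(contig = fix$CHROM,
                          pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT,
                          stringsAsFactors = FALSE)
  ids <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
  genotype_block(variant_ids = ids, positions = positions,
                 G = t(dos), sample_ids = colnames(gt))
}

# GT strings -> dosage of ALT allele; tolerates phased separators
gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  known <- clean %in% c(names(lut), "./.", ".", NA)
  if (any(!known & !is.na(clean))) {
    bad <- which(!known & !is.na(clean), arr.ind = TRUE)[1, ]
    stop("unparseable GT '", gt[bad[1], bad[2]], "' at record ", bad[1])
  }
  hit <- match(clean, names(lut))
  d[] <- lut[hit]
  d
}

read_dosage_block <- function(path) {
  tab <- read.table(path, header = TRUE, check.names = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("dosage file must start with a sample_id column")
  ids <- names(tab)[-1]
  G <- as.matrix(tab[, -1, drop = FALSE])
  if (any(!is.na(G) & !(G %in% c(0, 1, 2))))
    stop("dosage entries must be 0, 1, 2 or NA")
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("variant ids must be contig:pos:ref:alt")
  positions <- data.frame(contig = vapply(parts, `[`, "", 1L),
                          pos = as.integer(vapply(parts, `[`, "", 2L)),
                          ref = vapply(parts, `[`, "", 3L),
                          alt = vapply(parts, `[`, "", 4L),
                          stringsAsFactors = FALSE)
  genotype_block(variant_ids = ids, positions = positions, G = G,
                 sample_ids = tab$sample_id)
}

# orient each site to count the minor allele, then apply the MAF ceiling
filter_by_maf <- function(blk, maf_max) {
  af <- observed_maf(blk$G)
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    blk$G[, flip] <- 2 - blk$G[, flip]
    af[flip] <- 1 - af[flip]
  }
  blk$maf <- af
  keep <- !is.na(af) & af <= maf_max
  n_rm <- sum(!keep)
  if (n_rm > 0) message(n_rm, " variant(s) removed at MAF > ", maf_max)
  out <- subset_block(blk, variants = which(keep))
  if (ncol(out$G) == 0L)
    warning("all variants filtered; returning an empty block")
  out
}

subset_block <- function(blk, samples = NULL, variants = NULL) {
  if (!is.null(samples)) {
    blk$G <- blk$G[samples, , drop = FALSE]
    blk$sample_ids <- blk$sample_ids[samples]
  }
  if (!is.null(variants)) {
    blk$G <- blk$G[, variants, drop = FALSE]
    blk$variant_ids <- blk$variant_ids[variants]
    blk$positions <- blk$positions[variants, , drop = FALSE]
    blk$maf <- blk$maf[variants]
  }
  blk
}

#' Sample and variant quality-control filter
#'
#' Removes samples whose genotype-missingness fraction exceeds
#' `sample_missing_max`, *then* removes variants whose call rate among the
#' remaining samples falls below `variant_callrate_min`. The order
#' (samples first, then variants) is fixed. MAF is recomputed on the
#' surviving samples by default.
#'
#' @param block A [genotype_block] with missingness still encoded as NA.
#' @param cohort Optional [cohort_data]; filtered to the surviving samples.
#' @param sample_missing_max Maximum tolerated per-sample missing fraction
#'   (default 0.10).
#' @param variant_callrate_min Minimum per-variant call rate (default 0.90).
#' @param recompute_maf Recompute MAF after sample removal (default TRUE).
#' @return The filtered block, or `list(block, cohort)` when a cohort is
#'   supplied.
#' @export
qc_filter <- function(block, cohort = NULL, sample_missing_max = 0.10,
                      variant_callrate_min = 0.90, recompute_maf = TRUE) {
  for (thr in c(sample_missing_max, variant_callrate_min))
    if (!is.numeric(thr) || thr <= 0 || thr > 1)
      stop("QC thresholds must lie in (0, 1]")
  miss_s <- rowMeans(is.na(block$G))
  keep_s <- miss_s <= sample_missing_max
  if (any(!keep_s))
    message(sum(!keep_s), " sample(s) removed at missingness > ",
            sample_missing_max)
  block <- subset_block(block, samples = which(keep_s))
  callrate <- colMeans(!is.na(block$G))
  keep_v <- callrate >= variant_callrate_min
  if (any(!keep_v))
    message(sum(!keep_v), " variant(s) removed at call rate < ",
            variant_callrate_min)
  block <- subset_block(block, variants = which(keep_v))
  if (recompute_maf) block$maf <- observed_maf(block$G)
  if (is.null(cohort)) return(block)
  idx <- match(block$sample_ids, cohort$sample_ids)
  cohort$sample_ids <- cohort$sample_ids[idx]
  cohort$Y <- if (is.matrix(cohort$Y)) cohort$Y[idx, , drop = FALSE] else cohort$Y[idx]
  cohort$X <- cohort$X[idx, , drop = FALSE]
  if (!is.null(cohort$ancestry)) cohort$ancestry <- cohort$ancestry[idx]
  if (!is.null(cohort$split)) cohort$split <- cohort$split[idx]
  list(block = block, cohort = cohort)
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing dosage with the expected dosage `2 * MAF` of its
#' variant (MAF computed on non-missing calls), so per-variant allele
#' frequency estimates are unchanged by imputation. Set
#' `value = "maf"` to impute the MAF itself instead of the expected
#' dosage.
#'
#' @param block A [genotype_block].
#' @param value `"expected_dosage"` (2 x MAF, default) or `"maf"`.
#' @return The block with no missing entries.
#' @export
impute_missing <- function(block, value = c("expected_dosage", "maf")) {
  value <- match.arg(value)
  if (!anyNA(block$G)) return(block)
  if (any(colSums(!is.na(block$G)) == 0L))
    stop("variant(s) with zero observed calls: MAF undefined, cannot impute")
  fill <- if (value == "expected_dosage") 2 * block$maf else block$maf
  idx <- which(is.na(block$G), arr.ind = TRUE)
  block$G[idx] <- fill[idx[, 2L]]
  block
}

#' Stratified train/test split
#'
#' Randomly assigns each sample to the training or test set, stratified
#' by ancestry when available (one stratum otherwise). Per-stratum train
#' counts are `round(train_frac * stratum size)`; the assignment is
#' deterministic under a fixed seed. Strata with fewer than 2 samples go
#' wholly to train with a warning.
#'
#' @param cohort A [cohort_data].
#' @param train_frac Training fraction in (0, 1), default 0.8.
#' @param seed Integer RNG seed.
#' @return The cohort with `$split` set to "train"/"test".
#' @export
split_train_test <- function(cohort, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  strata <- if (is.null(cohort$ancestry)) rep("all", length(cohort$sample_ids))
            else cohort$ancestry
  split <- character(length(strata))
  rng <- local_rng(seed)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2L) {
      warning("stratum '", s, "' has < 2 samples; placed wholly in train")
      split[idx] <- "train"
      next
    }
    n_train <- round(train_frac * length(idx))
    train_idx <- rng$sample(idx, n_train)
    split[idx] <- "test"
    split[train_idx] <- "train"
  }
  cohort$split <- split
  cohort
}

# Self-contained RNG stream: keeps package functions from disturbing the
# caller's .Random.seed and makes seeds composable.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    st
  }
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    sample = function(x, size) with_state(sample(x, size)),
    runif = function(n, ...) with_state(runif(n, ...)),
    rnorm = function(n, ...) with_state(rnorm(n, ...)),
    rbinom = function(n, ...) with_state(rbinom(n, ...)),
    rbeta = function(n, ...) with_state(rbeta(n, ...)),
    rgamma = function(n, ...) with_state(rgamma(n, ...)),
    rgen = function(expr_fun) with_state(expr_fun())
  )
}
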