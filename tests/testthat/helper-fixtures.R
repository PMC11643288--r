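# Fixture builders shared across test files. Everything is generated in
# code (written to tempfiles where a reader is under test).

# Write a minimal VCF with given per-variant genotype string vectors.
write_toy_vcf <- function(gt_rows, pos, ref, alt, contig = "chr1",
                          path = tempfile(fileext = ".vcf")) {
  n <- length(gt_rows[[1L]])
  ids <- sprintf("S%03d", seq_len(n))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_along(gt_rows), function(i)
    paste(c(contig, pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}

# genotype string vector with a given count of hets and missing calls
gt_vec <- function(n, n_het = 0L, n_hom = 0L, n_miss = 0L,
                   miss_at = NULL, het_at = NULL) {
  g <- rep("0/0", n)
  if (!is.null(het_at)) g[het_at] <- "0/1"
  else if (n_het > 0L) g[seq_len(n_het)] <- "0/1"
  if (n_hom > 0L) g[n - seq_len(n_hom) + 1L] <- "1/1"
  if (!is.null(miss_at)) g[miss_at] <- "./."
  else if (n_miss > 0L) g[n_het + seq_len(n_miss)] <- "./."
  g
}

# small deterministic genotype block built directly (no file round-trip)
toy_block <- function(G, contig = "chr1", pos = NULL) {
  G <- as.matrix(G)
  p <- ncol(G)
  if (is.null(pos)) pos <- seq_len(p) * 100L
  positions <- data.frame(contig = rep(contig, p), pos = pos,
                          ref = rep("A", p), alt = rep("T", p),
                          stringsAsFactors = FALSE)
  ids <- paste(contig, pos, "A", "T", sep = ":")
  genotype_block(ids, positions, G, sprintf("S%03d", seq_len(nrow(G))))
}

toy_cohort <- function(n, seed = 1L, n_cov = 3L, ancestry = NULL) {
  set.seed(seed)
  cohort_data(sample_ids = sprintf("S%03d", seq_len(n)),
              Y = rbinom(n, 1, 0.5),
              X = matrix(runif(n * n_cov), n,
                         dimnames = list(NULL, paste0("c", seq_len(n_cov)))),
              ancestry = ancestry)
}

# brute-force interval membership: variant POS (1-based) inside
# half-open 0-based [start, end) <=> start <= pos - 1 < end
brute_force_gene_counts <- function(cres, block, cell_type, abc_min) {
  cres <- cres[cres$CellType == cell_type & cres$`ABC.Score` >= abc_min, ]
  sets <- list()
  for (i in seq_len(nrow(cres))) {
    for (v in seq_along(block$variant_ids)) {
      p0 <- block$positions$pos[v] - 1L
      if (block$positions$contig[v] == cres$chr[i] &&
          p0 >= cres$start[i] && p0 < cres$end[i]) {
        g <- cres$TargetGene[i]
        sets[[g]] <- union(sets[[g]], block$variant_ids[v])
      }
    }
  }
  sets
}

# independent Newton-Raphson logistic regression (test oracle; no ridge)
nr_logistic <- function(X, y, max_iter = 100L, tol = 1e-12) {
  X <- as.matrix(X)
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  list(coef = beta, loglik = sum(y * eta - log(1 + exp(eta))))
}

# quick simulated dataset for inference tests
quick_sim <- function(n = 600L, M = 8L, p = 40L, seed = 1L, h2 = 0.2,
                      ...) {
  spec <- cohort_spec(n = n, M = M, variants_per_gene = p,
                      c_covariates = 4L, q_annotations = 4L)
  synth <- generate_cohort(spec, seed = seed)
  truth <- simulate_phenotypes(synth, seed = seed,
                               heritability_target = h2, ...)
  list(synth = synth, truth = truth)
}
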