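test_that("VCF loading keeps biallelic sites at or below the MAF ceiling", {
  n <- 50L
  # MAFs: 1/100 = 0.01, 4/100 = 0.04, 20/100 = 0.20, triallelic, all-ref
  path <- write_toy_vcf(
    list(gt_vec(n, n_het = 1L), gt_vec(n, n_het = 4L),
         gt_vec(n, n_het = 20L), gt_vec(n, n_het = 2L), gt_vec(n)),
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = rep("A", 5), alt = c("T", "C", "G", "T,C", "G"))
  blk <- suppressMessages(load_genotypes(path, maf_max = 0.05))
  # the 0.20 site and the triallelic are gone; the monomorphic site stays
  expect_setequal(blk$positions$pos, c(100L, 200L, 500L))
  expect_equal(unname(blk$maf[order(blk$positions$pos)]),
               c(0.01, 0.04, 0))
})

test_that("sites where ALT is the major allele are flipped to minor dosage", {
  n <- 50L
  path <- write_toy_vcf(
    list(c(rep("1/1", 48), "0/1", "0/1")),  # ALT freq 0.98, minor = REF
    pos = 100L, ref = "A", alt = "T")
  blk <- load_genotypes(path, maf_max = 0.05)
  expect_equal(ncol(blk$G), 1L)
  expect_equal(unname(blk$maf), 0.02)
  expect_equal(sum(blk$G), 2)  # two het carriers of the minor (REF) allele
})

test_that("dosage text reader round-trips and rejects bad entries", {
  G <- rbind(c(0, 1), c(2, 0), c(0, NA))
  tab <- data.frame(sample_id = c("a", "b", "c"),
                    `chr1:10:A:T` = G[, 1], `chr2:20:G:C` = G[, 2],
                    check.names = FALSE)
  f <- tempfile(); write.table(tab, f, row.names = FALSE, quote = FALSE)
  blk <- suppressMessages(load_genotypes(f, format = "dosage", maf_max = 0.5))
  expect_equal(unname(blk$G[, "chr1:10:A:T"]), G[, 1])
  tab2 <- tab; tab2[1, 2] <- 3
  f2 <- tempfile(); write.table(tab2, f2, row.names = FALSE, quote = FALSE)
  expect_error(load_genotypes(f2, format = "dosage"), "0, 1, 2 or NA")
})

test_that("QC removes samples first, then variants, matching a mask oracle", {
  set.seed(7)
  n <- 20L; p <- 50L
  G <- matrix(rbinom(n * p, 2L, 0.05), n, p)
  G[sample(length(G), 120L)] <- NA   # planted missingness
  blk <- toy_block(G)
  out <- suppressMessages(qc_filter(blk, sample_missing_max = 0.10,
                                    variant_callrate_min = 0.90))
  # independent mask computation
  keep_s <- rowMeans(is.na(G)) <= 0.10
  keep_v <- colMeans(!is.na(G[keep_s, , drop = FALSE])) >= 0.90
  expect_equal(nrow(out$G), sum(keep_s))
  expect_equal(ncol(out$G), sum(keep_v))
  expect_equal(unname(out$G), unname(G[keep_s, keep_v, drop = FALSE]))
  # idempotence
  out2 <- suppressMessages(qc_filter(out))
  expect_identical(out2$G, out$G)
})

test_that("QC thresholds outside (0, 1] are a configuration error", {
  blk <- toy_block(matrix(0, 4, 2))
  expect_error(qc_filter(blk, sample_missing_max = 0), "\\(0, 1\\]")
  expect_error(qc_filter(blk, variant_callrate_min = 1.2), "\\(0, 1\\]")
})

test_that("imputation fills 2 x MAF and preserves allele frequencies", {
  # variant with MAF 0.02 on observed calls and one missing entry
  G <- matrix(0, 25, 2)
  G[1, 1] <- 1       # 1/48 alleles -> MAF on observed calls
  G[3, 1] <- NA
  blk <- toy_block(G)
  expect_equal(unname(blk$maf[1]), 1 / 48)
  imp <- impute_missing(blk)
  expect_equal(unname(imp$G[3, 1]), 2 * (1 / 48))
  expect_false(anyNA(imp$G))
  # mean dosage / 2 equals the observed MAF before and after imputation
  expect_equal(unname(colMeans(imp$G) / 2), unname(blk$maf))
  # the maf variant (configurable interpretation) fills MAF itself
  expect_equal(unname(impute_missing(blk, value = "maf")$G[3, 1]), 1 / 48)
  # no-missing block returns bit-identical
  blk2 <- toy_block(matrix(c(0, 1, 0, 2), 2, 2))
  expect_identical(impute_missing(blk2), blk2)
})

test_that("imputation errors on a variant with zero observed calls", {
  G <- matrix(c(NA, NA, 0, 1), 2, 2)
  blk <- toy_block(G)
  expect_error(impute_missing(blk), "zero observed calls")
})

test_that("train/test split is a stratified, seeded partition", {
  co <- toy_cohort(100L, seed = 3)
  sp <- split_train_test(co, train_frac = 0.8, seed = 11)
  expect_equal(sum(sp$split == "train"), 80L)
  expect_setequal(unique(sp$split), c("train", "test"))
  # two strata 60/40 -> 48 and 32 train labels
  co2 <- toy_cohort(100L, seed = 3,
                    ancestry = rep(c("EUR", "AFR"), c(60L, 40L)))
  sp2 <- split_train_test(co2, 0.8, seed = 11)
  expect_equal(unname(table(sp2$split, sp2$ancestry)["train", c("EUR", "AFR")]),
               c(48L, 32L))
  # determinism and partition property
  sp3 <- split_train_test(co2, 0.8, seed = 11)
  expect_identical(sp2$split, sp3$split)
  expect_false(identical(sp2$split,
                         split_train_test(co2, 0.8, seed = 12)$split))
  # singleton stratum goes wholly to train with a warning
  co3 <- toy_cohort(11L, seed = 3, ancestry = c(rep("A", 10), "B"))
  expect_warning(sp4 <- split_train_test(co3, 0.8, seed = 1), "wholly in train")
  expect_equal(sp4$split[11], "train")
})

test_that("covariates are scaled to [0, 1] and phenotypes validated", {
  f <- tempfile()
  write.table(data.frame(sample_id = c("a", "b", "c"), phenotype = c(0, 1, 1),
                         age = c(60, 80, 100), pc1 = c(-2, 0, 2)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  co <- read_cohort(f)
  expect_true(all(co$X >= 0 & co$X <= 1))
  expect_equal(unname(co$X[, "age"]), c(0, 0.5, 1))
  f2 <- tempfile()
  write.table(data.frame(sample_id = "a", phenotype = 2, age = 60),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(f2), "0/1")
})
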