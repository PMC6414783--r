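test_that("median-of-ratios size factors behave as defined", {
  m <- matrix(rep(c(10, 100, 1000), 3), nrow = 3,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
  norm <- median_of_ratios_normalize(m)
  expect_equal(unname(norm$size_factors), c(1, 1, 1))
  expect_equal(norm$normalized, m)

  # hand computation: geometric means (sqrt(200), sqrt(20000), sqrt(2e6)),
  # per-sample ratios are constant 1/sqrt(2) and sqrt(2)
  m2 <- matrix(c(10, 100, 1000, 20, 200, 2000), nrow = 3,
               dimnames = list(paste0("t", 1:3), c("a", "b")))
  norm2 <- median_of_ratios_normalize(m2)
  expect_equal(unname(norm2$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(norm2$normalized[, "a"], norm2$normalized[, "b"])

  # scale equivariance: doubling one column doubles its factor ratio
  set.seed(1)
  m3 <- matrix(rpois(200, 50) + 1, ncol = 2)
  m3 <- cbind(m3, m3[, 1] * 2)
  sf <- median_of_ratios_normalize(m3)$size_factors
  expect_equal(sf[3] / sf[1], 2)

  expect_error(median_of_ratios_normalize(matrix(c(0, 1, 1, 0), 2)),
               "positive")
})

test_that("normalization is idempotent and matches the DESeq2 oracle", {
  set.seed(42)
  m <- matrix(rnbinom(40 * 10, mu = 100, size = 5) + 1, nrow = 40,
              dimnames = list(paste0("t", 1:40), paste0("s", 1:10)))
  norm <- median_of_ratios_normalize(m)
  renorm <- median_of_ratios_normalize(norm$normalized)
  expect_equal(unname(renorm$size_factors), rep(1, 10), tolerance = 1e-9)

  skip_if_not_installed("DESeq2")
  # DESeq2 leaves the overall scale free; compare after centering its
  # factors to geometric mean 1
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  sf_ref <- sf_ref / exp(mean(log(sf_ref)))
  expect_equal(unname(norm$size_factors), unname(sf_ref),
               tolerance = 1e-12)
})

test_that("expressed-transcript filter counts positive individuals", {
  m <- rbind(a = c(1, 2, 3, rep(0, 16)),
             b = c(5, 9, rep(0, 17)),
             c = rep(0, 19),
             d = rep(1, 19))
  expect_equal(expressed_transcripts(m), c("a", "d"))
  expect_equal(expressed_transcripts(m, min_individuals = 2),
               c("a", "b", "d"))
})

test_that("LD r-squared is symmetric, relabel-invariant and NA-safe", {
  g1 <- c(0, 0, 1, 1, 2, 2)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  g2 <- c(0, 1, 0, 1, 2, 2)
  # independent hand computation from the definition
  r_hand <- (mean(g1 * g2) - mean(g1) * mean(g2)) /
    sqrt((mean(g1^2) - mean(g1)^2) * (mean(g2^2) - mean(g2)^2))
  expect_equal(ld_r2(g1, g2), r_hand^2)
  expect_equal(ld_r2(g1, g2), ld_r2(g2, g1))
  expect_true(is.na(ld_r2(g1, rep(1, 6))))
  expect_equal(ld_r2(c(g1, NA), c(g2, 0)), ld_r2(g1, g2))
})

test_that("LD partner discovery is intra-chromosomal with an inclusive cut", {
  g <- rbind(snpA = c(0, 0, 1, 1, 2, 2),
             snpB = c(0, 0, 1, 1, 2, 2),
             snpC = c(0, 1, 0, 1, 2, 2),
             snpD = c(0, 0, 1, 1, 2, 2))
  colnames(g) <- paste0("i", 1:6)
  chrom <- c(snpA = "chr1", snpB = "chr1", snpC = "chr1", snpD = "chr2")
  partners <- ld_partners("snpA", g, chrom, r2_min = 0.75)
  expect_true("snpB" %in% partners$partner)
  expect_false("snpD" %in% partners$partner)   # same genotypes, other chrom
  expect_true("snpA" %in% partners$partner)    # self, r2 = 1
  expect_equal(partners$r2[partners$partner == "snpA"], 1)

  r2_ac <- ld_r2(g["snpA", ], g["snpC", ])
  at <- ld_partners("snpA", g, chrom, r2_min = r2_ac)
  expect_true("snpC" %in% at$partner)          # threshold is inclusive
  above <- ld_partners("snpA", g, chrom, r2_min = r2_ac + 1e-9)
  expect_false("snpC" %in% above$partner)

  # SNPs with missing genotypes never enter as partners
  g2 <- g; g2["snpB", 1] <- NA
  p2 <- ld_partners("snpA", g2, chrom, r2_min = 0.75)
  expect_false("snpB" %in% p2$partner)
})

test_that("Spearman rho and p behave across exact and approximate paths", {
  # tied dosages get average ranks: rho computed by hand from the ranks
  x <- c(0, 0, 1, 1, 2)
  expect_equal(spearman_test(x, c(1, 2, 3, 4, 5))$rho,
               cor(c(1.5, 1.5, 3.5, 3.5, 5), 1:5))
  expect_equal(spearman_test(1:6, 6:1)$rho, -1)
  expect_equal(spearman_test(1:6, 1:6)$p_value, 2 / factorial(6))

  # exact path vs a Monte-Carlo permutation oracle (n = 6)
  set.seed(7)
  xs <- rnorm(6); ys <- xs + rnorm(6)
  exact <- spearman_test(xs, ys)
  mc <- mc_spearman_p(xs, ys, 20000)
  expect_lt(abs(exact$p_value - mc),
            3 * sqrt(mc * (1 - mc) / 20000) + 1e-3)

  # t approximation vs the permutation oracle at the cohort size n = 19
  set.seed(8)
  g <- sample(0:2, 19, replace = TRUE)
  e <- 300 * 1.4^g + rnorm(19, sd = 60)
  appr <- spearman_test(g, e)
  mc <- mc_spearman_p(g, e, 10000)
  expect_lt(abs(appr$p_value - mc), 3 * sqrt(mc * (1 - mc) / 10000) + 0.01)

  expect_error(spearman_test(1:3, 1:3), ">= 4")
  expect_warning(r <- spearman_test(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r$rho))
})

test_that("genotype-expression correlation recovers direction", {
  # dosage groups 8/7/4 with decreasing mean expression, like an eQTL where
  # the reference allele drives higher expression
  set.seed(12)
  dosage <- rep(0:2, times = c(8, 7, 4))
  expr <- c(rnorm(8, 404, 20), rnorm(7, 323, 20), rnorm(4, 214, 20))
  r <- genotype_expression_correlation(dosage, expr)
  expect_lt(r$rho, -0.6)
  expect_lt(r$p_value, 0.05)
})

test_that("per-transcript Bonferroni caps and gates significance", {
  res <- data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8", "s9", "s10"),
    transcript = c("t1", rep("t2", 4), rep("t3", 5)),
    rho = c(0.9, 0.7, 0.5, -0.8, 0.61, rep(0.2, 5)),
    p_value = c(0.002, 0.01, 0.01, 0.01, 0.2, rep(0.4, 5)))
  out <- bonferroni_per_transcript(res)
  expect_equal(out$q_value[1], 0.002)            # m = 1: q = p
  expect_equal(out$q_value[2], 0.04)             # m = 4: q = 4p
  expect_true(all(out$q_value[6:10] == 1))       # capped at 1
  expect_true(out$significant[1])
  expect_true(out$significant[2])                # |rho| > 0.6 and q < 0.05
  expect_false(out$significant[3])               # |rho| too small
  expect_false(out$significant[5])               # q too large
})

test_that("a planted two-fold cis effect is recovered; a null is not", {
  rec <- vapply(1:40, function(i) cis_recovery_replicate(4000 + i), NA)
  expect_gte(mean(rec, na.rm = TRUE), 0.9)
  null_rec <- vapply(1:40, function(i) {
    cis_recovery_replicate(6000 + i, effect_size = 1)
  }, NA)
  expect_lte(mean(null_rec, na.rm = TRUE), 0.10)
})
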