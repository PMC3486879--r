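# Additive-model association, q-values, filters, t-tests and LD.

si_from_pheno <- function(y, exon = "E1", samples = NULL) {
  samples <- samples %||% sprintf("S%03d", seq_along(y))
  m <- matrix(1 - y, nrow = 1, dimnames = list(exon, samples))
  structure(m, mode = "ratio")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

geno_row <- function(x, snp = "rs1", allele = "G", samples = NULL) {
  samples <- samples %||% sprintf("S%03d", seq_along(x))
  m <- matrix(as.integer(x), nrow = 1, dimnames = list(snp, samples))
  genotype_matrix(m, stats::setNames(allele, snp))
}

test_that("a perfectly linear phenotype gives R^2 = 1 and the counted allele", {
  x <- rep(0:2, each = 10)
  g <- geno_row(x)
  si <- si_from_pheno(0.1 * x)
  res <- associate(g, si, data.frame(snp_id = "rs1", exon_id = "E1"))
  expect_equal(res$beta, 0.1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)
  expect_equal(res$skipping_allele, "G")
})

test_that("recoding the counted allele flips beta and the skipping allele", {
  set.seed(5)
  x <- rbinom(60, 2, 0.4)
  y <- 0.05 * x + abs(rnorm(60, 0, 0.04))
  snps <- snp_table(data.frame(snp_id = "rs1", chrom = "1", pos = 1,
                               ref = "A", alt = "G"))
  r1 <- associate(geno_row(x, allele = "G"), si_from_pheno(y),
                  data.frame(snp_id = "rs1", exon_id = "E1"), snps = snps)
  r2 <- associate(geno_row(2L - x, allele = "A"), si_from_pheno(y),
                  data.frame(snp_id = "rs1", exon_id = "E1"), snps = snps)
  expect_equal(r2$beta, -r1$beta)
  expect_equal(r2$p_value, r1$p_value)
  expect_equal(r2$r_squared, r1$r_squared)
  expect_equal(r1$skipping_allele, "G")
  expect_equal(r2$skipping_allele, "G")
})

test_that("monomorphic SNPs are flagged untestable and excluded from FDR", {
  g <- geno_row(rep(1L, 20))
  si <- si_from_pheno(runif(20))
  res <- associate(g, si, data.frame(snp_id = "rs1", exon_id = "E1"))
  expect_false(res$testable)
  expect_true(is.na(res$q_value))
})

test_that("p-values are calibrated under dosage permutation", {
  set.seed(17)
  y <- abs(rnorm(80, 0, 0.05))
  x <- rbinom(80, 2, 0.3)
  ps <- replicate(2000, {
    ols <- associate(geno_row(sample(x)), si_from_pheno(y),
                     data.frame(snp_id = "rs1", exon_id = "E1"),
                     compute_q = FALSE)
    ols$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.05)
})

test_that("q-values with pi0 = 1 equal Benjamini-Hochberg exactly", {
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(5:400, 1))^sample(1:3, 1)
    expect_equal(qvalues(p, pi0 = 1), p.adjust(p, method = "BH"))
  }
})

test_that("q-values are monotone in p-rank, order-invariant, and bounded", {
  set.seed(8)
  p <- runif(500)^2
  q <- qvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  perm <- sample(length(p))
  expect_equal(qvalues(p[perm]), q[perm])
  expect_equal(qvalues(rep(1, 150)), rep(1, 150))
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("hit filtering uses strict inequalities at all three thresholds", {
  base <- data.frame(snp_id = "rs", exon_id = "E", beta = 1, intercept = 0,
                     n_used = 100L, testable = TRUE, skipping_allele = "A")
  mk <- function(p, q, r2) cbind(base, p_value = p, q_value = q, r_squared = r2)
  expect_equal(nrow(filter_hits(mk(0.05, 0.05, 0.1))), 0L)   # p at boundary
  expect_equal(nrow(filter_hits(mk(0.01, 0.08, 0.03))), 0L)  # R2 at boundary
  expect_equal(nrow(filter_hits(mk(0.01, 0.10, 0.05))), 0L)  # q at boundary
  expect_equal(nrow(filter_hits(mk(0.01, 0.08, 0.05))), 1L)
})

test_that("genotype-group t-test handles identical, shifted and degenerate input", {
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("GG", "GT"), each = 4)
  r <- genotype_group_ttest(v, g, "GG", "GT")
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  # degenerate: both groups constant
  r0 <- genotype_group_ttest(rep(1, 8), g, "GG", "GT")
  expect_false(r0$testable)
  # calibration and power
  set.seed(21)
  p_null <- replicate(2000, {
    x <- rnorm(15); y <- rnorm(15)
    genotype_group_ttest(c(x, y), rep(c("a", "b"), each = 15), "a", "b")$p_value
  })
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.02)
  p_shift <- replicate(300, {
    x <- rnorm(30); y <- rnorm(30, mean = 2)
    genotype_group_ttest(c(x, y), rep(c("a", "b"), each = 30), "a", "b")$p_value
  })
  expect_gt(mean(p_shift < 0.001), 0.9)
})

test_that("LD estimates recover known haplotype structure", {
  set.seed(31)
  # identical dosage vectors: complete LD
  x <- rbinom(300, 2, 0.4)
  g <- genotype_matrix(rbind(snpA = x, snpB = x),
                       c(snpA = "A", snpB = "A"))
  colnames(g) <- sprintf("S%03d", 1:300)
  ld <- pairwise_ld(g, "snpA", "snpB")
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_equal(ld$d_prime, 1, tolerance = 1e-6)
  # independent SNPs: r2 near 0
  g0 <- simulate_ld_pair(4000, 0.3, 0.4, r = 0)
  ld0 <- pairwise_ld(g0, "snpA", "snpB")
  expect_lt(ld0$r2, 0.01)
  # D' = 1 with unequal frequencies gives r2 < 1
  r_target <- 0.12 / sqrt(0.2 * 0.8 * 0.4 * 0.6)  # D = pA(1-pB): one missing haplotype
  g1 <- simulate_ld_pair(4000, 0.2, 0.4, r = r_target)
  ld1 <- pairwise_ld(g1, "snpA", "snpB")
  expect_equal(ld1$d_prime, 1, tolerance = 0.05)
  expect_lt(ld1$r2, 0.6)
  expect_equal(ld1$r2, 0.375, tolerance = 0.08)
  # monomorphic SNP flagged
  gm <- genotype_matrix(rbind(snpA = rep(0L, 50), snpB = rbinom(50, 2, 0.5)),
                        c(snpA = "A", snpB = "A"))
  colnames(gm) <- sprintf("S%03d", 1:50)
  expect_false(pairwise_ld(gm, "snpA", "snpB")$testable)
})
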