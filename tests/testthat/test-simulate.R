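# Synthetic-data generator: determinism, plant/recover consistency and
# distributional structure.

test_that("identical config and seed give identical output", {
  a <- simulate_study(sim_config(seed = 20, n_genes = 6L, n_samples = 30L))
  b <- simulate_study(sim_config(seed = 20, n_genes = 6L, n_samples = 30L))
  expect_identical(a$genome$seqs, b$genome$seqs)
  expect_identical(as.data.frame(a$models), as.data.frame(b$models))
  expect_identical(as.data.frame(a$snps), as.data.frame(b$snps))
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$exon_expr, b$exon_expr)
  expect_identical(a$trait_catalog$snp_id, b$trait_catalog$snp_id)
  c <- simulate_study(sim_config(seed = 21, n_genes = 6L, n_samples = 30L))
  expect_false(identical(a$genome$seqs, c$genome$seqs))
})

test_that("cassette_fraction = 0 yields no skipped exons", {
  s <- simulate_study(sim_config(seed = 4, n_genes = 8L, n_samples = 20L,
                                 cassette_fraction = 0))
  expect_equal(nrow(find_skipped_exons(s$models)), 0L)
  expect_equal(nrow(s$truth$planted), 0L)
})

test_that("every planted SNP is recovered with its motif and position", {
  s <- small_study(seed = 31, n_genes = 20L, n_samples = 20L)
  scan <- call_ise_snps(s$snps, s$genome, s$motifs)
  pl <- s$truth$planted
  expect_gt(nrow(pl), 5L)
  expect_true(all(pl$snp_id %in% ise_snp_ids(scan)))
  for (k in seq_len(nrow(pl))) {
    hr <- scan$profiles[[pl$snp_id[k]]]$hits_ref
    expect_true(any(hr$motif == pl$motif[k] &
                      hr$snp_pos_in_motif == pl$pos_in_motif[k]))
    # the alternate allele disrupts: no alt-window hit at all
    expect_equal(nrow(scan$profiles[[pl$snp_id[k]]]$hits_alt), 0L)
  }
  # every planted cassette exon is found by the skipped-exon detector
  sk <- find_skipped_exons(s$models)
  expect_true(all(pl$exon_id %in%
                    sprintf("%s:%d-%d", sk$gene_id, sk$start, sk$end)))
})

test_that("planted links are recovered with the recorded side and distance", {
  s <- small_study(seed = 32, n_genes = 15L, n_samples = 20L)
  sk <- find_skipped_exons(s$models)
  links <- link_ise_snp_to_exons(s$snps[s$snps$snp_id %in%
                                          s$truth$planted$snp_id, ],
                                 s$models, sk)
  pl <- s$truth$planted
  for (k in seq_len(nrow(pl))) {
    l <- links[links$snp_id == pl$snp_id[k] & links$exon_id == pl$exon_id[k], ]
    expect_equal(nrow(l), 1L)
    expect_true(l$is_skipped)
    expect_equal(l$side, pl$side[k])
    expect_equal(l$distance_bp, pl$distance_bp[k])
  }
})

test_that("genotypes follow Hardy-Weinberg at the assigned MAF", {
  cfg <- sim_config(seed = 9, n_samples = 4000L)
  snps <- snp_table(data.frame(snp_id = c("a", "b"), chrom = "1",
                               pos = c(1L, 2L), ref = "A", alt = "G",
                               class = "intronic", maf = c(0, 0.3)))
  g <- simulate_genotypes(cfg, snps)
  expect_true(all(g["a", ] == 0L))
  p <- 0.3
  obs <- table(factor(g["b", ], levels = 0:2))
  gof <- suppressWarnings(chisq.test(obs, p = c((1 - p)^2, 2 * p * (1 - p), p^2)))
  expect_gt(gof$p.value, 0.01)
  expect_equal(mean(g["b", ]), 2 * p, tolerance = 0.05)
})

test_that("SI is centered at 1 for dosage-0 samples and shifts with dosage", {
  cfg <- sim_config(seed = 12, n_genes = 15L, n_samples = 600L)
  sim <- simulate_genome_and_annotation(cfg)
  g <- simulate_genotypes(cfg, sim$snps)
  ex <- simulate_expression(cfg, sim, g)
  pl <- sim$truth$planted
  skip <- sapply(seq_len(nrow(pl)), function(k) {
    d <- as.numeric(g[pl$snp_id[k], ])
    si <- ex$si_true[pl$exon_id[k], ]
    c(mean(si[d == 0]), mean(abs(1 - si[d == 0])), mean(abs(1 - si[d == 2])))
  })
  # E[SI] = 1 at dosage 0 (deviations are sign-symmetric)
  expect_equal(mean(skip[1, ]), 1, tolerance = 0.01)
  # |1-SI| grows by ~2*beta_skip from dosage 0 to 2
  expect_equal(mean(skip[3, ] - skip[2, ], na.rm = TRUE), 2 * cfg$beta_skip,
               tolerance = 0.03)
  # non-cassette exons stay near 1
  other <- setdiff(rownames(ex$si_true), pl$exon_id)
  expect_equal(mean(ex$si_true[other, ]), 1, tolerance = 0.01)
})

test_that("the trait catalog respects q0 and planted enrichment", {
  cfg0 <- sim_config(seed = 14, n_genes = 10L, trait_q0 = 0)
  sim <- simulate_genome_and_annotation(cfg0)
  expect_equal(nrow(simulate_trait_catalog(cfg0, sim)), 0L)
  # with odds >> 1, planted SNPs are over-represented
  cfg5 <- sim_config(seed = 14, n_genes = 40L, trait_q0 = 0.05,
                     trait_enrichment_odds = 10)
  sim5 <- simulate_genome_and_annotation(cfg5)
  cat5 <- simulate_trait_catalog(cfg5, sim5)
  pl <- sim5$truth$planted$snp_id
  rate_planted <- mean(pl %in% cat5$snp_id)
  rate_bg <- mean(setdiff(sim5$snps$snp_id, pl) %in% cat5$snp_id)
  expect_gt(rate_planted, rate_bg)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(intron_len = c(10L, 20L)), "30 bp")
  expect_error(sim_config(cassette_fraction = 1.5))
  expect_error(sim_config(beta_skip = -0.1))
})
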