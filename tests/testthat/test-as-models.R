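# Skipped-exon detection and SNP-exon linking.

cassette_gene <- function() {
  # isoform A = e1,e2,e3 ; isoform B = e1,e3 (canonical cassette)
  gene_models(data.frame(
    gene_id = "G1",
    transcript_id = c("A", "A", "A", "B", "B"),
    chrom = "1", strand = "+",
    start = c(100L, 300L, 500L, 100L, 500L),
    end = c(200L, 400L, 600L, 200L, 600L)))
}

test_that("a canonical cassette exon is detected and terminal exons never are", {
  sk <- find_skipped_exons(cassette_gene())
  expect_equal(nrow(sk), 1L)
  expect_equal(sk$start, 300L)
  expect_equal(sk$end, 400L)
  expect_equal(sk$inclusion_isoforms, "A")
  expect_equal(sk$exclusion_isoforms, "B")
})

test_that("single-isoform genes yield no skipped exons", {
  gm <- gene_models(data.frame(gene_id = "G1", transcript_id = "A",
                               chrom = "1", strand = "+",
                               start = c(1L, 100L, 200L), end = c(50L, 150L, 250L)))
  expect_equal(nrow(find_skipped_exons(gm)), 0L)
})

test_that("result is independent of transcript input order", {
  gm <- rbind_shuffled <- as.data.frame(cassette_gene())
  set.seed(1)
  shuffled <- gene_models(gm[sample(nrow(gm)), ])
  expect_equal(find_skipped_exons(shuffled), find_skipped_exons(cassette_gene()))
})

test_that("skipped exons equal the brute-force all-pairs comparison", {
  set.seed(99)
  for (i in 1:200) {
    gm <- rand_gene_model()
    expect_equal(skipped_keys(find_skipped_exons(gm)), brute_skipped(gm))
  }
})

test_that("strict cassette mode requires the flanking exons in the excluder", {
  # excluding isoform lacks the downstream flank as well -> not strict-cassette
  gm <- gene_models(data.frame(
    gene_id = "G1",
    transcript_id = c("A", "A", "A", "A", "B", "B"),
    chrom = "1", strand = "+",
    start = c(100L, 300L, 500L, 700L, 100L, 700L),
    end   = c(200L, 400L, 600L, 800L, 200L, 800L)))
  lenient <- find_skipped_exons(gm)
  strict <- find_skipped_exons(gm, strict_cassette = TRUE)
  expect_equal(nrow(lenient), 2L)   # e2 and e3 both absent from B
  expect_equal(nrow(strict), 0L)    # B retains neither flank pair
  # with the true cassette excluder the strict call appears
  sk <- find_skipped_exons(cassette_gene(), strict_cassette = TRUE)
  expect_equal(nrow(sk), 1L)
})

test_that("ISE SNPs link to the nearest exon on each side with distances", {
  gm <- cassette_gene()
  sk <- find_skipped_exons(gm)
  # SNP in the intron between e1 and cassette e2, 10 bases from e2
  snp <- data.frame(snp_id = "rs1", chrom = "1", pos = 289L,
                    ref = "A", alt = "G", class = "intronic", maf = 0.3)
  links <- link_ise_snp_to_exons(snp, gm, sk)
  expect_equal(nrow(links), 2L)
  dn <- links[links$side == "exon_downstream_of_snp", ]
  up <- links[links$side == "exon_upstream_of_snp", ]
  expect_equal(dn$exon_start, 300L)
  expect_true(dn$is_skipped)
  expect_equal(dn$distance_bp, 10L)
  expect_equal(up$exon_end, 200L)
  expect_false(up$is_skipped)
  expect_equal(up$distance_bp, 89L)
  expect_equal(exon_skipping_snp_ids(links), "rs1")
})

test_that("SNPs adjacent to a boundary have distance 0", {
  gm <- cassette_gene()
  snp <- data.frame(snp_id = "rs0", chrom = "1", pos = 200L,
                    ref = "A", alt = "G", class = "intronic", maf = 0.3)
  links <- link_ise_snp_to_exons(snp, gm, NULL)
  up <- links[links$side == "exon_upstream_of_snp", ]
  expect_equal(up$distance_bp, 0L)
})

test_that("SNPs with both adjacent exons constitutive are not exon-skipping", {
  gm <- gene_models(data.frame(
    gene_id = "G1", transcript_id = c("A", "A", "B", "B"),
    chrom = "1", strand = "+",
    start = c(100L, 500L, 100L, 500L), end = c(200L, 600L, 200L, 600L)))
  sk <- find_skipped_exons(gm)
  snp <- data.frame(snp_id = "rs1", chrom = "1", pos = 350L,
                    ref = "A", alt = "G", class = "intronic", maf = 0.3)
  links <- link_ise_snp_to_exons(snp, gm, sk)
  expect_true(all(!links$is_skipped))
  expect_length(exon_skipping_snp_ids(links), 0L)
})

test_that("the strand filter keeps only host genes on the SNP's strand", {
  plus <- as.data.frame(cassette_gene())
  minus <- plus
  minus$gene_id <- "G2"; minus$transcript_id <- paste0("m", minus$transcript_id)
  minus$strand <- "-"
  gm <- gene_models(rbind(plus, minus))
  snp <- data.frame(snp_id = "rs1", chrom = "1", pos = 250L, ref = "A",
                    alt = "G", class = "intronic", maf = 0.3, strand = "+")
  links <- link_ise_snp_to_exons(snp, gm, NULL)
  expect_equal(unique(links$gene_id), "G1")
  # without a strand column both genes host the SNP
  links2 <- link_ise_snp_to_exons(snp[setdiff(names(snp), "strand")], gm, NULL)
  expect_setequal(unique(links2$gene_id), c("G1", "G2"))
})

test_that("non-intronic SNPs yield no links", {
  gm <- cassette_gene()
  exonic <- data.frame(snp_id = "rsE", chrom = "1", pos = 150L,
                       ref = "A", alt = "G", class = "intronic", maf = 0.3)
  expect_equal(nrow(link_ise_snp_to_exons(exonic, gm, NULL)), 0L)
})

test_that("merging annotation sources deduplicates and pools isoforms", {
  a <- cassette_gene()
  # source 2 repeats isoform A and adds nothing else
  b <- gene_models(data.frame(gene_id = "G1", transcript_id = "A2",
                              chrom = "1", strand = "+",
                              start = c(100L, 300L, 500L),
                              end = c(200L, 400L, 600L)))
  merged <- merge_as_sources(a, b)
  expect_equal(length(unique(merged$transcript_id)), 2L)  # duplicate collapsed
  # pooling across sources makes the skipped exon detectable
  src1 <- gene_models(data.frame(gene_id = "G1", transcript_id = "A",
                                 chrom = "1", strand = "+",
                                 start = c(100L, 300L, 500L),
                                 end = c(200L, 400L, 600L)))
  src2 <- gene_models(data.frame(gene_id = "G1", transcript_id = "B",
                                 chrom = "1", strand = "+",
                                 start = c(100L, 500L), end = c(200L, 600L)))
  expect_equal(nrow(find_skipped_exons(src1)), 0L)
  expect_equal(nrow(find_skipped_exons(merge_as_sources(src1, src2))), 1L)
})

test_that("gene_id collisions across chromosomes are an error", {
  a <- cassette_gene()
  b <- gene_models(data.frame(gene_id = "G1", transcript_id = "C",
                              chrom = "2", strand = "+",
                              start = c(1L, 100L), end = c(50L, 150L)))
  expect_error(merge_as_sources(a, b), "chromosome")
})
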