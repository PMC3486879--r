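# Allele-aware hexamer scanning.

test_that("windows have length 2*flank+1, differ only at center, pad with N", {
  g <- genome_ref(c("1" = strrep("ACGT", 10)))
  snp <- data.frame(snp_id = "r", chrom = "1", pos = 20L, ref = "A", alt = "G")
  w <- extract_window(g, snp)
  expect_equal(nchar(w$seq_ref), 11L)
  expect_equal(substr(w$seq_ref, 6, 6), "A")
  expect_equal(substr(w$seq_alt, 6, 6), "G")
  d <- which(strsplit(w$seq_ref, "")[[1]] != strsplit(w$seq_alt, "")[[1]])
  expect_equal(d, 6L)
  # SNP at position 2 of the contig: 3 leading N
  snp2 <- data.frame(snp_id = "r2", chrom = "1", pos = 2L, ref = "G", alt = "T")
  w2 <- extract_window(g, snp2)
  expect_equal(substr(w2$seq_ref, 1, 3), "NNN")
  expect_equal(nchar(w2$seq_ref), 11L)
})

test_that("a genome/ref mismatch warns and keeps the declared alleles", {
  g <- genome_ref(c("1" = strrep("A", 21)))
  snp <- data.frame(snp_id = "r", chrom = "1", pos = 10L, ref = "C", alt = "T")
  expect_warning(w <- extract_window(g, snp), "differs")
  expect_equal(substr(w$seq_ref, 6, 6), "C")
  expect_equal(substr(w$seq_alt, 6, 6), "T")
})

test_that("an 11-mer yields exactly 6 frames with SNP positions 6..1", {
  fx <- window_fixture(paste0("AAAAA", "G", "AAAAA"), ref = "G", alt = "C")
  w <- extract_window(fx$genome, fx$snp)
  fr <- enumerate_frames(w, "ref")
  expect_equal(nrow(fr), 6L)
  expect_equal(fr$snp_pos, 6:1)
  expect_equal(fr$hexamer,
               c("AAAAAG", "AAAAGA", "AAAGAA", "AAGAAA", "AGAAAA", "GAAAAA"))
  # N in the window flags the covering frames ineligible but keeps 6 frames
  fxn <- window_fixture(paste0("NAAAA", "G", "AAAAA"), ref = "G", alt = "C")
  frn <- enumerate_frames(extract_window(fxn$genome, fxn$snp), "ref")
  expect_equal(nrow(frn), 6L)
  expect_equal(frn$eligible, c(FALSE, rep(TRUE, 5)))
})

test_that("matching is exact string equality with per-frame hits", {
  # three-motif example: G allele inside AGGGAT, CAGGGA, TCAGGG
  fx <- window_fixture("CCTCAGGGATC", ref = "G", alt = "A")
  p <- profile_alleles(fx$genome, fx$snp, motif_set(c("AGGGAT", "CAGGGA", "TCAGGG")))
  expect_equal(sort(p$hits_ref$snp_pos_in_motif), c(2L, 3L, 4L))
  expect_equal(nrow(p$hits_alt), 0L)
  expect_equal(p$effect_class, "loss")
  # hit invariants: motif base at the SNP position equals the allele,
  # genomic_start is consistent with the position in the motif
  with(p$hits_ref, {
    expect_equal(substr(motif, snp_pos_in_motif, snp_pos_in_motif),
                 rep("G", 3))
    expect_equal(genomic_start, fx$snp$pos - (snp_pos_in_motif - 1L))
  })
  # empty motif set: no hits
  p0 <- profile_alleles(fx$genome, fx$snp, motif_set(character()))
  expect_equal(nrow(p0$hits_ref) + nrow(p0$hits_alt), 0L)
  expect_equal(p0$effect_class, "none")
})

test_that("an alternate allele can gain a motif match absent for ref", {
  fx <- window_fixture("CCTCAAGGATC", ref = "A", alt = "G")
  p <- profile_alleles(fx$genome, fx$snp, motif_set(c("AGGGAT")))
  expect_equal(nrow(p$hits_ref), 0L)
  expect_equal(p$hits_alt$snp_pos_in_motif, 2L)
  expect_equal(p$effect_class, "gain")
})

test_that("scan hits equal the brute-force window slide on random cases", {
  set.seed(42)
  all_hex <- apply(expand.grid(rep(list(BASES), 6))[6:1], 1, paste, collapse = "")
  for (i in 1:300) {
    ms <- motif_set(sample(all_hex, sample(1:64, 1)))
    win <- rand_window()
    ref <- substr(win, 6, 6)
    alt <- sample(setdiff(BASES, ref), 1)
    fx <- window_fixture(win, ref = ref, alt = alt)
    w <- extract_window(fx$genome, fx$snp)
    got <- match_motifs(enumerate_frames(w, "ref"), ms, w, allele = ref)
    want <- brute_hits(win, ms)
    expect_equal(got[order(got$snp_pos_in_motif), c("motif", "snp_pos_in_motif")],
                 want[order(want$snp_pos), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("minus-strand scanning equals plus-strand scanning of the RC window", {
  set.seed(11)
  for (i in 1:50) {
    win <- rand_window()
    ref <- substr(win, 6, 6)
    alt <- sample(setdiff(BASES, ref), 1)
    ms <- motif_set(replicate(10, rand_window(6)))
    fx <- window_fixture(win, ref = ref, alt = alt)
    w_minus <- extract_window(fx$genome, fx$snp, strand = "-")
    # plus-strand scan of the reverse-complemented window with RC alleles
    fx2 <- window_fixture(revcomp(win), ref = revcomp(ref), alt = revcomp(alt))
    w_plus <- extract_window(fx2$genome, fx2$snp)
    expect_equal(w_minus$seq_ref, w_plus$seq_ref)
    expect_equal(w_minus$seq_alt, w_plus$seq_alt)
    h1 <- match_motifs(enumerate_frames(w_minus, "ref"), ms)
    h2 <- match_motifs(enumerate_frames(w_plus, "ref"), ms)
    expect_equal(h1[c("motif", "snp_pos_in_motif")],
                 h2[c("motif", "snp_pos_in_motif")])
  }
})

test_that("call_ise_snps respects the class filter and set semantics", {
  st <- small_study()
  # exonic SNPs are excluded even if their context matches a motif
  scan <- call_ise_snps(st$snps, st$genome, st$motifs)
  expect_true(all(scan$calls$snp_id %in%
                    st$snps$snp_id[st$snps$class == "intronic"]))
  # planted fixture: every planted SNP is called
  expect_true(all(st$truth$planted$snp_id %in% ise_snp_ids(scan)))
  # invariance under motif-set input order
  ms_shuffled <- motif_set(sample(as.character(st$motifs)))
  scan2 <- call_ise_snps(st$snps, st$genome, ms_shuffled)
  expect_equal(scan$calls, scan2$calls)
})

test_that("effect classes follow hit emptiness and equality", {
  # ref-only hit: loss (tested above); both-allele different hits: retention_shift
  fx <- window_fixture("CCTCAGGGATC", ref = "G", alt = "T")
  ms <- motif_set(c("AGGGAT", "TCATGG"))
  p <- profile_alleles(fx$genome, fx$snp, ms)
  expect_equal(p$effect_class, "retention_shift")
  expect_true(p$is_ise)
})
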