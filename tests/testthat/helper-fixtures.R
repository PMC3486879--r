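# Shared fixtures and independent brute-force oracles.

BASES <- c("A", "C", "G", "T")

rand_window <- function(len = 11L) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# Build a one-chromosome genome whose sequence IS the given window, with
# the SNP at the window center (0-based pos = flank).
window_fixture <- function(window, ref, alt, snp_id = "rs1", flank = 5L) {
  list(genome = genome_ref(c("1" = window)),
       snp = data.frame(snp_id = snp_id, chrom = "1", pos = flank,
                        ref = ref, alt = alt, class = "intronic", maf = 0.2))
}

# Independent motif-scan oracle: slide a 6-wide window over the 11-mer,
# keep the windows that cover the center base, match by string equality.
brute_hits <- function(window, motifs) {
  n <- nchar(window)
  center <- (n + 1L) %/% 2L
  out <- data.frame(motif = character(), snp_pos = integer())
  for (s in seq_len(n - 5L)) {
    if (s > center || s + 5L < center) next
    hex <- substr(window, s, s + 5L)
    if (grepl("N", hex, fixed = TRUE)) next
    if (hex %in% as.character(motifs))
      out <- rbind(out, data.frame(motif = hex, snp_pos = center - s + 1L))
  }
  out
}

# Random toy gene model: ladder of <= max_exons exons, <= max_iso isoform
# subsets (each keeping >= 2 exons).
rand_gene_model <- function(gene_id = "G1", max_exons = 8L, max_iso = 5L) {
  n_ex <- sample(3:max_exons, 1L)
  lens <- sample(20:100, n_ex, replace = TRUE)
  gaps <- sample(50:200, n_ex - 1L, replace = TRUE)
  starts <- 100L + c(0L, cumsum(lens[-n_ex] + gaps))
  ends <- starts + lens
  n_iso <- sample(2:max_iso, 1L)
  rows <- lapply(seq_len(n_iso), function(i) {
    keep <- which(stats::runif(n_ex) < 0.7)
    while (length(keep) < 2L) keep <- sort(unique(c(keep, sample.int(n_ex, 1L))))
    data.frame(gene_id = gene_id, transcript_id = sprintf("%s.t%d", gene_id, i),
               chrom = "1", strand = "+", start = starts[keep], end = ends[keep])
  })
  gene_models(do.call(rbind, rows))
}

# Independent skipped-exon oracle: compare all ordered isoform pairs; an
# internal exon of isoform I absent (by exact coordinates) from isoform J
# is skipped.
brute_skipped <- function(gm) {
  df <- as.data.frame(gm)
  out <- character()
  for (g in split(df, df$gene_id)) {
    txs <- lapply(split(g, g$transcript_id), function(tx) tx[order(tx$start), ])
    if (length(txs) < 2L) next
    keys <- lapply(txs, function(tx) paste(tx$start, tx$end, sep = "-"))
    for (i in seq_along(txs)) for (j in seq_along(txs)) {
      if (i == j) next
      ki <- keys[[i]]
      if (length(ki) < 3L) next
      internal <- ki[2:(length(ki) - 1L)]
      miss <- internal[!internal %in% keys[[j]]]
      if (length(miss))
        out <- c(out, paste(g$gene_id[1], miss))
    }
  }
  sort(unique(out))
}

skipped_keys <- function(sk) {
  if (!nrow(sk)) return(character())
  sort(unique(paste(sk$gene_id, paste(sk$start, sk$end, sep = "-"))))
}

# Small deterministic study used by several test files.
small_study <- function(seed = 7L, n_genes = 12L, n_samples = 60L, ...) {
  simulate_study(sim_config(seed = seed, n_genes = n_genes,
                            n_samples = n_samples, ...))
}
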