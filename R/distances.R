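# Distance-to-exon computations and distribution comparisons.

#' Distance from intronic SNPs to the nearest exon of their host gene(s)
#'
#' A SNP's host genes are those in whose intron it lies (inside the gene
#' span, in no exon, using the union of the gene's exons across
#' isoforms). The distance is the minimum gap, in bases strictly between
#' the SNP and an exon boundary, over all union exons of all host genes;
#' a SNP at the first intronic base has distance 0. Non-intronic SNPs get
#' `NA`.
#'
#' @param snps a `snp_table`.
#' @param gm a `gene_models` object.
#' @return integer vector (named by `snp_id`) of distances, `NA` where
#'   the SNP is intronic in no gene.
#' @export
nearest_exon_distance <- function(snps, gm) {
  s <- as.data.frame(snps)
  gdf <- as.data.frame(gm)
  genes <- split(gdf, gdf$gene_id)
  out <- stats::setNames(rep(NA_integer_, nrow(s)), s$snp_id)
  for (i in seq_len(nrow(s))) {
    pos <- s$pos[i]
    best <- NA_integer_
    for (g in genes) {
      if (g$chrom[1] != s$chrom[i]) next
      u <- gene_union_exons(g)
      if (pos < min(u$start) || pos >= max(u$end)) next
      if (any(pos >= u$start & pos < u$end)) next  # exonic here
      d <- min(gap_to_exon(pos, u$start, u$end))
      best <- if (is.na(best)) d else min(best, d)
    }
    out[i] <- best
  }
  out
}

#' Distance from a SNP to a linked skipped exon
#'
#' The gap in bases strictly between the SNP and the nearer boundary of
#' the exon (adjacency gives 0).
#'
#' @param snp_pos 0-based SNP position(s).
#' @param exon_start,exon_end 0-based half-open exon interval(s).
#' @return integer vector of distances.
#' @export
skipped_exon_distance <- function(snp_pos, exon_start, exon_end) {
  gap_to_exon(as.integer(snp_pos), as.integer(exon_start), as.integer(exon_end))
}

#' Two-sample Kolmogorov-Smirnov comparison of distance distributions
#'
#' @param sample_a,sample_b numeric samples (n >= 5 each).
#' @param exact exact p for small samples (passed to [stats::ks.test()];
#'   default lets `ks.test` decide).
#' @return list with `D`, `p_value`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(sample_a, sample_b, exact = NULL) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 5L || length(sample_b) < 5L)
    stop_fmt("both samples must have at least 5 values")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(sample_a), n_b = length(sample_b))
}

#' Per-group distance summaries (mean, median, SD)
#'
#' @param distances numeric distances (bp).
#' @param group group label per distance (e.g. all-intronic / ISE /
#'   trait-associated).
#' @return data frame with `group`, `n`, `mean_bp`, `median_bp`, `sd_bp`
#'   (sample SD, `NA` for singleton groups).
#' @export
summarize_distances <- function(distances, group) {
  ok <- !is.na(distances)
  distances <- distances[ok]; group <- group[ok]
  parts <- split(distances, group)
  data.frame(group = names(parts),
             n = lengths(parts),
             mean_bp = vapply(parts, mean, numeric(1)),
             median_bp = vapply(parts, stats::median, numeric(1)),
             sd_bp = vapply(parts, function(x)
               if (length(x) > 1L) stats::sd(x) else NA_real_, numeric(1)),
             row.names = NULL)
}
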