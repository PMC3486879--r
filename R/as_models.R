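# Skipped (cassette) exon detection from transcript models and linking of
# ISE SNPs to the adjacent exons they putatively regulate.

tx_exon_list <- function(gm) {
  df <- as.data.frame(gm)
  lapply(split(df, df$transcript_id), function(tx) tx[order(tx$start), ])
}

exon_key <- function(start, end) paste(start, end, sep = "-")

#' Find alternatively skipped exons of each gene
#'
#' An exon (identified by exact genomic coordinates) is skipped when some
#' isoform of the gene contains it as an internal exon while at least one
#' other isoform of the same gene contains no exon with identical
#' coordinates. First and last exons of an isoform are never used as
#' inclusion evidence, since they are by definition neither "skipped" nor
#' "included". In `strict_cassette` mode the excluding isoform must
#' additionally contain both exons flanking the candidate in an including
#' isoform.
#'
#' @param gm a `gene_models` object.
#' @param strict_cassette require the excluding isoform to retain both
#'   flanking exons (default `FALSE`: absence from any isoform suffices).
#' @return data frame of skipped exons: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `inclusion_isoforms`, `exclusion_isoforms`
#'   (comma-separated transcript ids) and `n_excluding`; sorted by gene
#'   and coordinate, independent of transcript input order.
#' @export
find_skipped_exons <- function(gm, strict_cassette = FALSE) {
  out <- list()
  for (g in split(as.data.frame(gm), gm$gene_id)) {
    txs <- lapply(split(g, g$transcript_id), function(tx) tx[order(tx$start), ])
    if (length(txs) < 2L) next
    tx_keys <- lapply(txs, function(tx) exon_key(tx$start, tx$end))
    # candidate internal exons with their flanks, per isoform
    cand <- list()
    for (tn in names(txs)) {
      tx <- txs[[tn]]
      n <- nrow(tx)
      if (n < 3L) next
      for (i in 2:(n - 1L)) {
        k <- exon_key(tx$start[i], tx$end[i])
        cand[[k]] <- c(cand[[k]], list(list(
          tx = tn, start = tx$start[i], end = tx$end[i],
          flank_up = exon_key(tx$start[i - 1L], tx$end[i - 1L]),
          flank_dn = exon_key(tx$start[i + 1L], tx$end[i + 1L]))))
      }
    }
    for (k in sort(names(cand))) {
      entries <- cand[[k]]
      incl <- sort(unique(vapply(entries, `[[`, "", "tx")))
      excl <- character()
      for (tn in names(txs)) {
        if (k %in% tx_keys[[tn]]) next
        ok <- if (strict_cassette) {
          any(vapply(entries, function(e)
            e$flank_up %in% tx_keys[[tn]] && e$flank_dn %in% tx_keys[[tn]],
            logical(1)))
        } else TRUE
        if (ok) excl <- c(excl, tn)
      }
      if (length(excl)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
          start = entries[[1]]$start, end = entries[[1]]$end,
          inclusion_isoforms = paste(incl, collapse = ","),
          exclusion_isoforms = paste(sort(excl), collapse = ","),
          n_excluding = length(excl))
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      inclusion_isoforms = character(),
                      exclusion_isoforms = character(), n_excluding = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# union-exon view of a gene: the distinct exon intervals of all isoforms
gene_union_exons <- function(g) {
  u <- unique(g[c("start", "end")])
  u[order(u$start, u$end), , drop = FALSE]
}

#' Link intronic SNPs to the nearest exon on each side of their intron
#'
#' For every host gene in which the SNP is intronic (inside the gene span
#' but in no exon of any isoform, using the union of the gene's exons),
#' the nearest exon upstream and downstream of the SNP is reported
#' together with its distance (bases strictly between the SNP and the exon
#' boundary; adjacency gives 0) and whether that exon is alternatively
#' skipped. An "exon-skipping ISE SNP" is any ISE SNP with at least one
#' link to a skipped exon.
#'
#' @param snps a `snp_table` (typically restricted to ISE SNPs). If a
#'   `strand` column is present, only host genes on that strand are
#'   linked.
#' @param gm a `gene_models` object.
#' @param skipped skipped-exon table from [find_skipped_exons()]; may be
#'   `NULL` to skip the `is_skipped` annotation.
#' @return data frame of links: `snp_id`, `gene_id`, `exon_id`
#'   (`gene:start-end`), `exon_start`, `exon_end`, `side`
#'   (`exon_upstream_of_snp` / `exon_downstream_of_snp`), `distance_bp`,
#'   `is_skipped`.
#' @export
link_ise_snp_to_exons <- function(snps, gm, skipped = NULL) {
  s <- as.data.frame(snps)
  gdf <- as.data.frame(gm)
  genes <- split(gdf, gdf$gene_id)
  skip_keys <- if (!is.null(skipped) && nrow(skipped))
    paste(skipped$gene_id, exon_key(skipped$start, skipped$end)) else character()
  out <- list()
  for (i in seq_len(nrow(s))) {
    pos <- s$pos[i]; chrom <- s$chrom[i]
    for (g in genes) {
      if (g$chrom[1] != chrom) next
      if (!is.null(s$strand) && !is.na(s$strand[i]) && g$strand[1] != s$strand[i]) next
      u <- gene_union_exons(g)
      if (pos < min(u$start) || pos >= max(u$end)) next
      inside <- any(pos >= u$start & pos < u$end)
      if (inside) next  # exonic in this gene, not intronic
      for (side in c("up", "dn")) {
        if (side == "up") {
          cand <- u[u$end <= pos, , drop = FALSE]
          if (!nrow(cand)) next
          ex <- cand[which.max(cand$end), ]
          lab <- "exon_upstream_of_snp"
        } else {
          cand <- u[u$start > pos, , drop = FALSE]
          if (!nrow(cand)) next
          ex <- cand[which.min(cand$start), ]
          lab <- "exon_downstream_of_snp"
        }
        out[[length(out) + 1L]] <- data.frame(
          snp_id = s$snp_id[i], gene_id = g$gene_id[1],
          exon_id = paste0(g$gene_id[1], ":", ex$start, "-", ex$end),
          exon_start = ex$start, exon_end = ex$end, side = lab,
          distance_bp = gap_to_exon(pos, ex$start, ex$end),
          is_skipped = paste(g$gene_id[1], exon_key(ex$start, ex$end)) %in% skip_keys)
      }
    }
  }
  if (!length(out))
    return(data.frame(snp_id = character(), gene_id = character(),
                      exon_id = character(), exon_start = integer(),
                      exon_end = integer(), side = character(),
                      distance_bp = integer(), is_skipped = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' SNP ids with at least one link to a skipped exon
#' @param links link table from [link_ise_snp_to_exons()].
#' @return character vector of exon-skipping SNP ids.
#' @export
exon_skipping_snp_ids <- function(links) {
  unique(links$snp_id[links$is_skipped])
}

#' Merge gene models from several annotation sources
#'
#' Transcripts are pooled per `gene_id`; duplicate transcripts (identical
#' exon structure within a gene) are collapsed to one. Transcript ids
#' clashing across sources with different structures are disambiguated
#' with a source suffix.
#'
#' @param ... `gene_models` objects, or a single list of them.
#' @return a unified `gene_models` object.
#' @export
merge_as_sources <- function(...) {
  srcs <- list(...)
  if (length(srcs) == 1L && !inherits(srcs[[1]], "gene_models")) srcs <- srcs[[1]]
  dfs <- lapply(seq_along(srcs), function(i) {
    d <- as.data.frame(srcs[[i]]); d$.src <- i; d
  })
  all <- do.call(rbind, dfs)
  for (g in split(all, all$gene_id))
    if (length(unique(g$chrom)) > 1L)
      stop_fmt("gene_id '%s' occurs on different chromosomes across sources",
               g$gene_id[1])
  # transcript signature: gene + ordered exon intervals
  sigs <- vapply(split(all, paste(all$.src, all$transcript_id)), function(tx) {
    tx <- tx[order(tx$start), ]
    paste(tx$gene_id[1], paste(exon_key(tx$start, tx$end), collapse = ";"))
  }, character(1))
  keep_tx <- names(sigs)[!duplicated(sigs)]
  parts <- split(all, paste(all$.src, all$transcript_id))[keep_tx]
  used <- character()
  rows <- lapply(parts, function(tx) {
    id <- tx$transcript_id[1]
    if (id %in% used) id <- paste0(id, ".src", tx$.src[1])
    used <<- c(used, id)
    tx$transcript_id <- id
    tx$.src <- NULL
    tx
  })
  gene_models(do.call(rbind, rows))
}
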