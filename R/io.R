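# Readers and writers for every external format the pipeline touches.
# All coordinates are converted at these boundaries to the single internal
# convention: 0-based half-open intervals, 0-based SNP positions,
# chromosome names without the "chr" prefix.

## ---- genome (FASTA) -------------------------------------------------------

#' Read a genome FASTA into an in-memory accessor
#'
#' Sequence names are truncated at the first whitespace and normalized with
#' [norm_chrom()].
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return a `genome_ref` object.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- norm_chrom(sub("\\s.*$", "", names(ss)))
  genome_ref(seqs)
}

#' Construct a genome accessor from named sequences
#'
#' @param seqs named character vector of chromosome sequences.
#' @return a `genome_ref` object.
#' @export
genome_ref <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_fmt("all sequences must be named")
  seqs <- toupper(unlist(seqs))
  names(seqs) <- norm_chrom(names(seqs))
  structure(list(seqs = seqs), class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("<genome_ref> ", length(x$seqs), " sequence(s), ",
      sum(nchar(x$seqs)), " bp total\n", sep = "")
  invisible(x)
}

#' Extract genome sequence, padding with N beyond contig ends
#'
#' @param genome a `genome_ref`.
#' @param chrom chromosome name (any "chr" prefix ignored).
#' @param start,end 0-based half-open interval; may extend past contig
#'   bounds, in which case the overhang is returned as `N`.
#' @return a single uppercase string of length `end - start`.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  chrom <- norm_chrom(chrom)
  if (!chrom %in% names(genome$seqs))
    stop_fmt("chromosome '%s' absent from genome", chrom)
  s <- genome$seqs[[chrom]]
  len <- nchar(s)
  n <- end - start
  lo <- min(max(start, 0L), len)
  hi <- min(max(end, 0L), len)
  core <- if (hi > lo) substr(s, lo + 1L, hi) else ""
  left <- min(max(0L, lo - start), n)
  right <- n - left - nchar(core)
  paste0(strrep("N", left), core, strrep("N", right))
}

#' Write a genome accessor to FASTA
#'
#' @param genome a `genome_ref`.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## ---- transcript models ----------------------------------------------------

#' Construct a validated gene-model table
#'
#' The internal representation of transcript models: one row per exon with
#' columns `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end`
#' (0-based half-open). Exons of a transcript must be sorted,
#' non-overlapping, on a single chromosome and strand, and every transcript
#' of a gene must share the gene's chromosome and strand.
#'
#' @param df data frame with the columns above.
#' @return a `gene_models` object (a data frame).
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("missing columns: %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$chrom <- norm_chrom(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) stop_fmt("exon with start >= end")
  if (any(!df$strand %in% c("+", "-"))) stop_fmt("strand must be '+' or '-'")
  df <- df[order(df$gene_id, df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (tx in split(df, df$transcript_id)) {
    if (length(unique(tx$chrom)) > 1L || length(unique(tx$strand)) > 1L)
      stop_fmt("transcript '%s' spans several chromosomes or strands",
               tx$transcript_id[1])
    if (nrow(tx) > 1L && any(tx$start[-1L] < tx$end[-nrow(tx)]))
      stop_fmt("transcript '%s' has overlapping exons", tx$transcript_id[1])
  }
  for (g in split(df, df$gene_id)) {
    if (length(unique(g$chrom)) > 1L)
      stop_fmt("gene '%s' has transcripts on several chromosomes", g$gene_id[1])
    if (length(unique(g$strand)) > 1L)
      stop_fmt("gene '%s' has transcripts on several strands", g$gene_id[1])
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read transcript models from genePred or GTF
#'
#' genePred rows carry 0-based half-open `exonStarts`/`exonEnds` and are
#' mapped directly; GTF exon lines are 1-based closed and are converted to
#' the internal 0-based half-open convention.
#'
#' @param path annotation file.
#' @param dialect `"genepred"` (tab-separated, columns name, chrom, strand,
#'   txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds and
#'   optionally a gene symbol in column 11) or `"gtf"`.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path, dialect = c("genepred", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "genepred") read_genepred(path) else read_gtf(path)
}

read_genepred <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_fmt("no records in '%s'", path)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stop_fmt("malformed genePred line %d: expected >= 10 fields, got %d",
               i, length(f))
    n_exon <- suppressWarnings(as.integer(f[8]))
    starts <- suppressWarnings(as.integer(strsplit(f[9], ",")[[1]]))
    ends <- suppressWarnings(as.integer(strsplit(f[10], ",")[[1]]))
    if (is.na(n_exon) || n_exon < 1L)
      stop_fmt("genePred line %d: transcript '%s' has zero exons", i, f[1])
    if (anyNA(starts) || anyNA(ends) ||
        length(starts) != n_exon || length(ends) != n_exon)
      stop_fmt("malformed genePred line %d: exon lists disagree with exonCount", i)
    data.frame(gene_id = if (length(f) >= 12L && nzchar(f[12])) f[12] else f[1],
               transcript_id = f[1], chrom = f[2], strand = f[3],
               start = starts, end = ends)
  })
  gene_models(do.call(rbind, rows))
}

read_gtf <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
    gr <- gr[gr$type == "exon", , drop = FALSE]
    df <- data.frame(gene_id = gr$gene_id,
                     transcript_id = gr$transcript_id,
                     chrom = as.character(gr$seqnames),
                     strand = as.character(gr$strand),
                     start = gr$start - 1L,  # 1-based closed -> 0-based half-open
                     end = gr$end)
    return(gene_models(df))
  }
  # fallback parser for the exon-line subset of GTF 2.2
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) stop_fmt("malformed GTF line %d", i)
    if (f[3] != "exon") return(NULL)
    attr_get <- function(key) {
      m <- regmatches(f[9], regexec(paste0(key, ' "([^"]+)"'), f[9]))[[1]]
      if (length(m) < 2L) stop_fmt("GTF line %d lacks attribute '%s'", i, key)
      m[2]
    }
    data.frame(gene_id = attr_get("gene_id"),
               transcript_id = attr_get("transcript_id"),
               chrom = f[1], strand = f[7],
               start = as.integer(f[4]) - 1L, end = as.integer(f[5]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop_fmt("no exon records in '%s'", path)
  gene_models(do.call(rbind, rows))
}

#' Write gene models to genePred or GTF
#'
#' @param gm a `gene_models` object.
#' @param path output path.
#' @param dialect output dialect.
#' @export
write_gene_models <- function(gm, path, dialect = c("genepred", "gtf")) {
  dialect <- match.arg(dialect)
  txs <- split(as.data.frame(gm), gm$transcript_id)
  if (dialect == "genepred") {
    lines <- vapply(txs, function(tx) {
      tx <- tx[order(tx$start), ]
      paste(tx$transcript_id[1], tx$chrom[1], tx$strand[1],
            min(tx$start), max(tx$end), min(tx$start), max(tx$end),
            nrow(tx),
            paste0(paste(tx$start, collapse = ","), ","),
            paste0(paste(tx$end, collapse = ","), ","),
            0, tx$gene_id[1], sep = "\t")
    }, character(1))
  } else {
    lines <- unlist(lapply(txs, function(tx) {
      tx <- tx[order(tx$start), ]
      sprintf('%s\texonskip\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
              tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$gene_id,
              tx$transcript_id)
    }))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- SNPs -----------------------------------------------------------------

#' Construct a validated SNP table
#'
#' One row per biallelic single-nucleotide variant: `snp_id`, `chrom`,
#' `pos` (0-based), `ref`, `alt` (single bases, distinct), `class`
#' (`intronic`, `exonic`, `intergenic` or `other`) and `maf` (folded minor
#' allele frequency in \[0, 0.5\], `NA` when unknown).
#'
#' @param df data frame with the columns above (`class` and `maf` optional).
#' @return a `snp_table` object (a data frame).
#' @export
snp_table <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$class)) df$class <- "other"
  if (is.null(df$maf)) df$maf <- NA_real_
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "class", "maf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("missing columns: %s", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  df <- df[c(need, extra)]
  df$chrom <- norm_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  df$maf <- as.numeric(df$maf)
  if (any(df$pos < 0L)) stop_fmt("negative SNP position")
  bad <- !df$ref %in% DNA_BASES | !df$alt %in% DNA_BASES
  if (any(bad))
    stop_fmt("non-SNV alleles for: %s", paste(df$snp_id[bad], collapse = ", "))
  if (any(df$ref == df$alt))
    stop_fmt("ref and alt alleles identical for: %s",
             paste(df$snp_id[df$ref == df$alt], collapse = ", "))
  if (any(!df$class %in% c("intronic", "exonic", "intergenic", "other")))
    stop_fmt("unknown snp class value")
  badf <- !is.na(df$maf) & (df$maf < 0 | df$maf > 0.5)
  if (any(badf))
    stop_fmt("MAF outside [0, 0.5] (must be folded) for: %s",
             paste(df$snp_id[badf], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Read SNPs from a VCF subset or a tabular file
#'
#' VCF `POS` (1-based) is converted to the internal 0-based convention;
#' multi-allelic and indel records are skipped with a reported count. The
#' tabular dialect is a TSV with a header naming at least
#' `snp_id, chrom, pos, ref, alt` (plus optional `class`, `maf`) and
#' carries 0-based positions as-is. The SNP class and folded MAF are read
#' from the VCF `INFO` keys `CLASS=` and `MAF=` when present.
#'
#' @param path input file.
#' @param dialect `"vcf"` or `"tabular"`.
#' @return a `snp_table`; the number of skipped VCF records is available as
#'   `attr(x, "n_skipped")`.
#' @export
read_snps <- function(path, dialect = c("vcf", "tabular")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df)[names(df) == "ref_allele"] <- "ref"
    names(df)[names(df) == "alt_allele"] <- "alt"
    return(snp_table(df))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    warn_fmt("no variant records retained from '%s'", path)
    return(structure(snp_table(data.frame(snp_id = character(), chrom = character(),
                                          pos = integer(), ref = character(),
                                          alt = character())),
                     n_skipped = 0L))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 5L)) stop_fmt("malformed VCF line %d", which(nf < 5L)[1])
  chrom <- vapply(f, `[`, "", 1L)
  pos1 <- as.integer(vapply(f, `[`, "", 2L))
  id <- vapply(f, `[`, "", 3L)
  ref <- toupper(vapply(f, `[`, "", 4L))
  alt <- toupper(vapply(f, `[`, "", 5L))
  info <- ifelse(nf >= 8L, vapply(f, function(x) x[min(8L, length(x))], ""), "")
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% DNA_BASES & alt %in% DNA_BASES & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!keep)
  if (n_skipped)
    message(sprintf("read_snps: skipped %d multi-allelic/indel record(s)", n_skipped))
  if (!any(keep)) warn_fmt("zero variant records retained from '%s'", path)
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) >= 2L) x[2] else NA_character_, "")
  }
  cls <- info_field(info[keep], "CLASS")
  maf <- suppressWarnings(as.numeric(info_field(info[keep], "MAF")))
  df <- data.frame(snp_id = id[keep], chrom = chrom[keep], pos = pos1[keep] - 1L,
                   ref = ref[keep], alt = alt[keep],
                   class = ifelse(is.na(cls), "other", cls), maf = maf)
  structure(snp_table(df), n_skipped = n_skipped)
}

#' Write a SNP table as VCF or TSV
#'
#' @param snps a `snp_table`.
#' @param path output path.
#' @param dialect `"vcf"` (positions written 1-based) or `"tabular"`
#'   (0-based, mirrors the internal representation).
#' @export
write_snps <- function(snps, path, dialect = c("vcf", "tabular")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    utils::write.table(as.data.frame(snps), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  info <- paste0("CLASS=", snps$class,
                 ifelse(is.na(snps$maf), "", sprintf(";MAF=%.6g", snps$maf)))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  snps$chrom, snps$pos + 1L, snps$snp_id, snps$ref, snps$alt, info)
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", body), path)
  invisible(path)
}

## ---- motif sets -----------------------------------------------------------

#' Construct an ISE motif set
#'
#' @param motifs character vector of hexamers over A/C/G/T.
#' @param name set label, e.g. `"ISE_5ss"`.
#' @return a `motif_set`: an uppercase, deduplicated, sorted character
#'   vector with a `name` attribute.
#' @export
motif_set <- function(motifs, name = "ISE") {
  motifs <- toupper(as.character(motifs))
  bad <- which(nchar(motifs) != 6L | !is_dna(motifs))
  if (length(bad))
    stop_fmt("invalid motif(s) at entries: %s (must be 6 bases over ACGT)",
             paste(bad, collapse = ", "))
  structure(sort(unique(motifs)), name = name, class = "motif_set")
}

#' Read a plain-text motif list (one hexamer per line)
#'
#' @param path input file; blank lines ignored.
#' @param name set label.
#' @return a `motif_set`.
#' @export
read_motif_set <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  idx <- which(nzchar(lines))
  motifs <- toupper(lines[idx])
  bad <- idx[nchar(motifs) != 6L | !is_dna(motifs)]
  if (length(bad))
    stop_fmt("invalid motif line(s) in '%s': %s (must be 6 bases over ACGT)",
             path, paste(bad, collapse = ", "))
  motif_set(motifs, name = name)
}

#' Write a motif set to a plain-text list
#' @param motifs a `motif_set`.
#' @param path output path.
#' @export
write_motif_set <- function(motifs, path) {
  writeLines(as.character(motifs), path)
  invisible(path)
}

#' @export
print.motif_set <- function(x, ...) {
  cat("<motif_set '", attr(x, "name"), "'> ", length(x), " hexamer(s)\n", sep = "")
  invisible(x)
}

## ---- expression matrices --------------------------------------------------

#' Read a TSV expression matrix (features x samples)
#'
#' First column holds feature ids, the header row sample ids.
#'
#' @param path input TSV.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop_fmt("negative intensities in '%s'", path)
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix (features x samples).
#' @param path output path.
#' @param id_col name of the feature-id column.
#' @export
write_expression <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- genotypes ------------------------------------------------------------

#' Construct a validated genotype dosage matrix
#'
#' @param dosages integer matrix (SNPs x samples) of counted-allele copies
#'   in \{0, 1, 2\}, `NA` for missing.
#' @param counted_allele named character vector (per SNP) naming the allele
#'   whose copies are counted.
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, counted_allele) {
  m <- as.matrix(dosages)
  storage.mode(m) <- "integer"
  if (any(!is.na(m) & !m %in% 0:2)) stop_fmt("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(m))) stop_fmt("dosage matrix needs SNP rownames")
  counted_allele <- toupper(counted_allele)
  if (is.null(names(counted_allele))) names(counted_allele) <- rownames(m)
  if (!all(rownames(m) %in% names(counted_allele)))
    stop_fmt("counted allele missing for some SNPs")
  structure(m, counted_allele = counted_allele[rownames(m)],
            class = c("genotype_matrix", class(m)))
}

#' Read a genotype dosage TSV
#'
#' Columns: `snp_id`, `counted_allele`, then one column per sample with
#' dosages in \{0, 1, 2\} (`NA` for missing).
#'
#' @param path input TSV.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df[[1]]
  genotype_matrix(m, stats::setNames(df[[2]], df[[1]]))
}

#' Write a genotype matrix as TSV
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(snp_id = rownames(g),
                   counted_allele = attr(g, "counted_allele"),
                   unclass(g), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- trait catalog --------------------------------------------------------

#' Read a trait-associated SNP catalog (TSV: snp_id, trait)
#' @param path input TSV.
#' @return a `trait_catalog` data frame; unique SNP ids via [trait_snp_ids()].
#' @export
read_trait_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "trait") %in% names(df)))
    stop_fmt("trait catalog needs columns snp_id, trait")
  structure(df, class = c("trait_catalog", "data.frame"))
}

#' Write a trait catalog TSV
#' @param cat a `trait_catalog` (or data frame with snp_id, trait).
#' @param path output path.
#' @export
write_trait_catalog <- function(cat, path) {
  utils::write.table(as.data.frame(cat), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deduplicated SNP ids of a trait catalog
#' @param cat a `trait_catalog`.
#' @return character vector of unique SNP ids.
#' @export
trait_snp_ids <- function(cat) unique(cat$snp_id)

## ---- exon map -------------------------------------------------------------

#' Read an exon metadata map (TSV: exon_id, gene_id, chrom, start, end)
#'
#' Couples expression-matrix exon features to gene ids and genomic
#' coordinates (0-based half-open), standing in for the proprietary
#' array-probeset annotation.
#'
#' @param path input TSV.
#' @return data frame.
#' @export
read_exon_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exon_id", "gene_id")
  if (!all(need %in% names(df)))
    stop_fmt("exon map needs at least columns exon_id, gene_id")
  if (!is.null(df$chrom)) df$chrom <- norm_chrom(df$chrom)
  df
}

#' Write an exon metadata map
#' @param df exon map data frame.
#' @param path output path.
#' @export
write_exon_map <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
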