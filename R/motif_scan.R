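# Allele-aware hexamer scanning around intronic SNPs.
#
# For each variant an 11-base window (5 bases of flank on either side of
# the SNP) is extracted; the window is fragmented into the 6 hexamer
# frames that contain the SNP, starting with the SNP in the last position
# of the hexamer and sliding the frame upstream one base at a time until
# the SNP sits in the first position. A SNP is an ISE SNP when, for at
# least one allele, one of its frames exactly equals a motif in the ISE
# hexamer set.

#' Extract the allele-substituted sequence window around a SNP
#'
#' @param genome a `genome_ref`.
#' @param snp single-row `snp_table` (or list with `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param flank bases of context on each side of the SNP (default 5, i.e.
#'   an 11-base window).
#' @param strand strand on which to read the window; `" -"` windows are
#'   reverse-complemented so that scanning always runs on the pre-mRNA
#'   sense sequence of the host gene. The SNP stays at the center index.
#' @return a `snp_window`: list with `seq_ref`, `seq_alt` (uppercase,
#'   length `2*flank + 1`, differing exactly at the center), `snp_id`,
#'   `chrom`, `pos`, `flank`, `strand`. Positions beyond the contig are
#'   padded with `N`. If the genome base at `pos` differs from the
#'   declared reference allele a warning is raised and both declared
#'   alleles are substituted into the observed context.
#' @export
extract_window <- function(genome, snp, flank = 5L, strand = "+") {
  pos <- as.integer(snp$pos)
  win <- genome_seq(genome, snp$chrom, pos - flank, pos + flank + 1L)
  center <- flank + 1L
  obs <- substr(win, center, center)
  ref <- toupper(snp$ref); alt <- toupper(snp$alt)
  if (obs != ref && obs != "N")
    warn_fmt("genome base '%s' at %s:%d differs from declared ref '%s' (snp %s)",
             obs, snp$chrom, pos, ref, snp$snp_id %||% "?")
  seq_ref <- win; substr(seq_ref, center, center) <- ref
  seq_alt <- win; substr(seq_alt, center, center) <- alt
  if (strand == "-") {
    seq_ref <- revcomp(seq_ref)
    seq_alt <- revcomp(seq_alt)
  }
  structure(list(snp_id = snp$snp_id %||% NA_character_,
                 chrom = norm_chrom(snp$chrom), pos = pos, flank = flank,
                 strand = strand, seq_ref = seq_ref, seq_alt = seq_alt),
            class = "snp_window")
}

#' Enumerate the SNP-containing hexamer frames of a window
#'
#' An 11-base window yields exactly 6 frames; the SNP occupies hexamer
#' positions 6, 5, 4, 3, 2, 1 in turn as the frame shifts upstream.
#' Frames containing `N` are returned but flagged ineligible for matching.
#'
#' @param window a `snp_window`.
#' @param allele `"ref"` or `"alt"`.
#' @return data frame with `hexamer`, `snp_pos` (1-based position of the
#'   SNP within the hexamer) and `eligible`.
#' @export
enumerate_frames <- function(window, allele = c("ref", "alt")) {
  allele <- match.arg(allele)
  seq <- if (allele == "ref") window$seq_ref else window$seq_alt
  flank <- window$flank
  center <- flank + 1L                      # 1-based index of the SNP base
  starts <- (center - 5L):center            # frame starts, SNP pos 6 .. 1
  hex <- substring(seq, starts, starts + 5L)
  data.frame(hexamer = hex,
             snp_pos = center - starts + 1L,
             eligible = !grepl("N", hex, fixed = TRUE))
}

#' Match hexamer frames against an ISE motif set
#'
#' Exact string equality only; each matching frame yields one hit.
#'
#' @param frames output of [enumerate_frames()].
#' @param motifs a `motif_set`.
#' @param window the originating `snp_window` (for genomic coordinates),
#'   or `NULL`.
#' @param allele allele label carried into the hits.
#' @return data frame of motif hits: `snp_id`, `allele`, `motif`,
#'   `snp_pos_in_motif`, `genomic_start` (0-based start of the matched
#'   hexamer on the plus strand; for minus-strand windows the start of the
#'   genomic interval whose reverse complement is the motif).
#' @export
match_motifs <- function(frames, motifs, window = NULL, allele = NA_character_) {
  hit <- frames$eligible & frames$hexamer %in% as.character(motifs)
  h <- frames[hit, , drop = FALSE]
  if (is.null(window)) {
    gs <- rep(NA_integer_, nrow(h))
    id <- rep(NA_character_, nrow(h))
  } else if (window$strand == "-") {
    gs <- window$pos - (6L - h$snp_pos)
    id <- rep(window$snp_id, nrow(h))
  } else {
    gs <- window$pos - (h$snp_pos - 1L)
    id <- rep(window$snp_id, nrow(h))
  }
  data.frame(snp_id = id, allele = rep(allele, nrow(h)), motif = h$hexamer,
             snp_pos_in_motif = h$snp_pos, genomic_start = gs)
}

#' Scan both alleles of a SNP and classify the allelic motif effect
#'
#' The effect class is a pure function of the two hit lists: `loss` when
#' only the reference allele matches motifs, `gain` when only the
#' alternate allele does, `retention_shift` when both alleles match
#' (possibly different motifs), and `none` when the hit lists are equal
#' (in particular both empty).
#'
#' @inheritParams extract_window
#' @param motifs a `motif_set`.
#' @return an `allele_motif_profile`: list with `snp_id`, `hits_ref`,
#'   `hits_alt` (data frames as from [match_motifs()]), `effect_class`,
#'   `is_ise` (any hit on either allele) and the `window`.
#' @export
profile_alleles <- function(genome, snp, motifs, flank = 5L, strand = "+") {
  w <- extract_window(genome, snp, flank = flank, strand = strand)
  hr <- match_motifs(enumerate_frames(w, "ref"), motifs, w, allele = toupper(snp$ref))
  ha <- match_motifs(enumerate_frames(w, "alt"), motifs, w, allele = toupper(snp$alt))
  key <- function(h) paste(h$motif, h$snp_pos_in_motif)
  effect <- if (nrow(hr) == 0L && nrow(ha) == 0L) "none"
  else if (nrow(ha) == 0L) "loss"
  else if (nrow(hr) == 0L) "gain"
  else if (setequal(key(hr), key(ha))) "none"
  else "retention_shift"
  structure(list(snp_id = snp$snp_id %||% NA_character_, hits_ref = hr,
                 hits_alt = ha, effect_class = effect,
                 is_ise = nrow(hr) + nrow(ha) > 0L, window = w),
            class = "allele_motif_profile")
}

#' @export
print.allele_motif_profile <- function(x, ...) {
  cat("<allele_motif_profile> ", x$snp_id, ": ", nrow(x$hits_ref),
      " ref / ", nrow(x$hits_alt), " alt hit(s), effect ", x$effect_class,
      "\n", sep = "")
  invisible(x)
}

#' Call ISE SNPs over a SNP table
#'
#' Scans every SNP of the required class against the motif set; a SNP is
#' an ISE SNP when at least one allele carries at least one exact hexamer
#' hit.
#'
#' @param snps a `snp_table`.
#' @param genome a `genome_ref`.
#' @param motifs a `motif_set` (typically the union of the 5'ss- and
#'   3'ss-proximal ISE lists).
#' @param require_class SNP class scanned (default `"intronic"`); `NULL`
#'   scans all classes.
#' @param flank flank length (default 5).
#' @param strand_of named character vector mapping `snp_id` to the strand
#'   of the host gene; SNPs absent from it are scanned on `"+"`.
#' @return an `ise_scan`: list with `calls` (data frame: `snp_id`,
#'   `n_hits_ref`, `n_hits_alt`, `effect_class`, `is_ise`), `hits` (all
#'   motif hits) and `profiles` (named list of profiles).
#' @export
call_ise_snps <- function(snps, genome, motifs, require_class = "intronic",
                          flank = 5L, strand_of = NULL) {
  s <- as.data.frame(snps)
  if (!is.null(require_class)) s <- s[s$class %in% require_class, , drop = FALSE]
  profiles <- vector("list", nrow(s))
  names(profiles) <- s$snp_id
  for (i in seq_len(nrow(s))) {
    strand <- if (!is.null(strand_of) && s$snp_id[i] %in% names(strand_of))
      strand_of[[s$snp_id[i]]] else "+"
    profiles[[i]] <- profile_alleles(genome, s[i, ], motifs,
                                     flank = flank, strand = strand)
  }
  calls <- data.frame(
    snp_id = s$snp_id,
    n_hits_ref = vapply(profiles, function(p) nrow(p$hits_ref), integer(1)),
    n_hits_alt = vapply(profiles, function(p) nrow(p$hits_alt), integer(1)),
    effect_class = vapply(profiles, function(p) p$effect_class, character(1)),
    is_ise = vapply(profiles, function(p) p$is_ise, logical(1)),
    row.names = NULL)
  hits <- do.call(rbind, c(lapply(profiles, function(p) rbind(p$hits_ref, p$hits_alt)),
                           list(make.row.names = FALSE)))
  structure(list(calls = calls, hits = hits, profiles = profiles),
            class = "ise_scan")
}

#' @export
print.ise_scan <- function(x, ...) {
  cat("<ise_scan> ", nrow(x$calls), " SNP(s) scanned, ",
      sum(x$calls$is_ise), " ISE SNP(s)\n", sep = "")
  invisible(x)
}

#' ISE SNP ids of a scan
#' @param scan an `ise_scan`.
#' @return character vector of SNP ids called as ISE SNPs.
#' @export
ise_snp_ids <- function(scan) scan$calls$snp_id[scan$calls$is_ise]
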