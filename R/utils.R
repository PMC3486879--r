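#' @keywords internal
"_PACKAGE"

# Shared internal helpers. Coordinates are 0-based half-open everywhere
# inside the package; conversions happen only in R/io.R.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a chromosome name
#'
#' Strips a leading "chr" prefix so that annotation sources using either
#' convention match each other.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return reverse-complemented uppercase strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# gap in bases strictly between a SNP base at `pos` (0-based) and an exon
# [start, end); 0 when adjacent, NA_integer_ never returned for inside
gap_to_exon <- function(pos, start, end) {
  ifelse(pos >= end, pos - end,
         ifelse(pos < start, start - pos - 1L, 0L))
}
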