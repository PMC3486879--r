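# Covariate-matched resampling enrichment: is a query SNP set enriched
# for an annotation (e.g. exon-skipping ISE SNPs) beyond chance, matching
# random draws to the query's minor-allele-frequency spectrum and,
# optionally, to its distance-to-nearest-exon distribution?

#' Build covariate-matched sampling bins
#'
#' MAF bins are fixed-width over \[0, 0.5\]; distance bins are log10-spaced
#' over the pooled (query + background) distance range. In
#' `maf_and_distance` mode the joint bin is the MAF-bin x distance-bin
#' cross.
#'
#' @param query data frame with `snp_id`, `maf` and (for distance
#'   matching) `distance`.
#' @param background data frame with the same columns: the pool random
#'   sets are drawn from (per the study design, intronic SNPs).
#' @param matching_mode `"maf"` or `"maf_and_distance"`.
#' @param maf_bin_width width of the MAF bins (default 0.05, i.e. 10 bins).
#' @param n_distance_bins number of log-spaced distance bins.
#' @return a `matching_bins` object: list with `query_counts` (needed
#'   draws per bin), `pools` (background SNP ids per bin), `mode`, and the
#'   bin edges.
#' @export
build_bins <- function(query, background,
                       matching_mode = c("maf", "maf_and_distance"),
                       maf_bin_width = 0.05, n_distance_bins = 8L) {
  matching_mode <- match.arg(matching_mode)
  if (any(is.na(query$maf))) stop_fmt("query SNP(s) with missing MAF")
  if (any(is.na(background$maf))) stop_fmt("background SNP(s) with missing MAF")
  maf_edges <- seq(0, 0.5, by = maf_bin_width)
  if (maf_edges[length(maf_edges)] < 0.5) maf_edges <- c(maf_edges, 0.5)
  maf_bin <- function(x) findInterval(x, maf_edges, rightmost.closed = TRUE)
  qb <- maf_bin(query$maf)
  bb <- maf_bin(background$maf)
  dist_edges <- NULL
  if (matching_mode == "maf_and_distance") {
    if (is.null(query$distance) || is.null(background$distance) ||
        any(is.na(query$distance)) || any(is.na(background$distance)))
      stop_fmt("distance covariate required for maf_and_distance matching")
    d_all <- c(query$distance, background$distance)
    lo <- log10(min(d_all) + 1); hi <- log10(max(d_all) + 1)
    if (hi <= lo) hi <- lo + 1e-6
    dist_edges <- 10^seq(lo, hi, length.out = n_distance_bins + 1L) - 1
    dist_bin <- function(x) findInterval(x, dist_edges, rightmost.closed = TRUE)
    qb <- paste(qb, dist_bin(query$distance), sep = ".")
    bb <- paste(bb, dist_bin(background$distance), sep = ".")
  } else {
    qb <- as.character(qb); bb <- as.character(bb)
  }
  query_counts <- table(qb)
  pools <- split(background$snp_id, bb)
  empty <- setdiff(names(query_counts), names(pools))
  if (length(empty))
    stop_fmt("no background SNPs available for query bin(s): %s",
             paste(empty, collapse = ", "))
  short <- names(query_counts)[unlist(query_counts) >
                                 lengths(pools[names(query_counts)])]
  if (length(short))
    stop_fmt("background pool smaller than query count in bin(s): %s",
             paste(short, collapse = ", "))
  structure(list(query_counts = query_counts, pools = pools,
                 mode = matching_mode, maf_edges = maf_edges,
                 dist_edges = dist_edges),
            class = "matching_bins")
}

#' Draw covariate-matched random SNP sets
#'
#' Each set replicates the query's per-bin counts exactly; sampling is
#' uniform without replacement within a set and independent across sets.
#'
#' @param bins a `matching_bins` object.
#' @param n_sets number of sets (the study design uses 1000).
#' @return list of `n_sets` character vectors of SNP ids.
#' @export
draw_matched_sets <- function(bins, n_sets = 1000L) {
  needed <- unclass(bins$query_counts)
  bin_ids <- names(bins$query_counts)
  lapply(seq_len(n_sets), function(i) {
    unlist(lapply(bin_ids, function(b) {
      pool <- bins$pools[[b]]
      pool[sample.int(length(pool), needed[[b]])]
    }), use.names = FALSE)
  })
}

#' Covariate-matched enrichment test
#'
#' Compares the observed overlap between a query SNP set and an
#' annotation set with the overlaps of covariate-matched random sets
#' drawn from the background. The empirical p-value uses the
#' `(1 + #[null >= observed]) / (n_sets + 1)` estimator, counting ties
#' (conservative, never exactly zero).
#'
#' @param query_ids query SNP ids (e.g. trait-associated SNPs).
#' @param annotation_ids annotation SNP ids (e.g. exon-skipping ISE SNPs).
#' @param universe data frame with `snp_id`, `maf` and optionally
#'   `distance`, covering at least the query and the background pool
#'   (typically all intronic SNPs).
#' @param matching_mode `"maf"` or `"maf_and_distance"`.
#' @param n_sets number of random sets.
#' @param exclude_query drop query SNPs from the sampling pool.
#' @param maf_bin_width,n_distance_bins bin construction parameters.
#' @return an `enrichment_result`: list with `observed_count`,
#'   `null_counts`, `empirical_p`, `n_query`, `n_annotation`,
#'   `matching_mode`, `n_sets`.
#' @export
enrichment_test <- function(query_ids, annotation_ids, universe,
                            matching_mode = c("maf", "maf_and_distance"),
                            n_sets = 1000L, exclude_query = FALSE,
                            maf_bin_width = 0.05, n_distance_bins = 8L) {
  matching_mode <- match.arg(matching_mode)
  query_ids <- unique(query_ids)
  annotation_ids <- unique(annotation_ids)
  query <- universe[universe$snp_id %in% query_ids, , drop = FALSE]
  if (nrow(query) < length(query_ids))
    stop_fmt("%d query SNP(s) missing from the universe",
             length(query_ids) - nrow(query))
  background <- if (exclude_query)
    universe[!universe$snp_id %in% query_ids, , drop = FALSE] else universe
  bins <- build_bins(query, background, matching_mode,
                     maf_bin_width = maf_bin_width,
                     n_distance_bins = n_distance_bins)
  observed <- sum(query_ids %in% annotation_ids)
  sets <- draw_matched_sets(bins, n_sets = n_sets)
  null_counts <- vapply(sets, function(s) sum(s %in% annotation_ids), integer(1))
  p <- (1 + sum(null_counts >= observed)) / (n_sets + 1)
  structure(list(observed_count = observed, null_counts = null_counts,
                 empirical_p = p, n_query = length(query_ids),
                 n_annotation = length(annotation_ids),
                 matching_mode = matching_mode, n_sets = n_sets),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> observed ", x$observed_count, " of ", x$n_query,
      " query SNPs in annotation (null mean ",
      round(mean(x$null_counts), 2), "); empirical p = ",
      signif(x$empirical_p, 3), " [", x$matching_mode, ", ",
      x$n_sets, " sets]\n", sep = "")
  invisible(x)
}

#' Distance-stratified enrichment
#'
#' Restricts the annotation to exon-skipping SNPs whose distance to the
#' linked skipped exon is strictly below each threshold, and runs one
#' matched enrichment test per stratum (study thresholds: 60, 200, 1000
#' and 5000 bp).
#'
#' @param query_ids query SNP ids.
#' @param links link table from [link_ise_snp_to_exons()]; only rows with
#'   `is_skipped = TRUE` define the annotation.
#' @param universe covariate table as in [enrichment_test()].
#' @param thresholds strict upper bounds (bp) defining the strata.
#' @param ... passed to [enrichment_test()].
#' @return named list of `enrichment_result`s (or `NULL` for an empty
#'   stratum), one per threshold.
#' @export
distance_stratified_enrichment <- function(query_ids, links, universe,
                                           thresholds = c(60, 200, 1000, 5000),
                                           ...) {
  sk <- links[links$is_skipped, , drop = FALSE]
  res <- lapply(thresholds, function(thr) {
    ann <- unique(sk$snp_id[sk$distance_bp < thr])
    if (!length(ann)) return(NULL)
    enrichment_test(query_ids, ann, universe, ...)
  })
  names(res) <- paste0("lt_", thresholds, "bp")
  res
}
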