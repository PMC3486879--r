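# Splicing Index: per-exon, per-sample ratio of exon-level to gene-level
# expression; skip calls per individual; array-to-model exon mapping.

#' Compute the Splicing Index matrix
#'
#' In `ratio` mode (the default) `SI = exon intensity / gene intensity`,
#' so that 1 means proportional inclusion and `|1 - SI|` quantifies
#' skipping; `log2_ratio` applies log2 to that ratio. Samples are matched
#' by id; gene intensities below the floor yield `NaN`, which downstream
#' calls and association exclude.
#'
#' @param exon_expr exon-level expression matrix (exons x samples).
#' @param gene_expr gene-level expression matrix (genes x samples).
#' @param exon_to_gene named character vector mapping exon ids to gene
#'   ids, or an exon map data frame with `exon_id` and `gene_id`.
#' @param mode `"ratio"` or `"log2_ratio"`.
#' @param gene_floor minimum gene intensity; defaults to
#'   `1e-6 * median(gene_expr)`.
#' @return an `si_matrix`: numeric matrix (exons x samples) with
#'   attributes `gene_id` (per exon) and `mode`.
#' @export
compute_si <- function(exon_expr, gene_expr, exon_to_gene,
                       mode = c("ratio", "log2_ratio"), gene_floor = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(exon_to_gene))
    exon_to_gene <- stats::setNames(exon_to_gene$gene_id, exon_to_gene$exon_id)
  samples <- intersect(colnames(exon_expr), colnames(gene_expr))
  if (!length(samples)) stop_fmt("no shared samples between matrices")
  exon_expr <- exon_expr[, samples, drop = FALSE]
  gene_expr <- gene_expr[, samples, drop = FALSE]
  genes <- exon_to_gene[rownames(exon_expr)]
  missing <- rownames(exon_expr)[is.na(genes) | !genes %in% rownames(gene_expr)]
  if (length(missing))
    stop_fmt("exon(s) with no gene mapping in gene_expr: %s",
             paste(missing, collapse = ", "))
  g <- gene_expr[genes, , drop = FALSE]
  if (is.null(gene_floor)) gene_floor <- 1e-6 * stats::median(gene_expr)
  si <- exon_expr / g
  si[g < gene_floor] <- NaN
  if (mode == "log2_ratio") si <- log2(si)
  structure(si, gene_id = stats::setNames(unname(genes), rownames(exon_expr)),
            mode = mode, class = c("si_matrix", class(si)))
}

#' Call per-sample exon skipping from a Splicing Index matrix
#'
#' An exon is called spliced in a sample when its SI is strictly below
#' `lower` or strictly above `upper` (defaults 0.8 and 1.2 on the ratio
#' scale). `NaN`/`NA` entries are never called.
#'
#' @param si an `si_matrix` in ratio mode.
#' @param lower,upper skip-call thresholds, `lower < upper`.
#' @return list with `calls` (logical matrix) and `counts` (per-exon
#'   number of calling samples).
#' @export
call_skipped <- function(si, lower = 0.8, upper = 1.2) {
  if (lower >= upper) stop_fmt("lower threshold must be below upper")
  if (identical(attr(si, "mode"), "log2_ratio"))
    warn_fmt("skip-call thresholds are ratio-scale; si is log2_ratio")
  calls <- (si < lower) | (si > upper)
  calls[is.na(calls)] <- FALSE
  list(calls = calls, counts = rowSums(calls))
}

#' Select frequently skipped exons
#'
#' Keeps exons skipped in strictly more than a threshold number of
#' individuals. The threshold defaults to the top `top_fraction` of the
#' cohort (`ceiling(top_fraction * n_samples)`; 18 for 176 samples) and
#' can be fixed explicitly via `min_individuals`.
#'
#' @param counts per-exon skip counts from [call_skipped()].
#' @param n_samples cohort size.
#' @param top_fraction fraction of the cohort defining the threshold.
#' @param min_individuals explicit threshold overriding `top_fraction`.
#' @return character vector of selected exon ids.
#' @export
select_frequently_skipped <- function(counts, n_samples, top_fraction = 0.10,
                                      min_individuals = NULL) {
  thr <- min_individuals %||% ceiling(top_fraction * n_samples)
  names(counts)[counts > thr]
}

#' Map array exons onto model exons by reciprocal overlap
#'
#' A mapping is accepted when more than `min_array_frac` of the array
#' exon's length and more than `min_model_frac` of the model exon's
#' length overlap (defaults 95% and 90%). Among multiple accepted
#' candidates the pair maximizing the summed overlap fractions is kept,
#' greedily and one-to-one.
#'
#' @param array_exons data frame with `exon_id`, `chrom`, `start`, `end`.
#' @param model_exons data frame with `chrom`, `start`, `end` (e.g. the
#'   skipped-exon table) and optionally `gene_id`.
#' @param min_array_frac,min_model_frac acceptance thresholds (strict
#'   inequalities).
#' @return data frame of accepted mappings: `exon_id`, `model_gene_id`,
#'   `model_start`, `model_end`, `overlap_frac_array`,
#'   `overlap_frac_model`.
#' @export
map_array_exons <- function(array_exons, model_exons,
                            min_array_frac = 0.95, min_model_frac = 0.90) {
  empty <- data.frame(exon_id = character(), model_gene_id = character(),
                      model_start = integer(), model_end = integer(),
                      overlap_frac_array = numeric(), overlap_frac_model = numeric())
  if (!nrow(array_exons) || !nrow(model_exons)) return(empty)
  a <- as.data.frame(array_exons); m <- as.data.frame(model_exons)
  a$chrom <- norm_chrom(a$chrom); m$chrom <- norm_chrom(m$chrom)
  pairs <- merge(cbind(a, .ai = seq_len(nrow(a))),
                 cbind(m, .mi = seq_len(nrow(m))),
                 by = "chrom", suffixes = c(".a", ".m"))
  if (!nrow(pairs)) return(empty)
  ov <- pmax(0L, pmin(pairs$end.a, pairs$end.m) - pmax(pairs$start.a, pairs$start.m))
  fa <- ov / (pairs$end.a - pairs$start.a)
  fm <- ov / (pairs$end.m - pairs$start.m)
  ok <- fa > min_array_frac & fm > min_model_frac
  pairs <- pairs[ok, , drop = FALSE]; fa <- fa[ok]; fm <- fm[ok]
  if (!nrow(pairs)) return(empty)
  o <- order(fa + fm, decreasing = TRUE)
  used_a <- used_m <- integer()
  keep <- integer()
  for (i in o) {
    if (pairs$.ai[i] %in% used_a || pairs$.mi[i] %in% used_m) next
    keep <- c(keep, i)
    used_a <- c(used_a, pairs$.ai[i]); used_m <- c(used_m, pairs$.mi[i])
  }
  mg <- if ("gene_id.m" %in% names(pairs)) pairs$gene_id.m
  else if ("gene_id" %in% names(m) && "gene_id" %in% names(pairs)) pairs$gene_id
  else rep(NA_character_, nrow(pairs))
  aid <- if ("exon_id.a" %in% names(pairs)) pairs$exon_id.a else pairs$exon_id
  res <- data.frame(exon_id = aid[keep],
                    model_gene_id = mg[keep],
                    model_start = pairs$start.m[keep],
                    model_end = pairs$end.m[keep],
                    overlap_frac_array = fa[keep],
                    overlap_frac_model = fm[keep])
  res <- res[order(res$exon_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
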