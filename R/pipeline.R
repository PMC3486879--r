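# End-to-end pipeline: scan -> skipped exons -> link -> SI -> associate
# -> enrich -> distances, with per-stage file outputs and a JSON +
# markdown report.

#' Default pipeline settings
#'
#' All defaults equal the study's printed values: 5-base flank (11-base
#' windows), ratio-scale SI with skip thresholds 0.8/1.2, association
#' filters p < 0.05, FDR < 0.10, R^2 > 0.03, 1000 matched random sets,
#' distance strata 60/200/1000/5000 bp, array-exon mapping 95%/90%.
#'
#' @return named list of settings.
#' @export
pipeline_settings <- function() {
  list(flank = 5L, si_mode = "ratio", si_lower = 0.8, si_upper = 1.2,
       top_fraction = 0.10, p_max = 0.05, fdr_max = 0.10, r2_min = 0.03,
       n_sets = 1000L, matching_mode = "maf",
       distance_strata = c(60, 200, 1000, 5000),
       min_array_frac = 0.95, min_model_frac = 0.90,
       strict_cassette = FALSE)
}

#' Run the full ISE SNP / exon-skipping analysis
#'
#' Executes every stage on either a simulated study (from
#' [simulate_study()]) or a directory of input files (as written by
#' [write_study()]): ISE SNP calling, skipped-exon detection, SNP-exon
#' linking, Splicing Index and skip calls, genotype association with FDR
#' filtering, MAF-matched trait-catalog enrichment, and distance
#' summaries. Stage outputs are written as TSV/JSON files when `outdir`
#' is given; rerunning a downstream stage from those files reproduces the
#' end-to-end result.
#'
#' @param input a study list from [simulate_study()] or a directory path
#'   containing the files written by [write_study()].
#' @param outdir optional output directory for stage files and the
#'   report.
#' @param settings settings list, see [pipeline_settings()].
#' @param seed seed for the enrichment draws.
#' @return a `pipeline_report`: list with per-stage counts, the
#'   enrichment results, the distance summary and the settings used.
#' @export
run_pipeline <- function(input, outdir = NULL, settings = pipeline_settings(),
                         seed = 1L) {
  if (is.character(input)) {
    dirp <- input
    input <- list(
      genome = read_fasta(file.path(dirp, "genome.fa")),
      models = read_gene_models(file.path(dirp, "models.genePred")),
      snps = read_snps(file.path(dirp, "snps.vcf"), dialect = "vcf"),
      genotypes = read_genotypes(file.path(dirp, "genotypes.tsv")),
      exon_expr = read_expression(file.path(dirp, "exon_expression.tsv")),
      gene_expr = read_expression(file.path(dirp, "gene_expression.tsv")),
      exon_map = read_exon_map(file.path(dirp, "exon_map.tsv")),
      trait_catalog = read_trait_catalog(file.path(dirp, "trait_catalog.tsv")),
      motifs = read_motif_set(file.path(dirp, "ise_motifs.txt")))
  }
  st <- settings
  save_tsv <- function(df, name) {
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  scan <- call_ise_snps(input$snps, input$genome, input$motifs,
                        require_class = "intronic", flank = st$flank)
  save_tsv(scan$calls, "scan_calls.tsv")
  ise_ids <- ise_snp_ids(scan)

  skipped <- find_skipped_exons(input$models,
                                strict_cassette = st$strict_cassette)
  save_tsv(skipped, "skipped_exons.tsv")

  ise_snps <- as.data.frame(input$snps)
  ise_snps <- ise_snps[ise_snps$snp_id %in% ise_ids, , drop = FALSE]
  links <- link_ise_snp_to_exons(ise_snps, input$models, skipped)
  save_tsv(links, "links.tsv")
  es_ids <- exon_skipping_snp_ids(links)

  si <- compute_si(input$exon_expr, input$gene_expr, input$exon_map,
                   mode = st$si_mode)
  calls <- call_skipped(si, lower = st$si_lower, upper = st$si_upper)
  frequent <- select_frequently_skipped(calls$counts, ncol(si),
                                        top_fraction = st$top_fraction)

  mapping <- map_array_exons(input$exon_map, skipped,
                             min_array_frac = st$min_array_frac,
                             min_model_frac = st$min_model_frac)
  save_tsv(mapping, "exon_mapping.tsv")

  assoc <- associate(input$genotypes, si,
                     links[links$is_skipped, , drop = FALSE],
                     snps = input$snps)
  hits <- filter_hits(assoc, p_max = st$p_max, fdr_max = st$fdr_max,
                      r2_min = st$r2_min)
  save_tsv(assoc, "associations.tsv")
  save_tsv(hits, "association_hits.tsv")

  snps_df <- as.data.frame(input$snps)
  intronic <- snps_df[snps_df$class == "intronic", , drop = FALSE]
  universe <- data.frame(snp_id = intronic$snp_id, maf = intronic$maf)
  query <- intersect(trait_snp_ids(input$trait_catalog), universe$snp_id)
  set.seed(seed)
  enr <- enrichment_test(query, es_ids, universe,
                         matching_mode = st$matching_mode, n_sets = st$n_sets)
  enr_dist <- distance_stratified_enrichment(query, links, universe,
                                             thresholds = st$distance_strata,
                                             n_sets = st$n_sets)

  ned <- nearest_exon_distance(intronic, input$models)
  dist_tab <- rbind(
    data.frame(group = "intronic", distance = unname(ned)),
    data.frame(group = "ise",
               distance = unname(ned[names(ned) %in% ise_ids])),
    data.frame(group = "skipped_exon",
               distance = links$distance_bp[links$is_skipped &
                                              links$snp_id %in% ise_ids]))
  dist_summary <- summarize_distances(dist_tab$distance, dist_tab$group)
  save_tsv(dist_summary, "distance_summary.tsv")

  report <- structure(list(
    counts = list(
      n_snps = nrow(snps_df), n_intronic_snps = nrow(intronic),
      n_ise_snps = length(ise_ids), n_skipped_exons = nrow(skipped),
      n_links = nrow(links), n_exon_skipping_ise_snps = length(es_ids),
      n_mapped_exons = nrow(mapping),
      n_frequently_skipped_exons = length(frequent),
      n_associations_tested = sum(assoc$testable),
      n_association_hits = nrow(hits),
      n_trait_snps = length(query)),
    enrichment = list(trait = enr, by_distance = enr_dist),
    distance_summary = dist_summary,
    settings = st, seed = seed), class = "pipeline_report")
  if (!is.null(outdir)) {
    ser <- list(counts = report$counts,
                enrichment = list(
                  trait = list(observed = enr$observed_count,
                               empirical_p = enr$empirical_p,
                               null_mean = mean(enr$null_counts)),
                  by_distance = lapply(enr_dist, function(e)
                    if (is.null(e)) NULL else
                      list(observed = e$observed_count,
                           empirical_p = e$empirical_p))),
                distance_summary = dist_summary,
                settings = st, seed = seed)
    jsonlite::write_json(ser, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    md <- c("# Pipeline report", "",
            sprintf("- %s: %s", names(report$counts),
                    unlist(report$counts)),
            "",
            sprintf("- trait enrichment: observed %d, empirical p = %.4g",
                    enr$observed_count, enr$empirical_p))
    writeLines(md, file.path(outdir, "report.md"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  cat("  trait enrichment p = ", signif(x$enrichment$trait$empirical_p, 3),
      "\n", sep = "")
  invisible(x)
}
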