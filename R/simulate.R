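# Synthetic-data generator. Emulates the statistical structure the
# analysis assumes -- intron/exon architecture with cassette exons, ISE
# hexamer motifs planted around intronic SNPs, Hardy-Weinberg genotypes,
# genotype-dependent Splicing Index variation, and a trait catalog with
# planted enrichment -- so that every stage of the pipeline can be
# exercised end to end without any external download.

#' Simulation configuration
#'
#' Defaults are the study conditions the pipeline targets: 176 samples,
#' an additive effect of 0.15 on `|1 - SI|` per disrupting-allele copy,
#' Gaussian SI noise with sd 0.05, folded MAFs uniform on \[0.05, 0.5\]
#' and a motif set of 127 hexamers.
#'
#' @param seed base random seed (integer; stage-specific seeds are
#'   derived from it by small fixed offsets).
#' @param n_genes number of simulated genes.
#' @param exons_per_gene,exon_len,intron_len integer ranges `c(min, max)`.
#' @param cassette_fraction fraction of internal exons made skippable.
#' @param plant_rate fraction of cassette exons receiving a planted ISE
#'   SNP in an adjacent intron.
#' @param n_null_snps_per_gene background SNPs scattered per gene (class
#'   assigned from their actual location).
#' @param maf_range folded-MAF range SNP frequencies are drawn from.
#' @param motif_n size of the simulated ISE hexamer set.
#' @param n_samples cohort size.
#' @param si_noise_sd Gaussian sd of the SI fluctuation around 1.
#' @param beta_skip increase in `|1 - SI|` per disrupting-allele copy at
#'   a planted SNP's cassette exon.
#' @param trait_q0 base probability that a SNP enters the trait catalog.
#' @param trait_enrichment_odds odds multiplier for planted exon-skipping
#'   ISE SNPs entering the trait catalog.
#' @param intergene_gap bases between consecutive genes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 30L,
                       exons_per_gene = c(4L, 8L), exon_len = c(80L, 200L),
                       intron_len = c(300L, 3000L), cassette_fraction = 0.5,
                       plant_rate = 0.8, n_null_snps_per_gene = 10L,
                       maf_range = c(0.05, 0.5), motif_n = 127L,
                       n_samples = 176L, si_noise_sd = 0.05, beta_skip = 0.15,
                       trait_q0 = 0.05, trait_enrichment_odds = 5,
                       intergene_gap = 500L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              cassette_fraction = cassette_fraction, plant_rate = plant_rate,
              n_null_snps_per_gene = as.integer(n_null_snps_per_gene),
              maf_range = maf_range, motif_n = as.integer(motif_n),
              n_samples = as.integer(n_samples), si_noise_sd = si_noise_sd,
              beta_skip = beta_skip, trait_q0 = trait_q0,
              trait_enrichment_odds = trait_enrichment_odds,
              intergene_gap = as.integer(intergene_gap))
  stopifnot(cfg$n_genes >= 1L, cfg$n_samples >= 2L,
            cfg$cassette_fraction >= 0, cfg$cassette_fraction <= 1,
            cfg$plant_rate >= 0, cfg$plant_rate <= 1,
            cfg$beta_skip >= 0, cfg$si_noise_sd >= 0,
            cfg$trait_q0 >= 0, cfg$trait_q0 <= 1,
              cfg$trait_enrichment_odds > 0,
            cfg$maf_range[1] >= 0, cfg$maf_range[2] <= 0.5,
            diff(cfg$exons_per_gene) >= 0, cfg$exons_per_gene[1] >= 3L,
            diff(cfg$exon_len) >= 0, cfg$exon_len[1] >= 10L,
            diff(cfg$intron_len) >= 0)
  if (cfg$intron_len[1] < 30L)
    stop_fmt("introns must be at least 30 bp to host a planted SNP window")
  class(cfg) <- "sim_config"
  cfg
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate an ISE hexamer motif set
#'
#' @param cfg a `sim_config`.
#' @return a `motif_set` of `cfg$motif_n` distinct hexamers.
#' @export
simulate_motif_set <- function(cfg) {
  set.seed(cfg$seed + 11L)
  all_hex <- apply(expand.grid(rep(list(DNA_BASES), 6))[6:1], 1, paste,
                   collapse = "")
  motif_set(sample(all_hex, cfg$motif_n), name = "ISE_sim")
}

# all 6 SNP-containing hexamers of an 11-mer given as a character vector
frames_of <- function(chars) {
  s <- paste(chars, collapse = "")
  substring(s, 1:6, 6:11)
}

#' Simulate a genome, transcript models and SNPs with planted ISE motifs
#'
#' Lays `n_genes` genes end to end on one chromosome. Every gene gets a
#' full-length isoform; each internal exon is made a cassette with
#' probability `cassette_fraction`, adding one isoform that lacks exactly
#' that exon. For each cassette exon, with probability `plant_rate`, an
#' ISE SNP is planted in an adjacent intron: a motif from the set is
#' written into the sequence, the reference allele is the motif base the
#' SNP falls on, and the alternate allele is chosen so that no frame of
#' the alternate window matches any motif (a motif-disrupting allele).
#' The 5 window bases outside the planted motif are regenerated until the
#' alternate window is motif-free, so plant/recover is exact; accidental
#' motif matches elsewhere are left untouched as legitimate nulls.
#' Background SNPs are scattered over each gene and classified from their
#' actual location (intronic/exonic).
#'
#' @param cfg a `sim_config`.
#' @param motifs optional `motif_set`; simulated from `cfg` when missing.
#' @return list with `genome` (a `genome_ref`), `models` (a
#'   `gene_models`), `snps` (a `snp_table`), `exon_map` (all model exons
#'   with ids `gene:start-end`), `motifs`, and `truth` (list: `planted`
#'   data frame, `cassette_exons` data frame).
#' @export
simulate_genome_and_annotation <- function(cfg, motifs = NULL) {
  if (is.null(motifs)) motifs <- simulate_motif_set(cfg)
  set.seed(cfg$seed + 23L)
  motif_chars <- strsplit(as.character(motifs), "")
  names(motif_chars) <- as.character(motifs)

  chrom_chars <- character(0)
  cursor <- 0L
  model_rows <- list()
  planted <- list()
  cassettes <- list()
  snp_rows <- list()
  snp_counter <- 0L

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("G%03d", g)
    n_ex <- rint(1L, cfg$exons_per_gene)
    ex_len <- rint(n_ex, cfg$exon_len)
    in_len <- rint(n_ex - 1L, cfg$intron_len)
    gene_start <- cursor + cfg$intergene_gap
    starts <- integer(n_ex); ends <- integer(n_ex)
    p <- gene_start
    for (j in seq_len(n_ex)) {
      starts[j] <- p; ends[j] <- p + ex_len[j]
      p <- ends[j] + if (j < n_ex) in_len[j] else 0L
    }
    gene_end <- ends[n_ex]
    gene_seq <- sample(DNA_BASES, gene_end - gene_start, replace = TRUE)

    # transcript models: full isoform + one skipping isoform per cassette
    tx_full <- sprintf("%s.t1", gene_id)
    model_rows[[length(model_rows) + 1L]] <- data.frame(
      gene_id = gene_id, transcript_id = tx_full, chrom = "1", strand = "+",
      start = starts, end = ends)
    internal <- if (n_ex >= 3L) 2:(n_ex - 1L) else integer(0)
    cas <- internal[stats::runif(length(internal)) < cfg$cassette_fraction]
    t_i <- 1L
    for (j in cas) {
      t_i <- t_i + 1L
      keep <- setdiff(seq_len(n_ex), j)
      model_rows[[length(model_rows) + 1L]] <- data.frame(
        gene_id = gene_id, transcript_id = sprintf("%s.t%d", gene_id, t_i),
        chrom = "1", strand = "+", start = starts[keep], end = ends[keep])
    }

    # plant ISE SNPs next to cassette exons (windows kept disjoint so a
    # later plant cannot overwrite an earlier motif)
    occupied <- integer(0)
    for (j in cas) {
      exon_id <- sprintf("%s:%d-%d", gene_id, starts[j], ends[j])
      has_snp <- stats::runif(1) < cfg$plant_rate
      cassettes[[length(cassettes) + 1L]] <- data.frame(
        gene_id = gene_id, chrom = "1", start = starts[j], end = ends[j],
        exon_id = exon_id, planted_snp = NA_character_)
      if (!has_snp) next
      pos <- NA_integer_; side <- NA_character_
      for (try in 1:50) {
        side_try <- sample(c("up", "dn"), 1L)
        ilen <- if (side_try == "up") starts[j] - ends[j - 1L]
        else starts[j + 1L] - ends[j]
        dmax <- ilen - 7L
        d <- round(10^stats::runif(1, log10(6), log10(max(6L, dmax))))
        d <- min(max(6L, d), dmax)
        pos_try <- if (side_try == "up") starts[j] - 1L - d else ends[j] + d
        if (!any((pos_try - 10L):(pos_try + 10L) %in% occupied)) {
          pos <- pos_try; side <- side_try; break
        }
      }
      if (is.na(pos)) next
      occupied <- c(occupied, (pos - 10L):(pos + 10L))
      m <- sample(as.character(motifs), 1L)
      pim <- sample.int(6L, 1L)
      mstart <- pos - (pim - 1L)
      ref <- substr(m, pim, pim)
      # write motif, then randomize the 5 non-motif window bases until the
      # alternate-allele window matches no motif at all
      rel <- mstart - gene_start  # 0-based offset of motif in gene_seq
      gene_seq[(rel + 1L):(rel + 6L)] <- motif_chars[[m]]
      win_rel <- (pos - 5L - gene_start):(pos + 5L - gene_start)  # 0-based
      outside <- win_rel[win_rel < rel | win_rel > rel + 5L]
      alt <- NA_character_
      for (try in 1:200) {
        gene_seq[outside + 1L] <- sample(DNA_BASES, length(outside), replace = TRUE)
        win <- gene_seq[win_rel + 1L]
        for (cand in sample(setdiff(DNA_BASES, ref))) {
          wa <- win; wa[6] <- cand
          if (!any(frames_of(wa) %in% motifs)) { alt <- cand; break }
        }
        if (!is.na(alt)) break
      }
      if (is.na(alt)) { # pathological motif context; leave unplanted
        cassettes[[length(cassettes)]]$planted_snp <- NA_character_
        next
      }
      snp_counter <- snp_counter + 1L
      snp_id <- sprintf("snp%05d", snp_counter)
      planted[[length(planted) + 1L]] <- data.frame(
        snp_id = snp_id, gene_id = gene_id, chrom = "1", pos = pos,
        ref = ref, alt = alt, motif = m, pos_in_motif = pim,
        side = if (side == "up") "exon_downstream_of_snp" else "exon_upstream_of_snp",
        exon_id = exon_id, exon_start = starts[j], exon_end = ends[j],
        distance_bp = d)
      cassettes[[length(cassettes)]]$planted_snp <- snp_id
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        snp_id = snp_id, chrom = "1", pos = pos, ref = ref, alt = alt,
        class = "intronic", planted = TRUE)
    }

    # background SNPs, avoiding planted windows
    avoid <- unlist(lapply(planted, function(pl)
      if (pl$gene_id == gene_id) (pl$pos - 8L):(pl$pos + 8L) else NULL))
    cand_pos <- setdiff(seq(gene_start, gene_end - 1L), avoid)
    n_bg <- min(cfg$n_null_snps_per_gene, length(cand_pos))
    for (pos in sample(cand_pos, n_bg)) {
      snp_counter <- snp_counter + 1L
      in_exon <- any(pos >= starts & pos < ends)
      ref <- gene_seq[pos - gene_start + 1L]
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        snp_id = sprintf("snp%05d", snp_counter), chrom = "1", pos = pos,
        ref = ref, alt = sample(setdiff(DNA_BASES, ref), 1L),
        class = if (in_exon) "exonic" else "intronic", planted = FALSE)
    }

    chrom_chars <- c(chrom_chars,
                     sample(DNA_BASES, gene_start - cursor, replace = TRUE),
                     gene_seq)
    cursor <- gene_end
  }

  genome <- genome_ref(c("1" = paste(chrom_chars, collapse = "")))
  models <- gene_models(do.call(rbind, model_rows))
  snps <- do.call(rbind, snp_rows)
  snps$maf <- stats::runif(nrow(snps), cfg$maf_range[1], cfg$maf_range[2])
  planted_df <- if (length(planted)) do.call(rbind, planted) else
    data.frame(snp_id = character(), gene_id = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               motif = character(), pos_in_motif = integer(), side = character(),
               exon_id = character(), exon_start = integer(),
               exon_end = integer(), distance_bp = integer())
  cassette_df <- if (length(cassettes)) do.call(rbind, cassettes) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), exon_id = character(), planted_snp = character())
  mdf <- as.data.frame(models)
  exon_map <- unique(data.frame(
    exon_id = sprintf("%s:%d-%d", mdf$gene_id, mdf$start, mdf$end),
    gene_id = mdf$gene_id, chrom = mdf$chrom, start = mdf$start, end = mdf$end))
  exon_map <- exon_map[order(exon_map$gene_id, exon_map$start), , drop = FALSE]
  rownames(exon_map) <- NULL
  list(genome = genome, models = models,
       snps = snp_table(snps), exon_map = exon_map, motifs = motifs,
       truth = list(planted = planted_df, cassette_exons = cassette_df))
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Counted-allele (alternate) dosages drawn independently per SNP as
#' `Binomial(2, maf)`.
#'
#' @param cfg a `sim_config`.
#' @param snps a `snp_table` with MAFs.
#' @return a `genotype_matrix` (SNPs x samples), counted allele = alt.
#' @export
simulate_genotypes <- function(cfg, snps) {
  set.seed(cfg$seed + 37L)
  s <- as.data.frame(snps)
  m <- matrix(stats::rbinom(nrow(s) * cfg$n_samples, 2L, rep(s$maf, cfg$n_samples)),
              nrow = nrow(s), ncol = cfg$n_samples,
              dimnames = list(s$snp_id, sprintf("S%03d", seq_len(cfg$n_samples))))
  genotype_matrix(m, stats::setNames(s$alt, s$snp_id))
}

#' Simulate exon- and gene-level expression with genotype-dependent SI
#'
#' Gene intensities are log-normal. The true Splicing Index of an exon in
#' a sample is `1 + s * dev` with a random sign `s` and deviation
#' magnitude `dev = beta_skip * dosage + |e|`, `e ~ N(0, si_noise_sd)`,
#' at cassette exons carrying a planted SNP, and `1 + e` elsewhere; SI is
#' truncated below at 0.01. `|1 - SI|` is therefore linear in dosage with
#' slope `beta_skip`, and the SI of dosage-0 samples fluctuates
#' symmetrically about 1. Exon intensity is gene intensity times SI.
#'
#' @param cfg a `sim_config`.
#' @param sim output of [simulate_genome_and_annotation()].
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @return list with `exon_expr`, `gene_expr` (matrices) and `si_true`.
#' @export
simulate_expression <- function(cfg, sim, genotypes) {
  set.seed(cfg$seed + 53L)
  em <- sim$exon_map
  genes <- unique(em$gene_id)
  n <- cfg$n_samples
  samples <- colnames(genotypes)
  gene_expr <- matrix(stats::rlnorm(length(genes) * n, log(200), 0.4),
                      nrow = length(genes), dimnames = list(genes, samples))
  planted <- sim$truth$planted
  si <- matrix(1 + stats::rnorm(nrow(em) * n, 0, cfg$si_noise_sd),
               nrow = nrow(em), dimnames = list(em$exon_id, samples))
  for (k in seq_len(nrow(planted))) {
    ex <- planted$exon_id[k]
    dos <- as.numeric(genotypes[planted$snp_id[k], samples])
    dev <- cfg$beta_skip * dos + abs(stats::rnorm(n, 0, cfg$si_noise_sd))
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    si[ex, ] <- 1 + sgn * dev
  }
  si <- pmax(si, 0.01)
  exon_expr <- gene_expr[em$gene_id, , drop = FALSE] * si
  rownames(exon_expr) <- em$exon_id
  list(exon_expr = exon_expr, gene_expr = gene_expr, si_true = si)
}

#' Simulate a trait-associated SNP catalog with planted enrichment
#'
#' Every SNP enters the catalog with base probability `trait_q0`; planted
#' exon-skipping ISE SNPs enter with their odds multiplied by
#' `trait_enrichment_odds`. Because the base probability is constant and
#' MAFs are independent of catalog membership, the catalog's MAF spectrum
#' matches the background by construction.
#'
#' @param cfg a `sim_config`.
#' @param sim output of [simulate_genome_and_annotation()].
#' @return a `trait_catalog` data frame (snp_id, trait).
#' @export
simulate_trait_catalog <- function(cfg, sim) {
  set.seed(cfg$seed + 71L)
  s <- as.data.frame(sim$snps)
  q0 <- cfg$trait_q0
  odds0 <- q0 / (1 - q0)
  odds1 <- odds0 * cfg$trait_enrichment_odds
  q1 <- odds1 / (1 + odds1)
  pr <- ifelse(s$snp_id %in% sim$truth$planted$snp_id, q1, q0)
  sel <- stats::runif(nrow(s)) < pr
  traits <- sprintf("trait_%02d", sample.int(20L, sum(sel), replace = TRUE))
  structure(data.frame(snp_id = s$snp_id[sel], trait = traits),
            class = c("trait_catalog", "data.frame"))
}

#' Simulate a complete study
#'
#' Runs the genome/annotation, genotype, expression and trait-catalog
#' generators in order under the configuration's seed; identical
#' configurations give identical output.
#'
#' @param cfg a `sim_config`.
#' @return list with `config`, `genome`, `models`, `snps`, `exon_map`,
#'   `motifs`, `truth`, `genotypes`, `exon_expr`, `gene_expr`, `si_true`,
#'   `trait_catalog`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  sim <- simulate_genome_and_annotation(cfg)
  genotypes <- simulate_genotypes(cfg, sim$snps)
  expr <- simulate_expression(cfg, sim, genotypes)
  catalog <- simulate_trait_catalog(cfg, sim)
  c(list(config = cfg), sim,
    list(genotypes = genotypes, exon_expr = expr$exon_expr,
         gene_expr = expr$gene_expr, si_true = expr$si_true,
         trait_catalog = catalog))
}

#' Simulate genotypes at two loci with a target LD
#'
#' Draws haplotypes for two biallelic loci with allele frequencies `pA`,
#' `pB` and disequilibrium `D = r * sqrt(pA qA pB qB)`, then pairs them
#' into unphased dosages; supports testing of the EM-based LD estimator.
#'
#' @param n number of individuals.
#' @param pA,pB counted-allele frequencies.
#' @param r target correlation between the two loci's haplotype alleles.
#' @return a `genotype_matrix` with rows `snpA`, `snpB`.
#' @export
simulate_ld_pair <- function(n, pA, pB, r = 0) {
  D <- r * sqrt(pA * (1 - pA) * pB * (1 - pB))
  h <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
         (1 - pA) * (1 - pB) + D)
  if (any(h < -1e-12)) stop_fmt("infeasible r for these allele frequencies")
  h <- pmax(h, 0); h <- h / sum(h)
  hap <- sample.int(4L, 2L * n, replace = TRUE, prob = h)
  a <- as.integer(hap %in% c(1L, 2L))
  b <- as.integer(hap %in% c(1L, 3L))
  m <- rbind(snpA = a[seq_len(n)] + a[n + seq_len(n)],
             snpB = b[seq_len(n)] + b[n + seq_len(n)])
  colnames(m) <- sprintf("S%03d", seq_len(n))
  genotype_matrix(m, c(snpA = "A", snpB = "A"))
}

#' Write all components of a simulated study to files
#'
#' Emits the external formats the readers in this package accept: genome
#' FASTA, genePred transcript models, SNP VCF, genotype TSV, exon- and
#' gene-level expression TSVs, exon map TSV, trait-catalog TSV, motif
#' list and a truth JSON.
#'
#' @param study output of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(outdir, "genome.fa"),
    models = file.path(outdir, "models.genePred"),
    snps = file.path(outdir, "snps.vcf"),
    genotypes = file.path(outdir, "genotypes.tsv"),
    exon_expr = file.path(outdir, "exon_expression.tsv"),
    gene_expr = file.path(outdir, "gene_expression.tsv"),
    exon_map = file.path(outdir, "exon_map.tsv"),
    traits = file.path(outdir, "trait_catalog.tsv"),
    motifs = file.path(outdir, "ise_motifs.txt"),
    truth = file.path(outdir, "truth.json"))
  write_fasta(study$genome, paths["genome"])
  write_gene_models(study$models, paths["models"])
  write_snps(study$snps, paths["snps"], dialect = "vcf")
  write_genotypes(study$genotypes, paths["genotypes"])
  write_expression(study$exon_expr, paths["exon_expr"], id_col = "exon_id")
  write_expression(study$gene_expr, paths["gene_expr"], id_col = "gene_id")
  write_exon_map(study$exon_map, paths["exon_map"])
  write_trait_catalog(study$trait_catalog, paths["traits"])
  write_motif_set(study$motifs, paths["motifs"])
  jsonlite::write_json(study$truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
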