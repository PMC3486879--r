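# Genotype -> exon-skipping association: additive linear regression of
# |1 - SI| on counted-allele dosage, Storey q-value FDR, per-genotype
# t-tests, and pairwise LD from unphased dosages.

ols_fit <- function(x, y) {
  n <- length(x)
  vx <- stats::var(x)
  beta <- stats::cov(x, y) / vx
  intercept <- mean(y) - beta * mean(x)
  r <- suppressWarnings(stats::cor(x, y))
  r2 <- r * r
  if (is.na(r2)) r2 <- 0
  resid <- y - intercept - beta * x
  df <- n - 2L
  se <- sqrt(sum(resid^2) / df / (vx * (n - 1L)))
  t <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(-abs(t), df)
  list(beta = beta, intercept = intercept, r_squared = r2, t = t, p = p, n = n)
}

#' Associate SNP genotype with exon skipping
#'
#' For every (SNP, exon) pair in `pairs`, ordinary least squares of the
#' skipping phenotype `|1 - SI|` on the counted-allele dosage under an
#' additive model. Samples with missing genotype or non-finite SI are
#' dropped pairwise. Pairs with fewer than 3 complete samples or fewer
#' than 2 distinct dosages are flagged untestable and excluded from FDR.
#'
#' @param genotypes a `genotype_matrix`.
#' @param si an `si_matrix` in ratio mode.
#' @param pairs data frame with `snp_id` and `exon_id` (e.g. the link
#'   table from [link_ise_snp_to_exons()]); duplicated pairs are tested
#'   once.
#' @param snps optional `snp_table` used to name the non-counted allele.
#' @param compute_q add Storey q-values over the testable pairs.
#' @return data frame of `association_result` rows: `snp_id`, `exon_id`,
#'   `beta`, `intercept`, `p_value`, `r_squared`, `q_value`, `n_used`,
#'   `testable`, `skipping_allele` (the allele whose dosage increases
#'   `|1 - SI|`).
#' @export
associate <- function(genotypes, si, pairs, snps = NULL, compute_q = TRUE) {
  pr <- unique(as.data.frame(pairs)[c("snp_id", "exon_id")])
  pr <- pr[pr$snp_id %in% rownames(genotypes) & pr$exon_id %in% rownames(si), ,
           drop = FALSE]
  counted <- attr(genotypes, "counted_allele")
  other <- NULL
  if (!is.null(snps)) {
    s <- as.data.frame(snps)
    oth <- ifelse(toupper(s$ref) == counted[s$snp_id], s$alt, s$ref)
    other <- stats::setNames(toupper(oth), s$snp_id)
  }
  samples <- intersect(colnames(genotypes), colnames(si))
  res <- lapply(seq_len(nrow(pr)), function(i) {
    x <- as.numeric(genotypes[pr$snp_id[i], samples])
    y <- abs(1 - as.numeric(si[pr$exon_id[i], samples]))
    ok <- !is.na(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    testable <- length(x) >= 3L && length(unique(x)) >= 2L
    if (!testable)
      return(data.frame(snp_id = pr$snp_id[i], exon_id = pr$exon_id[i],
                        beta = NA_real_, intercept = NA_real_,
                        p_value = NA_real_, r_squared = NA_real_,
                        n_used = length(x), testable = FALSE,
                        skipping_allele = NA_character_))
    f <- ols_fit(x, y)
    ca <- unname(counted[pr$snp_id[i]])
    skip_allele <- if (f$beta > 0) ca
    else if (!is.null(other)) unname(other[pr$snp_id[i]])
    else "other"
    data.frame(snp_id = pr$snp_id[i], exon_id = pr$exon_id[i],
               beta = f$beta, intercept = f$intercept, p_value = f$p,
               r_squared = f$r_squared, n_used = f$n, testable = TRUE,
               skipping_allele = skip_allele)
  })
  res <- do.call(rbind, res) %||%
    data.frame(snp_id = character(), exon_id = character(), beta = numeric(),
               intercept = numeric(), p_value = numeric(), r_squared = numeric(),
               n_used = integer(), testable = logical(),
               skipping_allele = character())
  res$q_value <- NA_real_
  if (compute_q && any(res$testable))
    res$q_value[res$testable] <- qvalues(res$p_value[res$testable])
  res
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.95 (step
#' 0.05) with the smoother method (natural cubic smoothing spline through
#' `pi0(lambda)`, evaluated at the largest lambda, clipped to (0, 1\]),
#' then applies the step-up `q_i = min_{p_j >= p_i} pi0 * m * p_j / rank_j`.
#' When fewer than 100 p-values are supplied, or the smoother fails,
#' pi0 = 1 is used, in which case q-values equal Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param pi0 optional fixed null proportion (e.g. 1 to force BH).
#' @param lambda grid for pi0 estimation.
#' @return q-values in input order.
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_fmt("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  if (is.null(pi0)) {
    pi0 <- if (m < 100L) 1 else tryCatch({
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      est <- stats::predict(fit, x = max(lambda))$y
      if (!is.finite(est) || est <= 0) 1 else min(est, 1)
    }, error = function(e) 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(pmin(q, 1)), 1)
  q[ro]
}

#' Filter association results at the reporting thresholds
#'
#' Strict inequalities throughout: `p < p_max`, `q < fdr_max`,
#' `r_squared > r2_min` (defaults 0.05, 0.10 and 0.03).
#'
#' @param results data frame from [associate()].
#' @param p_max,fdr_max,r2_min thresholds.
#' @return the subset of testable rows passing all three filters.
#' @export
filter_hits <- function(results, p_max = 0.05, fdr_max = 0.10, r2_min = 0.03) {
  r <- results[results$testable & !is.na(results$q_value), , drop = FALSE]
  r[r$p_value < p_max & r$q_value < fdr_max & r$r_squared > r2_min, , drop = FALSE]
}

#' Two-sample t-test between genotype groups
#'
#' Unpaired, two-tailed; Welch by default with a pooled-variance option.
#'
#' @param values numeric phenotype values (e.g. SI or `|1 - SI|`).
#' @param groups genotype label per value.
#' @param group_a,group_b the two genotype labels to compare.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return list with `t`, `p_value`, `n_a`, `n_b`, `testable`.
#' @export
genotype_group_ttest <- function(values, groups, group_a, group_b,
                                 var_equal = FALSE) {
  a <- values[groups == group_a & !is.na(values)]
  b <- values[groups == group_b & !is.na(values)]
  if (length(a) < 2L || length(b) < 2L ||
      (stats::var(a) == 0 && stats::var(b) == 0))
    return(list(t = NA_real_, p_value = NA_real_,
                n_a = length(a), n_b = length(b), testable = FALSE))
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       n_a = length(a), n_b = length(b), testable = TRUE)
}

#' Pairwise linkage disequilibrium from unphased dosages
#'
#' Two-locus haplotype frequencies are estimated from dosage data with
#' the standard EM algorithm (the double heterozygote being the only
#' ambiguous class), then `r^2 = D^2 / (pA pa pB pb)` and
#' `D' = |D| / Dmax`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param snp_a,snp_b SNP ids (rows of `genotypes`).
#' @param min_n minimum number of samples typed at both SNPs.
#' @param tol EM convergence tolerance on the haplotype frequency.
#' @return list with `snp_a`, `snp_b`, `r2`, `d_prime`, `n`, `testable`.
#' @export
pairwise_ld <- function(genotypes, snp_a, snp_b, min_n = 10L, tol = 1e-10) {
  ga <- as.numeric(genotypes[snp_a, ])
  gb <- as.numeric(genotypes[snp_b, ])
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  if (n < min_n) stop_fmt("fewer than %d samples typed at both SNPs", min_n)
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(snp_a = snp_a, snp_b = snp_b, r2 = NA_real_,
                d_prime = NA_real_, n = n, testable = FALSE))
  # haplotypes: 11 = counted-counted; only ga==1 & gb==1 is ambiguous
  dh <- ga == 1 & gb == 1
  # known counted-counted haplotype copies from unambiguous genotypes
  known11 <- sum((ga * gb / 2)[!dh])   # e.g. (2,2)->2, (2,1)->1, (1,2)->1, (2,0)->0 ...
  h11 <- pA * pB
  for (iter in 1:1000) {
    num <- h11 * (1 - pA - pB + h11)
    den <- num + (pA - h11) * (pB - h11)
    frac <- if (den > 0) num / den else 0.5
    h11_new <- (known11 + sum(dh) * frac) / (2 * n)
    if (abs(h11_new - h11) < tol) { h11 <- h11_new; break }
    h11 <- h11_new
  }
  D <- h11 - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D < 0) min(pA * pB, (1 - pA) * (1 - pB))
  else min(pA * (1 - pB), (1 - pA) * pB)
  list(snp_a = snp_a, snp_b = snp_b, r2 = r2,
       d_prime = if (dmax > 0) abs(D) / dmax else NA_real_, n = n,
       testable = TRUE)
}
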