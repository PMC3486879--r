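---
title: "Methods: ISE variants, exon skipping and trait enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ISE variants, exon skipping and trait enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`exonskip` implements an analysis chain that connects three layers of
evidence about intronic variation and alternative splicing:

1. **Sequence**: does an intronic SNP fall inside an intronic splicing
   enhancer (ISE) hexamer for at least one allele, and does it sit next
   to an exon that transcript models show to be skippable?
2. **Expression**: does genotype at such a SNP predict per-individual
   exon skipping, quantified by the Splicing Index?
3. **Trait genetics**: are such SNPs over-represented among
   trait-associated variants, beyond what their allele-frequency (and
   distance-to-exon) profile predicts?

This vignette documents the model behind each stage, the tunable
parameters and their defaults, what the synthetic-data generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

# Coordinate conventions

All internal coordinates are 0-based half-open; conversions happen only
at the I/O boundary (`read_gene_models()` converts GTF's 1-based closed
exons; `read_snps()` converts VCF's 1-based positions). Chromosome names
are normalized by stripping any `chr` prefix. A single convention inside
the package eliminates the classic off-by-one family of bugs when
distances, windows and overlaps are combined across modules.

Only biallelic single-nucleotide variants enter the pipeline: the
hexamer scan is defined by substituting one base at the window center,
which has no meaning for indels or multi-allelic records (these are
counted and dropped at read time). Minor allele frequencies are stored
folded (≤ 0.5); an input frequency above 0.5 is treated as an error
rather than silently folded, so that upstream allele-orientation
mistakes surface instead of propagating.

# Allele-aware motif scanning

For a SNP at position $p$, the window is the $2f+1$-base sequence
centered on $p$ with flank $f = 5$ (so an 11-base window), padded with
`N` beyond contig ends. The window is fragmented into the 6 hexamer
frames that contain the SNP: the first frame has the SNP in its last
position, and the frame slides upstream one base at a time until the SNP
is in the first position, so the SNP's 1-based position within the frame
takes each value $6, 5, \dots, 1$ exactly once. A frame matches a motif
by exact string equality only — the ISE resource is a list of discrete
hexamers, not a weight matrix — and frames containing `N` never match
(conservative). A SNP is an **ISE SNP** when at least one frame of at
least one allele matches.

Both alleles are always scanned. The per-allele hit profiles yield an
effect class: *loss* (reference-only hits), *gain* (alternate-only),
*retention shift* (both alleles hit, possibly different motifs), *none*
(identical hit sets, in particular both empty). In the documented case
studies either allele may be the motif-bearing one, which is why
ISE-SNP status is defined on either allele rather than on the reference.

**Strand.** ISE motifs are defined on pre-mRNA sense sequence, so the
scanner reads the strand of the host gene: for minus-strand genes the
window is reverse-complemented before framing (`strand = "-"`), which by
construction equals plus-strand scanning of the reverse-complemented
window. Where no host gene is known the default is plus-strand scanning.

**5′ss vs 3′ss motif lists.** The ISE resource distinguishes hexamers
enriched near 5′ and near 3′ splice sites. Whether the original analysis
applied them selectively by SNP side is not documented; the default here
is the union of both lists, with side-specific scanning available simply
by passing the individual `motif_set`s.

# Skipped exons and SNP–exon links

An exon, identified by exact genomic coordinates, is **skipped** when
some isoform of the gene contains it as an internal exon while at least
one isoform of the same gene contains no exon with identical
coordinates. First and last exons of an isoform are never used as
inclusion evidence — by definition they are neither "skipped" nor
"included" — and where an exon is terminal in one isoform and internal
in another, only the isoforms where it is internal count as evidence.

Two deliberate choices:

* **Exact coordinate identity.** Annotation sources disagree by a few
  bases at exon edges; treating near-identical exons as identical would
  require an arbitrary tolerance. The default is exact identity
  (tolerance 0); cross-source reconciliation is left to
  `merge_as_sources()`, which pools isoforms per gene and collapses
  duplicate transcripts.
* **Lenient vs strict cassette.** The lenient rule above ("absent from
  at least one isoform") also captures alternative-first/last-exon
  artifacts. `strict_cassette = TRUE` additionally requires the
  excluding isoform to retain both flanking exons of the candidate,
  which is the textbook cassette configuration. The lenient rule is the
  default because it is the rule the analysis chain is defined around.

A SNP links to exons through its host gene(s): the genes in whose
intron it lies (inside the gene span, in no exon, using the union of the
gene's exons across isoforms — SNPs are linked to *exons*, not to
specific isoforms). On each side of the SNP the nearest union exon is
reported with its distance — the number of bases strictly between the
SNP and the exon boundary, so a SNP adjacent to a splice site has
distance 0 — and with a flag for whether that exon is skipped. An
**exon-skipping ISE SNP** is an ISE SNP with at least one link to a
skipped exon. When a SNP carries a strand annotation, only host genes on
that strand are considered.

# Splicing Index

For exon $e$, gene $g(e)$ and sample $s$:

$$\mathrm{SI}(e,s) = \frac{x_{e,s}}{y_{g(e),s}}$$

with $x$ exon-level and $y$ gene-level normalized intensity. SI equals 1
under proportional inclusion, and $|1-\mathrm{SI}|$ is the skipping
phenotype. A sample *calls* an exon spliced when $\mathrm{SI} > 1.2$ or
$\mathrm{SI} < 0.8$, strict inequalities exactly as printed in the
source analysis; exons skipped in strictly more than
$\lceil 0.10\,n \rceil$ individuals (18 of 176) are "frequently
skipped".

**Ratio vs log-ratio.** The source description calls SI a log-ratio, but
its thresholds (0.8/1.2) and the $|1-\mathrm{SI}|$ phenotype centered at
1 are only coherent on the ratio scale — on a log scale "no change" is 0,
not 1. The package's default is therefore the ratio; `log2_ratio` is
retained behind a flag and warns when skip calls are attempted on it.
This conflict is resolved by explicit default rather than silently.

**Degenerate input.** Gene intensities below a floor (default $10^{-6}$
times the matrix median) make the ratio numerically meaningless; those
entries are reported `NaN` and excluded from skip calls and association.

**Array-to-model exon mapping.** An array exon maps to a model exon when
more than 95% of the array exon's length and more than 90% of the model
exon's length overlap; among multiple accepted candidates the pair
maximizing the summed fractions wins, greedily one-to-one. The
proprietary probeset annotation is replaced by an explicit exon-map
table (`exon_id`, `gene_id`, coordinates) supplied with the expression
matrices.

# Association and FDR

For each (SNP, exon) pair from the link table, ordinary least squares of
$|1-\mathrm{SI}|$ on counted-allele dosage (additive model), two-sided p
from the slope's t statistic, $R^2$ the squared Pearson correlation.
Missing genotypes and non-finite SI are dropped pairwise; pairs with
fewer than 3 complete samples or a monomorphic dosage are flagged
untestable and excluded from FDR. The *skipping-associated allele* is
the counted allele when the slope is positive, otherwise the other
allele; recoding the counted allele flips the slope's sign and the
allele label and leaves p and $R^2$ unchanged.

Reported hits satisfy strict `p < 0.05`, `q < 0.10` and `R² > 0.03`.
q-values follow Storey's method: $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0.05, \dots, 0.95$, smoothed with a cubic smoothing spline
(df = 3) and read off at the largest $\lambda$, then the standard
step-up with a cumulative minimum. With fewer than 100 p-values the
smoother is unreliable, so $\pi_0 = 1$ is used, which makes the
q-values exactly Benjamini–Hochberg — the test suite asserts that
identity against `stats::p.adjust`.

Genotype-group comparisons use an unpaired two-tailed t-test, Welch by
default (the source analysis specifies only "non-paired and
two-tailed"; unequal group variances are the safer default), with a
pooled-variance option. Pairwise LD is estimated from unphased dosages
by the standard two-locus EM (the double heterozygote is the only
ambiguous class), giving $r^2 = D^2/(p_A q_A p_B q_B)$ and
$D' = |D|/D_{\max}$.

# Covariate-matched enrichment

The null question: given the query set's MAF spectrum (and optionally
its distance-to-nearest-exon distribution), how many exon-skipping ISE
SNPs would a random set of the same size and covariate profile contain?
1000 random sets are drawn from the intronic background, each
reproducing the query's per-bin counts exactly; sampling is without
replacement within a set and independent across sets. The empirical
p-value is $(1 + \#\{\text{null} \ge \text{observed}\})/(N+1)$ — ties
count toward the null, and the estimator never returns exactly zero, so
"p < 0.001" at 1000 draws corresponds to the observed count exceeding
every null draw.

Bin construction is declared configuration, not inferred intent: MAF
bins of width 0.05 over [0, 0.5] (10 bins), and 8 distance bins spaced
in log10 because distances to exons span orders of magnitude. Query
SNPs are not excluded from the sampling pool by default (the original
procedure does not exclude them); `exclude_query = TRUE` is available.
Distance-stratified enrichment restricts the annotation to exon-skipping
ISE SNPs strictly within 60, 200, 1000 and 5000 bp of their skipped
exon, one matched test per stratum.

# Distances

The nearest-exon distance of an intronic SNP is the minimum boundary gap
over the union exons of its host gene(s) — gene-annotation-based, not
genome-wide, mirroring how the quantity is defined in the source
analysis; host-gene scope also makes the invariant "nearest-exon
distance ≤ skipped-exon distance" hold by construction, which the test
suite checks across simulated genomes. Distribution comparisons use the
two-sample Kolmogorov–Smirnov test (`stats::ks.test`, exact for small
samples), and per-group summaries report mean, median and sample SD
(n−1 denominator), with SD absent for singleton groups.

# The synthetic-data generator

`simulate_study()` produces every input the pipeline reads, with the
structure the analysis assumes:

* **Genes** laid end to end on one chromosome: 4–8 exons of 80–200 bp,
  introns of 300–3000 bp, a full-length isoform per gene, and each
  internal exon turned into a cassette (an extra isoform lacking exactly
  that exon) with probability 0.5.
* **Planted ISE SNPs**: for 80% of cassette exons, a motif from the
  simulated ISE set (127 hexamers, the size of the 5′ss-proximal ISE
  list) is written into an adjacent intron at a log-uniform distance
  from the exon; the reference allele is the motif base at the SNP
  position, and the alternate allele is chosen so that no frame of the
  alternate window matches any motif (a clean motif-loss variant). Only
  the 5 window bases outside the motif are regenerated to guarantee
  this; sequence elsewhere is left alone, so accidental ISE SNPs among
  the background SNPs are legitimate nulls, as they are in real data.
* **Genotypes**: Hardy–Weinberg at each SNP's MAF (uniform on
  [0.05, 0.5]), independent across SNPs; 176 samples, matching the
  cohort size the analysis was designed around. A two-locus haplotype
  generator with target $r$ supports the LD estimator's tests.
* **Expression**: gene intensities log-normal; the true SI of a planted
  cassette exon is $1 + s\,(\beta d + |e|)$ with random sign $s$,
  dosage $d$ at the planted SNP, $\beta = 0.15$ per allele copy and
  $e \sim N(0, 0.05)$; other exons get $1 + e$. SI is truncated below
  at 0.01. This makes $|1-\mathrm{SI}| = \beta d + |e|$ *exactly linear
  in dosage* — so the association stage's slope estimate is unbiased for
  $\beta$ — while dosage-0 samples fluctuate symmetrically about
  SI = 1 with Gaussian noise. A formulation with two-sided noise inside
  the magnitude (e.g. $|\beta d + e|$) would fold the noise at low
  dosage and attenuate the recovered slope; the half-normal magnitude
  with a random deviation sign is the formulation under which the
  generator's stated contract (effect $\beta$ on $|1-\mathrm{SI}|$ per
  copy, SI centered at 1 under the null) is exactly true.
* **Trait catalog**: every SNP enters with base probability 0.05;
  planted exon-skipping ISE SNPs have their odds multiplied by the
  enrichment-odds parameter (default 5). With constant base probability
  and MAFs independent of membership, the catalog's MAF spectrum matches
  the background by construction, so the matched enrichment test is
  calibrated under odds = 1.

Everything is deterministic given the configuration: each stage seeds
from `cfg$seed` plus a small fixed offset, so identical configurations
give byte-identical outputs, and the whole study regenerates from a
single integer.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: realistic human site-frequency spectra and
recombination (no LD between planted SNPs by default), population
structure (no CEU/YRI distinction), cross-annotation-source exon
boundary noise, probe-level array effects upstream of the normalized
intensities, and motif biology beyond exact hexamer matching (no
cooperative or distance-dependent ISE action). The generator validates
the *statistical machinery*, not the biological discovery.

# Problem sizes and test design

The test suite exercises the brute-force oracle equivalences on 10,000
random windows and 1,000 random toy gene models, enrichment calibration
on 500 replicate null catalogs (200 draws each) over a 40-gene genome,
null-effect FDR control on 200 replicate cohorts of 176 samples over a
30-gene genome, and effect recovery on a single 150-gene genome with
over 200 planted SNPs. These sizes were chosen so the full suite runs
in a few minutes while keeping Monte-Carlo error well below the margins
being asserted; all of them are plain parameters in the test files and
scale up directly.

# Known limitations

* Exact hexamer matching only; no position-weight matrices or
  degenerate motifs, and no ESE/ESS/ISS resources are bundled.
* Exon-skipping detection covers cassette exons only — not alternative
  5′/3′ splice sites, intron retention or mutually exclusive exons.
* The association stage fits no covariates and no population-structure
  correction; stratified analysis is possible by subsetting samples.
* cis-eQTL status is consumed as an annotation on input SNP sets (the
  4 Mb / p < 0.01 definition is a labeling convention); the package
  does not perform eQTL discovery.
* The minimal VCF reader covers the biallelic-SNV subset the pipeline
  needs (CHROM/POS/ID/REF/ALT plus `CLASS`/`MAF` INFO keys), not the
  full VCF specification.
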