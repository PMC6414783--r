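---
title: "Methods: allele-specific expression detection and its validation in asecow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression detection and its validation in asecow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asecow)
```

## The problem

In a heterozygous individual the two alleles of a gene can be transcribed
unequally — allele-specific expression (ASE). ASE is the observable
footprint of cis-acting regulation (promoter/enhancer variants, allele-
specific miRNA targeting), of imprinting, and of nonsense-mediated decay,
and in livestock genetics it points at candidate causal variants inside
QTL intervals. `asecow` implements the complete analytical chain for
calling ASE from paired whole-genome (DNA) and RNA sequencing of a small
cattle cohort (around 19 animals in the motivating design) and for tracing
called ASE SNPs back to candidate cis-regulatory variants, together with a
synthetic-cohort generator so that every stage can be exercised and tested
without any sequencing data.

## Model and procedure

### DNA/RNA genotype concordance

For each animal, genotypes called from DNA and from RNA at the same site
are paired and classified: `BH` (both homozygous), `Bh` (both
heterozygous), `Hh` (DNA-hom / RNA-het, the signature expected from RNA
editing) and `hH` (DNA-het / RNA-hom, expected from imprinting or
mono-allelic expression). The concordant rate is $100\,(BH+Bh)/\text{overlap}$.
Two cohort-level rates are reported deliberately: the unweighted mean of
per-animal rates and the pooled rate computed from mean class counts.
These differ whenever animals have different overlap sizes and neither is
canonical, so `cohort_concordance()` emits both. Only `Bh`
(heterozygous-concordant) pairs proceed to ASE testing: allelic imbalance
is only interpretable where both assays agree the animal is heterozygous,
and dropping discordant sites removes imprinting/editing/genotyping-error
artefacts up front.

Multi-allelic sites are excluded from pairing (the analysis is SNP-only)
with a message; sites seen in one assay are tallied (`dna_only`,
`rna_only`) but never classified. Rates are kept at full precision
internally and rounded half-up to one decimal only at the reporting
boundary (`round_half_up()`).

### Binomial ASE detection

At a heterozygous-concordant site with `ref_count` + `alt_count` = $n$
reads, the alternate count is modelled as Binomial($n$, 0.5) under no
imbalance. `binomial_ase_test()` computes the exact two-sided p-value by
small-pmf summation — the sum of $P(X=i)$ over all outcomes no more likely
than the observed one — which matches the convention of `binom.test()`
(used as an independent oracle in the test suite, never as the
implementation). A site is flagged ASE iff $p < \alpha$ (default 0.05)
**and** at least one allele has ≥ 10 reads (`depth_filter()`); the depth
rule discards sites where the test has essentially no power while keeping
strongly mono-allelic sites (10/0 passes).

Two choices deserve emphasis:

* **No multiple-testing correction across sites by default.** Detection
  uses a plain per-site 5% threshold; this is the documented behaviour of
  the procedure being reproduced. An optional `fdr = TRUE` flag applies
  Benjamini–Hochberg for users who want genome-wide control.
* **Cohort-level ASE** is defined as "flagged in at least one animal";
  distinct sites are deduplicated when counting.

Calls inside copy-number-variable regions are unflagged
(`excluded_reason = "cnv_region"`) because allelic ratios there reflect
copy number, not regulation. Interval logic is BED-convention 0-based
half-open, applied to `pos − 1`, via `GenomicRanges::findOverlaps()`.
QTL annotation attaches every containing region label to each ASE SNP;
`chromosome_distribution()` rank-correlates per-chromosome ASE counts with
chromosome size and (expressed) gene counts.

### Reference-mapping bias and N-masking

Reads carrying the alternate allele mismatch the reference at the variant
site, so under a strict aligner mismatch budget they are preferentially
lost and the reference allele is overcounted — an apparent ASE artefact.
The remedy is N-masking: replacing the variant base in the reference with
N so both alleles align equally well. `simulate_read_mapping()` reproduces
this mechanism with deliberately minimal machinery: fixed-length
(default 20 nt) error-free reads compared ungapped at their true position,
a configurable mismatch budget (default 0), and an N that matches any
base. With an unmasked reference and a zero budget the alternate fraction
at a balanced het site is exactly 0; masked, it is binomial around 0.5.
The test suite verifies this at depth $10^4$ within 3 analytic standard
deviations. The model intentionally omits realistic error profiles,
multi-mapping and indels — it demonstrates the bias mechanism and its
removal, nothing more.

### LD-aware genotype–expression correlation

Transcript counts are normalized by median-of-ratios size factors:
$sf_j = \exp\left(\mathrm{median}_i\left(\log c_{ij} - \overline{\log c_{i\cdot}}\right)\right)$
over transcripts positive in every sample, rescaled to geometric mean 1 so
normalization is idempotent. The log-space median matches the behaviour of
the standard implementations (the suite cross-checks against
`DESeq2::estimateSizeFactorsForMatrix()` up to that overall scale, which
the reference leaves free). Transcripts expressed in fewer than 3 animals
are dropped.

Because a called ASE SNP is usually a marker for, not the cause of, the
regulatory difference, each ASE SNP is expanded to its intra-chromosomal
LD partners with genotype-dosage $r^2 \ge 0.75$ (inclusive; each SNP is
its own partner). $r^2$ is the squared Pearson correlation of 0/1/2
dosages over pairwise-complete animals — the composite (unphased) measure,
which approximates haplotype $r^2$ under Hardy–Weinberg equilibrium; no
phasing is attempted. SNPs with any missing genotype are excluded from
correlation testing (the analysis requires complete genotypes), and a
constant dosage vector yields `NA`, never a silent 0.

Each partner SNP is tested against the transcript by Spearman rank
correlation (average ranks for ties). The two-sided p-value is exact by
full permutation enumeration for $n \le 9$ and uses the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation otherwise; at the working
cohort size ($n = 19$) the suite checks the approximation against a
10,000-draw permutation oracle. Within each transcript, p-values receive a
Bonferroni adjustment over the $m$ SNPs tested against that transcript,
$q = \min(1, m\,p)$ — note this "q-value" is a Bonferroni-adjusted p, not
an FDR q-value; the naming follows the convention of the reproduced
analysis. A pair is significant iff $|\rho| > 0.6$ and $q < 0.05$.

### Allele-specific regulatory sites

For a candidate SNP, `extract_flanks()` builds the ±100 nt (miRNA) or
±10 nt (TFBS) window in two versions, one per allele, clipping at contig
ends with a truncation flag and refusing to proceed if the stated
reference allele disagrees with the genome.

`mirna_scan()` is a fully specified seed-plus-extension scheme, not a
re-implementation of any external target predictor: a candidate site
requires perfect Watson–Crick complementarity of miRNA positions 2–8 in
the antiparallel orientation, and the whole ungapped duplex is then scored
+5 per Watson–Crick pair, +1 per G:U wobble, −3 per mismatch (positions
running off the target count as mismatches; N never pairs), with a passing
threshold of 60 by default. Because the seed must be perfect, only the
`8mer` (A opposite miRNA position 1) and `7mer-m8` classes can occur; the
weaker classes remain in the vocabulary for completeness. Scores and
thresholds are configuration knobs, and results are **not** expected to
match any specific external scanner site-for-site. Site presence is binary
per allele (≥ 1 passing hit anywhere in the flank), and
`differential_sites()` partitions the panel into reference-only,
alternate-only and both — swapping alleles provably swaps the first two
lists. `pwm_match()` handles the TFBS analogue: both strands are scanned
with a 4×width log-odds matrix and windows scoring ≥ 85% of the maximum
attainable score are matches.

### Pyrosequencing validation arithmetic

The wet-lab confirmation assay measures allele percentages in genomic DNA
and cDNA of the same animal. The ASE ratio is
$$\text{ASE ratio} = \frac{(\text{allele1\%}/\text{allele2\%})_{\text{cDNA}}}{(\text{allele1\%}/\text{allele2\%})_{\text{gDNA}}},$$
1.0 meaning the cDNA balance mirrors the genomic one. It is exactly
reciprocal under allele swap and invariant to common rescaling.
`validate_snp()` operationalizes the published decision as: gDNA allele-1
percentage within 30–70% confirms heterozygosity, and a cDNA−gDNA shift
greater than the 4% replicate-variation detectability limit validates the
SNP. The original report does not state a numeric rule, so both knobs are
explicit parameters; the 30–70/4% defaults are one defensible
formalization. Complementary-strand assays are documented with an explicit
flag, never silently re-complemented — allele percentages are
strand-independent.

## The synthetic cohort generator

`generate_cohort(sim_config(...))` emits everything the pipeline consumes,
with truth labels. Default parameters and what they emulate:

| parameter | default | rationale |
|---|---|---|
| `n_individuals` | 19 | the motivating cohort size |
| `chrom_lengths` | 3 × 1 Mb | enough chromosomes for intra-chromosomal logic |
| `ld_block_size` | 10 SNPs | blocks copied from two founder haplotypes, zero within-block recombination: $r^2 = 1$ within, ~0 across — simpler than a coalescent and sufficient for threshold logic |
| `alt_allele_freq_range` | (0.1, 0.9) | segregating variants of mixed informativeness |
| depth | NB(mean 60, size 5) | the depth distribution of covered RNA-Seq sites is not reported anywhere authoritative; mean 60 is a free but realistic choice for ~50M-read muscle libraries |
| `p_ase`, `ase_fraction` | 0.1, 0.70 | a minority of sites truly imbalanced, at an effect size comparable to validated examples (0.60–0.72) |
| `overdispersion` | 0 | the detection test assumes binomial counts; raise rho to violate that assumption deliberately in robustness tests |
| `p_editing`, `p_imprinting`, `p_genotype_error` | 0.30, 0.04, 0.005 | calibrated analytically so a default cohort shows ~10% pair discordance split roughly 84/16 between Hh and hH, the pattern seen in muscle RNA-Seq vs WGS comparisons; these model *apparent* discordance (technical plus biological), not biological editing rates |
| `cis_effect_size` | 2 | a two-fold expression effect per alternate allele at cis-driven transcripts |
| `read_length` | 20 nt | minimal error-free read model that still exhibits mapping bias |

Imprinted sites render every DNA-het animal RNA-homozygous; edited sites
render every DNA-hom-ref animal RNA-heterozygous; genotype errors
perturb individual RNA calls. Allele counts exist only where simulated
depth is positive and always conserve depth.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: alignment and variant-calling error
structure, read-level base qualities, splicing, correlated depth along a
gene, population structure beyond two founders per block, and trans
regulation. The generator validates the statistical machinery, not the
upstream bioinformatics.

## Numerical and design choices

* Exact binomial p-values use the `1 + 1e-7` relative slack when comparing
  pmf values, the standard guard against floating-point ties; at the 0.5
  null the sum collapses to a symmetric tail formula.
* Spearman exact enumeration is capped at $n \le 9$ ($9! = 362{,}880$
  permutations); beyond that the t approximation is used.
* Size factors are geometric-mean-centred (see above); a matrix with no
  all-positive transcript is an error with guidance, not a silent
  fallback.
* Internal coordinates are 1-based (VCF-native); BED files are converted
  at the boundary, and the CNV/QTL containment test is
  `start <= pos − 1 < end`.
* Concordance with an empty overlap yields `NA` rates with a warning,
  never 0.
* The seed-site planter inserts the full reverse complement of the miRNA
  (so planted sites clear the default score threshold) and breaks the
  seed with a base that neither pairs nor wobbles, opposite miRNA
  position 5.
* Monomorphic or rare planted cis variants are not recoverable under the
  $|\rho| > 0.6$ filter with 19 animals (a variant carried by two animals
  caps the attainable rank correlation below 0.6); the recovery tests
  therefore plant intermediate-frequency variants, mirroring the published
  8/7/4 genotype-group example.

## Problem sizes used by the test suite

The suite runs the type-I-error property on 20,000 simulated balanced
sites (depths 20–200), power monotonicity on a 3×3 grid of 3,000 sites
per cell, N-masking at depth 10,000, and cis-effect recovery on 200
seeded replicates of a 19-animal, 40-SNP, 30-transcript cohort. These
sizes give Monte-Carlo error comfortably below the asserted margins while
keeping a full run under a minute of compute.

## Known limitations

* The detection step inherits the reproduced procedure's lack of
  genome-wide multiplicity control; interpret pooled counts accordingly.
* Dosage $r^2$ understates haplotype $r^2$ away from Hardy–Weinberg
  equilibrium.
* The miRNA scanner is a transparent scoring scheme for allele
  *differencing*; it is not a validated target predictor and its absolute
  site lists should not be compared with thermodynamic tools.
* Pyrosequencing validation encodes one formalization of a decision that
  in practice also involves expert judgement.
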