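#' Configuration for the synthetic ASE cohort generator
#'
#' Defines the statistical structure of a simulated cattle cohort: diploid
#' genotypes for `n_individuals` animals with intra-chromosomal LD blocks,
#' heterozygous-site RNA allele counts with configurable imbalance and
#' beta-binomial overdispersion, DNA/RNA genotype discordance from
#' imprinting-like (DNA-het, RNA-hom), editing-like (DNA-hom, RNA-het) and
#' genotype-error processes, transcript counts with multiplicative cis
#' genotype effects, and 3'UTR flank sequences carrying planted miRNA seed
#' sites broken by one allele.
#'
#' @param n_individuals number of diploid individuals (default 19, the size
#'   of a typical small ASE discovery cohort of the kind this pipeline
#'   targets).
#' @param n_snps total number of SNPs, spread across chromosomes
#'   proportionally to `chrom_lengths`.
#' @param chrom_lengths named integer vector, chromosome -> length in bp.
#' @param ld_block_size number of consecutive SNPs per LD block; within a
#'   block haplotypes are copied from two founders with zero recombination,
#'   so adjacent-SNP genotype r-squared is 1 within a block and ~0 across.
#' @param alt_allele_freq_range length-2 probabilities; each block's
#'   alternate-haplotype frequency is drawn uniformly from this range.
#' @param depth_mean,depth_dispersion negative-binomial RNA read depth per
#'   site and individual (mean and size). Defaults: mean 60, size 5.
#' @param p_ase probability that a polymorphic site is a true-ASE site.
#' @param ase_fraction expected fraction of RNA reads carrying the alternate
#'   allele at a true-ASE heterozygous site.
#' @param overdispersion beta-binomial intraclass correlation rho >= 0 for
#'   allele counts; 0 recovers the pure binomial the imbalance test assumes.
#' @param p_imprinting probability a site is imprinted: every DNA-het
#'   individual is mono-allelic (RNA-hom) there.
#' @param p_editing probability a site is edited: every DNA-hom-ref
#'   individual appears RNA-het there. The defaults (0.30 editing, 0.04
#'   imprinting, 0.005 per-call error) are calibrated analytically so a
#'   default cohort shows the ~10% DNA/RNA pair discordance with a roughly
#'   84/16 Hh/hH split typical of muscle RNA-Seq vs WGS comparisons; they
#'   model apparent (technical + biological) discordance, not biological
#'   editing rates.
#' @param p_genotype_error per-call probability that the RNA genotype is
#'   replaced by a different random genotype.
#' @param base_error_rate per-read probability of observing the wrong allele
#'   at a homozygous site.
#' @param n_transcripts number of transcripts in the expression matrix.
#' @param p_cis probability a transcript carries an active cis effect tied
#'   to a randomly assigned SNP.
#' @param cis_effect_size multiplicative expression effect per alternate
#'   allele copy at a transcript's cis SNP.
#' @param expression_mean,expression_dispersion negative-binomial baseline
#'   transcript counts (mean and size).
#' @param read_length length of simulated error-free reads used by the
#'   reference-bias mapping simulation.
#' @param n_utr_loci number of 3'UTR loci with a planted miRNA seed site
#'   broken by the alternate allele.
#' @param seed integer seed; the whole cohort is reproducible given it.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_individuals = 19,
                       n_snps = 300,
                       chrom_lengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                       ld_block_size = 10,
                       alt_allele_freq_range = c(0.1, 0.9),
                       depth_mean = 60,
                       depth_dispersion = 5,
                       p_ase = 0.1,
                       ase_fraction = 0.7,
                       overdispersion = 0,
                       p_imprinting = 0.04,
                       p_editing = 0.30,
                       p_genotype_error = 0.005,
                       base_error_rate = 0.001,
                       n_transcripts = 40,
                       p_cis = 0.25,
                       cis_effect_size = 2,
                       expression_mean = 300,
                       expression_dispersion = 20,
                       read_length = 20,
                       n_utr_loci = 2,
                       seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 2) {
    stop("config field 'n_individuals' must be >= 2")
  }
  if (!is.numeric(n_snps) || n_snps < 1) {
    stop("config field 'n_snps' must be >= 1")
  }
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("config field 'chrom_lengths' must be a named vector of positive lengths")
  }
  if (ld_block_size < 1) stop("config field 'ld_block_size' must be >= 1")
  if (length(alt_allele_freq_range) != 2 ||
      any(alt_allele_freq_range < 0) || any(alt_allele_freq_range > 1) ||
      alt_allele_freq_range[1] > alt_allele_freq_range[2]) {
    stop("config field 'alt_allele_freq_range' must be an increasing pair of probabilities")
  }
  if (depth_mean <= 0) stop("config field 'depth_mean' must be > 0")
  if (depth_dispersion <= 0) stop("config field 'depth_dispersion' must be > 0")
  for (nm in c("p_ase", "ase_fraction", "p_imprinting", "p_editing",
               "p_genotype_error", "base_error_rate", "p_cis")) {
    check_prob(get(nm), nm)
  }
  if (overdispersion < 0 || overdispersion >= 1) {
    stop("config field 'overdispersion' must be a rho in [0,1)")
  }
  if (cis_effect_size <= 0) stop("config field 'cis_effect_size' must be > 0")
  if (expression_mean <= 0) stop("config field 'expression_mean' must be > 0")
  if (read_length < 3) stop("config field 'read_length' must be >= 3")

  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    chrom_lengths = chrom_lengths, ld_block_size = as.integer(ld_block_size),
    alt_allele_freq_range = alt_allele_freq_range,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    p_ase = p_ase, ase_fraction = ase_fraction,
    overdispersion = overdispersion,
    p_imprinting = p_imprinting, p_editing = p_editing,
    p_genotype_error = p_genotype_error, base_error_rate = base_error_rate,
    n_transcripts = as.integer(n_transcripts), p_cis = p_cis,
    cis_effect_size = cis_effect_size,
    expression_mean = expression_mean,
    expression_dispersion = expression_dispersion,
    read_length = as.integer(read_length),
    n_utr_loci = as.integer(n_utr_loci),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_individuals, "individuals,", x$n_snps, "SNPs on",
      length(x$chrom_lengths), "chromosomes\n")
  cat("  ASE: p_ase =", x$p_ase, "ase_fraction =", x$ase_fraction,
      "rho =", x$overdispersion, "\n")
  cat("  discordance: imprinting", x$p_imprinting, "editing", x$p_editing,
      "error", x$p_genotype_error, "\n")
  cat("  cis effect:", x$cis_effect_size, "x per alt allele, seed", x$seed, "\n")
  invisible(x)
}
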