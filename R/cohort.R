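GT_LEVELS <- c("hom_ref", "het", "hom_alt")

dosage_to_gt <- function(d) {
  out <- rep(NA_character_, length(d))
  ok <- !is.na(d)
  out[ok] <- GT_LEVELS[d[ok] + 1L]
  out
}

gt_to_dosage <- function(gt) {
  match(gt, GT_LEVELS) - 1L
}

#' Simulate per-allele RNA read counts at one or more sites
#'
#' At a heterozygous site the alternate-allele count is beta-binomial
#' (`depth`, `ase_fraction`, `overdispersion`); `overdispersion = 0` is the
#' pure binomial assumed by the imbalance test. At a homozygous site all
#' reads carry the single allele except a base-error rate.
#'
#' @param genotype character vector in `hom_ref`/`het`/`hom_alt` (or dosage
#'   0/1/2).
#' @param depth non-negative integer read depth(s).
#' @param ase_fraction expected fraction of reads carrying the alternate
#'   allele at het sites.
#' @param overdispersion beta-binomial rho in [0,1); 0 = binomial.
#' @param base_error_rate per-read error probability at hom sites.
#' @param seed optional integer seed.
#' @return data.frame with columns `ref_count`, `alt_count`.
#' @export
simulate_allele_counts <- function(genotype, depth, ase_fraction = 0.5,
                                   overdispersion = 0, base_error_rate = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(depth < 0)) stop("depth must be >= 0")
  if (any(overdispersion < 0)) stop("overdispersion rho must be >= 0")
  if (is.numeric(genotype)) genotype <- dosage_to_gt(genotype)
  n <- max(length(genotype), length(depth))
  genotype <- rep_len(genotype, n)
  depth <- rep_len(as.integer(depth), n)
  ase_fraction <- rep_len(ase_fraction, n)

  alt <- integer(n)
  het <- genotype == "het"
  if (any(het)) {
    alt[het] <- rbetabinom(sum(het), depth[het], ase_fraction[het],
                           overdispersion)
  }
  hom_alt <- genotype == "hom_alt"
  hom_ref <- genotype == "hom_ref"
  if (base_error_rate > 0) {
    alt[hom_alt] <- depth[hom_alt] -
      stats::rbinom(sum(hom_alt), depth[hom_alt], base_error_rate)
    alt[hom_ref] <- stats::rbinom(sum(hom_ref), depth[hom_ref],
                                  base_error_rate)
  } else {
    alt[hom_alt] <- depth[hom_alt]
    alt[hom_ref] <- 0L
  }
  data.frame(ref_count = depth - alt, alt_count = alt)
}

#' Generate a synthetic ASE cohort
#'
#' Produces DNA and RNA genotype matrices with LD-block structure,
#' per-allele RNA read counts at every covered site, a transcript count
#' matrix with planted cis genotype effects, 3'UTR flank sequences with
#' planted miRNA seed sites broken by one allele, and a complete truth table
#' so every downstream stage of the pipeline can be tested against known
#' labels.
#'
#' Discordance processes: imprinted sites render every DNA-heterozygous
#' individual mono-allelic in RNA (DNA-het / RNA-hom); edited sites render
#' every DNA-hom-ref individual RNA-heterozygous (DNA-hom / RNA-het);
#' genotype errors replace individual RNA calls at random.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `sites` (truth table: chrom, pos, ref, alt, block, true_ase,
#'   ase_fraction, imprinted, edited), `individuals`, `dna_genotypes` and
#'   `rna_genotypes` (site x individual dosage matrices, 0/1/2),
#'   `allele_counts` (long data.frame: chrom, pos, individual, ref_count,
#'   alt_count; only sites with RNA depth > 0), `expression` (transcript x
#'   individual raw counts), `cis_truth` (transcript, cis_snp, cis_active,
#'   effect_size), `sequences` (planted 3'UTR loci and miRNA panel), and
#'   `config`.
#' @examples
#' co <- generate_cohort(sim_config(n_snps = 50, seed = 42))
#' dim(co$dna_genotypes)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be created by sim_config()")
  }
  set.seed(config$seed)
  n_ind <- config$n_individuals
  individuals <- sprintf("ind%02d", seq_len(n_ind))

  ## --- sites: spread over chromosomes proportional to length ------------
  chrom_w <- config$chrom_lengths / sum(config$chrom_lengths)
  n_per <- as.vector(stats::rmultinom(1, config$n_snps, chrom_w))
  sites <- do.call(rbind, lapply(seq_along(config$chrom_lengths), function(i) {
    n <- n_per[i]
    if (n == 0) return(NULL)
    data.frame(chrom = names(config$chrom_lengths)[i],
               pos = sort(sample.int(config$chrom_lengths[[i]], n)))
  }))
  n_snps <- nrow(sites)
  sites$ref <- sample(DNA_BASES, n_snps, replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(b) sample(setdiff(DNA_BASES, b), 1), "")
  rownames(sites) <- NULL

  ## --- LD blocks: two founder haplotypes, zero within-block recomb ------
  blk <- unlist(lapply(split(seq_len(n_snps), sites$chrom), function(idx) {
    ceiling(seq_along(idx) / config$ld_block_size)
  }), use.names = FALSE)
  sites$block <- paste0(sites$chrom, "_b", blk)
  dna <- matrix(0L, n_snps, n_ind,
                dimnames = list(paste0(sites$chrom, ":", sites$pos),
                                individuals))
  for (b in unique(sites$block)) {
    idx <- which(sites$block == b)
    f <- stats::runif(1, config$alt_allele_freq_range[1],
                      config$alt_allele_freq_range[2])
    hap1 <- stats::rbinom(n_ind, 1, f)   # founder-alt carried on haplotype 1?
    hap2 <- stats::rbinom(n_ind, 1, f)
    dna[idx, ] <- matrix(rep(hap1 + hap2, each = length(idx)),
                         nrow = length(idx))
  }

  ## --- truth labels ------------------------------------------------------
  sites$true_ase <- stats::runif(n_snps) < config$p_ase
  sites$ase_fraction <- ifelse(sites$true_ase, config$ase_fraction, 0.5)
  sites$imprinted <- stats::runif(n_snps) < config$p_imprinting
  sites$edited <- !sites$imprinted &
    stats::runif(n_snps) < config$p_editing

  ## --- RNA genotypes from DNA plus discordance processes ----------------
  rna <- dna
  for (i in which(sites$imprinted)) {
    het <- which(dna[i, ] == 1L)
    if (length(het)) {
      rna[i, het] <- 2L * stats::rbinom(length(het), 1, 0.5)  # mono-allelic
    }
  }
  for (i in which(sites$edited)) {
    hom_ref <- which(dna[i, ] == 0L)
    if (length(hom_ref)) rna[i, hom_ref] <- 1L
  }
  if (config$p_genotype_error > 0) {
    err <- which(matrix(stats::runif(length(rna)) < config$p_genotype_error,
                        nrow(rna)))
    for (k in err) {
      rna[k] <- sample(setdiff(0:2, rna[k]), 1)
    }
  }

  ## --- allele counts at covered sites ------------------------------------
  depth <- matrix(stats::rnbinom(n_snps * n_ind, mu = config$depth_mean,
                                 size = config$depth_dispersion),
                  n_snps, n_ind)
  cov_idx <- which(depth > 0, arr.ind = TRUE)
  rna_gt <- dosage_to_gt(rna[cov_idx])
  frac <- sites$ase_fraction[cov_idx[, 1]]
  # imprinted sites are mono-allelic: counts follow the expressed (RNA)
  # genotype; edited hom-ref sites show a roughly balanced mix
  frac[sites$edited[cov_idx[, 1]] & dna[cov_idx] == 0L] <- 0.5
  cnt <- simulate_allele_counts(rna_gt, depth[cov_idx], frac,
                                config$overdispersion,
                                config$base_error_rate)
  allele_counts <- data.frame(
    chrom = sites$chrom[cov_idx[, 1]],
    pos = sites$pos[cov_idx[, 1]],
    individual = individuals[cov_idx[, 2]],
    ref_count = cnt$ref_count,
    alt_count = cnt$alt_count
  )
  allele_counts <- allele_counts[order(allele_counts$chrom, allele_counts$pos,
                                       allele_counts$individual), ]
  rownames(allele_counts) <- NULL

  ## --- transcript expression with cis effects ----------------------------
  tx <- sprintf("tx%03d", seq_len(config$n_transcripts))
  cis_snp <- rownames(dna)[sample.int(n_snps, config$n_transcripts,
                                      replace = TRUE)]
  cis_active <- stats::runif(config$n_transcripts) < config$p_cis
  mu <- matrix(config$expression_mean, config$n_transcripts, n_ind,
               dimnames = list(tx, individuals))
  for (t in which(cis_active)) {
    mu[t, ] <- mu[t, ] * config$cis_effect_size^dna[cis_snp[t], ]
  }
  expression <- matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = config$expression_dispersion),
                       nrow(mu), ncol(mu), dimnames = dimnames(mu))
  cis_truth <- data.frame(transcript = tx, cis_snp = cis_snp,
                          cis_active = cis_active,
                          effect_size = ifelse(cis_active,
                                               config$cis_effect_size, 1))

  ## --- 3'UTR loci with planted, allele-broken miRNA sites ----------------
  sequences <- list()
  if (config$n_utr_loci > 0) {
    for (i in seq_len(config$n_utr_loci)) {
      mirna <- paste(sample(DNA_BASES, 22, replace = TRUE), collapse = "")
      utr <- paste(sample(DNA_BASES, 201, replace = TRUE), collapse = "")
      planted <- plant_seed_site(utr, mirna, position = 60 + 30 * i,
                                 broken_by = "alt")
      sequences[[sprintf("utr%02d", i)]] <- c(
        planted,
        list(mirna_id = sprintf("mir-%02d", i), mirna_seq = mirna)
      )
    }
  }

  structure(list(sites = sites, individuals = individuals,
                 dna_genotypes = dna, rna_genotypes = rna,
                 allele_counts = allele_counts,
                 expression = expression, cis_truth = cis_truth,
                 sequences = sequences, config = config),
            class = "synthetic_cohort")
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$sites), "SNPs x", length(x$individuals),
      "individuals;", nrow(x$allele_counts), "covered allele-count records\n")
  cat("  true ASE sites:", sum(x$sites$true_ase),
      "| imprinted:", sum(x$sites$imprinted),
      "| edited:", sum(x$sites$edited), "\n")
  cat("  expression:", nrow(x$expression), "transcripts (",
      sum(x$cis_truth$cis_active), "with active cis effect )\n")
  invisible(x)
}

#' Long-format genotype calls from a cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @param assay `"DNA"` or `"RNA"`.
#' @return data.frame: chrom, pos, ref_allele, alt_allele, individual, gt,
#'   assay — one row per site/individual call.
#' @export
genotype_calls <- function(cohort, assay = c("DNA", "RNA")) {
  assay <- match.arg(assay)
  m <- if (assay == "DNA") cohort$dna_genotypes else cohort$rna_genotypes
  data.frame(
    chrom = rep(cohort$sites$chrom, ncol(m)),
    pos = rep(cohort$sites$pos, ncol(m)),
    ref_allele = rep(cohort$sites$ref, ncol(m)),
    alt_allele = rep(cohort$sites$alt, ncol(m)),
    individual = rep(colnames(m), each = nrow(m)),
    gt = dosage_to_gt(as.vector(m)),
    assay = assay
  )
}
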