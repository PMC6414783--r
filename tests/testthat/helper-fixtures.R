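# Printed per-individual DNA/RNA comparison table of the 19-animal cohort
# (class counts and rates as published); used to check table-internal
# arithmetic.
table2_printed <- function() {
  txt <- "
individual dna_only rna_only overlap BH Bh rate Hh hH
LIM01 11420182 19039 44861 27410 11354 86.4 4979 1118
LIM02 11549679 17681 46624 29535 12671 90.5 3974 444
LIM03 11753420 15867 49721 31024 16413 95.4 1633 651
LIM04 11770633 13801 38579 23198 12968 93.7 1149 1264
LIM05 11668108 11596 36346 22687 11637 94.4 1513 509
LIM06 11645235 16568 44888 27925 12860 90.9 3295 808
LIM07 11287139 6218 15075 9088 3439 83.1 1947 601
LIM08 11734961 18876 55713 35061 17430 94.2 2306 916
LIM09 11563319 13215 33473 21119 9012 90.0 2897 445
LIM13 8718858 27165 28651 18020 3671 75.7 6707 253
LIM14 11665886 12410 34686 22388 9932 93.2 1796 570
LIM15 11516569 15344 40398 25775 10135 88.9 3931 557
LIM16 11766765 12041 35918 22612 11854 96.0 890 562
LIM17 9511239 21194 28415 17675 3677 75.1 6863 200
LIM18 11755926 8686 24893 15029 8585 94.9 902 377
LIM19 11517295 15901 40528 25083 11315 89.8 3573 557
LIM20 11330071 12058 19755 12190 4423 84.1 2753 389
LIM21 11110581 14100 30031 19059 6466 85.0 4147 359
LIM22 11534319 23041 77560 45999 24815 91.3 5907 839
"
  read.table(text = txt, header = TRUE)
}

# published pyrosequencing panel: ref/alt read counts of the six tested SNPs
table3_counts <- function() {
  data.frame(
    snp = c("rs382378456", "rs208775256", "rs41255587", "rs209641420",
            "rs110694123", "rs109919583"),
    ref_count = c(407, 26, 146, 303, 48, 47),
    alt_count = c(336, 12, 208, 221, 73, 121)
  )
}

# expand class counts into a long pairs table as produced by pair_genotypes()
pairs_from_counts <- function(BH, Bh, Hh, hH, individual = "X") {
  data.frame(chrom = "chr1",
             pos = seq_len(BH + Bh + Hh + hH),
             individual = individual,
             class = rep(c("BH", "Bh", "Hh", "hH"), times = c(BH, Bh, Hh, hH)))
}

# Monte-Carlo permutation oracle for the two-sided Spearman p-value
mc_spearman_p <- function(x, y, n_draws = 10000) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  hits <- 0L
  for (i in seq_len(n_draws)) {
    if (abs(cor(rx, sample(ry))) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_draws
}

# Build a miRNA perfectly complementary to `target_seq` in the register
# whose seed complement starts at `seed_start` (so the seed spans the SNP
# when seed_start <= snp_pos <= seed_start + 6).
mirna_for_register <- function(target_seq, seed_start, len = 22) {
  j <- seed_start + 8 - seq_len(len)          # target pos paired by miRNA p
  stopifnot(all(j >= 1), all(j <= nchar(target_seq)))
  bases <- substring(target_seq, j, j)
  paste(chartr("ACGT", "TGCA", bases), collapse = "")
}

# A SNP flank pair plus a panel of n_ref miRNAs binding only the reference
# allele and n_alt binding only the alternate allele, all with seed sites
# spanning the SNP.
mirna_diff_panel <- function(n_ref = 9, n_alt = 5, seed = 101) {
  set.seed(seed)
  ref_seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
  snp_pos <- 300
  ref_base <- substr(ref_seq, snp_pos, snp_pos)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  alt_seq <- ref_seq
  substr(alt_seq, snp_pos, snp_pos) <- alt_base
  combos <- expand.grid(offset = 0:6, len = c(20, 22))
  mk <- function(target, k) {
    mirna_for_register(target, snp_pos - combos$offset[k], combos$len[k])
  }
  mirnas <- c(
    stats::setNames(vapply(seq_len(n_ref), function(k) mk(ref_seq, k), ""),
                    sprintf("mir-ref-%02d", seq_len(n_ref))),
    stats::setNames(vapply(seq_len(n_alt), function(k) mk(alt_seq, k), ""),
                    sprintf("mir-alt-%02d", seq_len(n_alt)))
  )
  list(flanks = list(ref_sequence = ref_seq, alt_sequence = alt_seq,
                     snp_offset = snp_pos),
       mirnas = mirnas,
       ref_ids = sprintf("mir-ref-%02d", seq_len(n_ref)),
       alt_ids = sprintf("mir-alt-%02d", seq_len(n_alt)))
}

# One planted-cis-effect recovery replicate: returns TRUE when the planted
# regulatory SNP is significant for its transcript under the |rho| > 0.6 &
# Bonferroni-q < 0.05 filter. The planted variant is intermediate-frequency
# (the published worked example has genotype groups 8/7/4): a rare variant
# carried by one or two animals caps the attainable rank correlation below
# the 0.6 filter and is not recoverable by design.
cis_recovery_replicate <- function(seed, effect_size = 2) {
  cfg <- sim_config(n_individuals = 19, n_snps = 40, ld_block_size = 5,
                    alt_allele_freq_range = c(0.35, 0.65),
                    n_transcripts = 30, p_cis = 0.2,
                    cis_effect_size = effect_size,
                    p_imprinting = 0, p_editing = 0, p_genotype_error = 0,
                    n_utr_loci = 0, seed = seed)
  co <- generate_cohort(cfg)
  active <- which(co$cis_truth$cis_active)
  active <- active[vapply(active, function(t) {
    length(unique(co$dna_genotypes[co$cis_truth$cis_snp[t], ])) > 1
  }, TRUE)]
  if (length(active) == 0) return(NA)  # no recoverable signal planted
  t1 <- active[1]
  snp <- co$cis_truth$cis_snp[t1]
  snp_chrom <- stats::setNames(co$sites$chrom, rownames(co$dna_genotypes))
  partners <- ld_partners(snp, co$dna_genotypes, snp_chrom, r2_min = 0.75)
  expr <- median_of_ratios_normalize(co$expression)$normalized
  corr <- correlate_partners(partners, co$dna_genotypes, expr,
                             data.frame(snp = snp,
                                        transcript = co$cis_truth$transcript[t1]))
  any(corr$significant[corr$snp == snp])
}
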