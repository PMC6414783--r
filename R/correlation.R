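#' Median-of-ratios count normalization
#'
#' Size factor for sample j = median, over transcripts with a positive
#' geometric mean across samples, of count_ij / geomean_i (the median taken
#' in log space, as the reference implementations do); normalized counts
#' divide each column by its size factor. Factors are rescaled to have
#' geometric mean 1, which fixes the arbitrary overall scale and makes the
#' operation idempotent: renormalizing a normalized matrix returns unit
#' factors. This is the standard median-of-ratios scheme for
#' sequencing-depth correction of count matrices, implemented from its
#' definition so the stage is self-contained.
#'
#' @param raw_counts transcript x individual non-negative matrix.
#' @return list: `size_factors` (per column, geometric mean 1),
#'   `normalized` (matrix).
#' @export
median_of_ratios_normalize <- function(raw_counts) {
  raw_counts <- as.matrix(raw_counts)
  if (ncol(raw_counts) < 2) stop("need >= 2 individuals to normalize")
  log_geo <- rowMeans(log(raw_counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no transcript has positive counts in every sample; ",
         "median-of-ratios is undefined — filter samples or use a ",
         "different normalization")
  }
  log_sf <- apply(log(raw_counts[use, , drop = FALSE]) - log_geo[use], 2,
                  stats::median)
  sf <- exp(log_sf - mean(log_sf))
  list(size_factors = sf,
       normalized = sweep(raw_counts, 2, sf, "/"))
}

#' Transcripts expressed in enough individuals
#'
#' @param mat transcript x individual matrix (raw or normalized).
#' @param min_individuals minimum number of individuals with a positive
#'   value (default 3).
#' @return character vector of transcript ids (rownames).
#' @export
expressed_transcripts <- function(mat, min_individuals = 3) {
  keep <- rowSums(mat > 0) >= min_individuals
  rownames(mat)[keep]
}

#' Linkage-disequilibrium r-squared between two genotype-dosage vectors
#'
#' Squared Pearson correlation of alternate-allele dosages (0/1/2) over
#' pairwise-complete individuals: the composite (unphased) LD measure,
#' which approximates haplotype r-squared under Hardy-Weinberg
#' equilibrium. Invariant to allele relabeling (dosage -> 2 - dosage).
#'
#' @param g1,g2 numeric dosage vectors with possible NAs.
#' @return r-squared in [0,1], or NA when fewer than 2 complete pairs
#'   remain or either vector is constant (undefined, not 0).
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Intra-chromosomal LD partners of ASE SNPs
#'
#' For each ASE SNP, finds every SNP on the same chromosome whose
#' genotype-dosage r-squared with it reaches `r2_min` (inclusive; each SNP
#' is its own partner with r-squared 1). Only SNPs genotyped in every
#' individual enter downstream correlation testing.
#'
#' @param ase_snps character vector of ASE SNP ids (rownames of
#'   `genotypes`).
#' @param genotypes SNP x individual dosage matrix.
#' @param snp_chrom named chromosome vector aligned with
#'   `rownames(genotypes)` (names = SNP ids).
#' @param r2_min inclusive r-squared threshold (default 0.75).
#' @param complete_only restrict partners to SNPs with no missing genotype
#'   (default TRUE).
#' @return data.frame: ase_snp, partner, r2.
#' @export
ld_partners <- function(ase_snps, genotypes, snp_chrom, r2_min = 0.75,
                        complete_only = TRUE) {
  stopifnot(all(ase_snps %in% rownames(genotypes)))
  complete <- rowSums(is.na(genotypes)) == 0
  out <- list()
  for (s in ase_snps) {
    cands <- rownames(genotypes)[snp_chrom[rownames(genotypes)] ==
                                   snp_chrom[[s]]]
    if (complete_only) cands <- cands[complete[cands]]
    r2 <- vapply(cands, function(p) ld_r2(genotypes[s, ], genotypes[p, ]),
                 0)
    keep <- !is.na(r2) & r2 >= r2_min
    keep[cands == s] <- TRUE   # a SNP is always its own partner
    if (any(keep)) {
      out[[s]] <- data.frame(ase_snp = s, partner = cands[keep],
                             r2 = ifelse(cands[keep] == s, 1, r2[keep]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all permutations of 1..n as an (n! x n) matrix; n is capped by the exact
# Spearman path (n <= 9)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho uses average ranks for ties. The two-sided p-value is exact by full
#' permutation enumeration for n <= 9 and uses the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return list: rho, p_value, n (complete pairs). rho is NA when either
#'   vector is constant after pairing.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs for the Spearman test")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    P <- all_perms(n)
    ryp <- matrix(ry[P], nrow(P), n)
    cx <- rx - mean(rx)
    rhos <- as.vector(ryp %*% cx) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p_value = min(1, p), n = n)
}

#' Genotype-expression Spearman correlation
#'
#' @param dosage per-individual alternate-allele dosage (0/1/2).
#' @param expression_row per-individual (normalized) expression values,
#'   aligned with `dosage`.
#' @return list: rho, p_value, n.
#' @export
genotype_expression_correlation <- function(dosage, expression_row) {
  spearman_test(dosage, expression_row)
}

#' Per-transcript Bonferroni correction and significance filter
#'
#' For each transcript, m = number of SNPs tested against it; the adjusted
#' value is q = min(1, m * p). Note "q-value" here is this Bonferroni
#' adjustment, not a false-discovery-rate q-value. A pair is significant
#' iff |rho| > `rho_min` and q < `q_max`.
#'
#' @param results data.frame with columns transcript, rho, p_value.
#' @param rho_min absolute-rho threshold (default 0.6).
#' @param q_max adjusted-p threshold (default 0.05).
#' @return `results` plus n_tests_for_transcript, q_value, significant.
#' @export
bonferroni_per_transcript <- function(results, rho_min = 0.6, q_max = 0.05) {
  m <- table(results$transcript)
  results$n_tests_for_transcript <-
    as.integer(m[as.character(results$transcript)])
  results$q_value <- pmin(1, results$n_tests_for_transcript *
                            results$p_value)
  results$significant <- !is.na(results$rho) &
    abs(results$rho) > rho_min & results$q_value < q_max
  results
}

#' Correlate ASE-SNP LD partners with transcript expression
#'
#' Runs the full correlation stage: for each (LD partner SNP, transcript)
#' pair, Spearman correlation between genotype dosage and normalized
#' expression, then per-transcript Bonferroni and the rho/q filter.
#'
#' @param partners data.frame from [ld_partners()].
#' @param genotypes SNP x individual dosage matrix.
#' @param expression transcript x individual normalized matrix.
#' @param snp_transcripts data.frame with columns snp, transcript mapping
#'   each ASE SNP to the transcript(s) it lies in.
#' @param rho_min,q_max significance thresholds.
#' @return data.frame: snp, transcript, rho, p_value,
#'   n_tests_for_transcript, q_value, significant.
#' @export
correlate_partners <- function(partners, genotypes, expression,
                               snp_transcripts, rho_min = 0.6,
                               q_max = 0.05) {
  pairs <- merge(partners, snp_transcripts,
                 by.x = "ase_snp", by.y = "snp")
  pairs <- unique(pairs[, c("partner", "transcript")])
  pairs <- pairs[pairs$transcript %in% rownames(expression), , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(data.frame(snp = character(), transcript = character(),
                      rho = numeric(), p_value = numeric(),
                      n_tests_for_transcript = integer(),
                      q_value = numeric(), significant = logical()))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    g <- genotypes[pairs$partner[i], ]
    e <- expression[pairs$transcript[i], ]
    r <- if (length(unique(g[!is.na(g)])) < 2) {
      list(rho = NA_real_, p_value = NA_real_)
    } else spearman_test(g, e)
    data.frame(snp = pairs$partner[i], transcript = pairs$transcript[i],
               rho = r$rho, p_value = r$p_value)
  }))
  bonferroni_per_transcript(res, rho_min, q_max)
}
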