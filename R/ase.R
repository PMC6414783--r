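#' Minimum-read-depth filter for ASE candidates
#'
#' A site/individual passes when at least one allele has `min_reads` reads,
#' i.e. `max(ref_count, alt_count) >= min_reads`.
#'
#' @param ref_count,alt_count non-negative integer vectors.
#' @param min_reads threshold (default 10).
#' @return logical vector.
#' @export
depth_filter <- function(ref_count, alt_count, min_reads = 10) {
  pmax(ref_count, alt_count) >= min_reads
}

# exact two-sided binomial p by small-pmf summation: sum P(X = i) over all i
# with P(X = i) <= P(X = k) * (1 + eps); reduces to the symmetric tail sum
# when null_ratio = 0.5
binom_two_sided_p <- function(k, n, null_ratio = 0.5) {
  if (n == 0) stop("zero total depth: binomial test undefined")
  d <- stats::dbinom(k, n, null_ratio)
  rel_eps <- 1 + 1e-7
  if (null_ratio == 0.5) {
    m <- min(k, n - k)
    if (2 * m == n) return(1)
    p <- 2 * stats::pbinom(m, n, 0.5)
  } else {
    p <- sum(stats::dbinom(0:n, n, null_ratio)[
      stats::dbinom(0:n, n, null_ratio) <= d * rel_eps])
  }
  min(1, p)
}

#' Exact binomial test for allelic imbalance
#'
#' Two-sided exact binomial test of the alternate-allele count against a
#' null allelic ratio (default 0.5: equal expression of both alleles). The
#' two-sided p sums the probabilities of all outcomes no more likely than
#' the observed count. A site is flagged ASE iff p < `alpha` and it passes
#' the read-depth filter. No multiple-testing correction is applied across
#' sites by default — detection uses a plain per-site threshold; set
#' `fdr = TRUE` for an optional Benjamini-Hochberg adjustment.
#'
#' @param ref_count,alt_count integer vectors of per-allele read counts.
#' @param null_ratio expected alternate fraction under no imbalance.
#' @param alpha significance threshold (default 0.05).
#' @param min_reads depth-filter threshold (default 10).
#' @param fdr apply Benjamini-Hochberg across the supplied sites and test
#'   the adjusted p against `alpha` instead (off by default).
#' @return data.frame: ref_count, alt_count, alt_fraction, p_value, is_ase,
#'   excluded_reason (`low_depth` or NA).
#' @examples
#' binomial_ase_test(48, 73)   # alt fraction 0.6033, p < 0.05
#' @export
binomial_ase_test <- function(ref_count, alt_count, null_ratio = 0.5,
                              alpha = 0.05, min_reads = 10, fdr = FALSE) {
  n <- ref_count + alt_count
  if (any(n == 0)) stop("zero total depth: binomial test undefined")
  p <- vapply(seq_along(n), function(i) {
    binom_two_sided_p(alt_count[i], n[i], null_ratio)
  }, 0)
  p_eff <- if (fdr) stats::p.adjust(p, "BH") else p
  pass_depth <- depth_filter(ref_count, alt_count, min_reads)
  data.frame(
    ref_count = ref_count, alt_count = alt_count,
    alt_fraction = alt_count / n,
    p_value = p,
    is_ase = p_eff < alpha & pass_depth,
    excluded_reason = ifelse(pass_depth, NA_character_, "low_depth")
  )
}

regions_to_granges <- function(regions) {
  if (any(regions$start >= regions$end)) {
    stop("malformed region: start must be < end (0-based half-open)")
  }
  GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    label = if (!is.null(regions$label)) regions$label else
      paste0("region", seq_len(nrow(regions)))
  )
}

positions_to_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(start = calls$pos, end = calls$pos))
}

#' Exclude ASE calls inside copy-number-variable regions
#'
#' Allelic ratios inside CNVs reflect copy number rather than regulation,
#' so any call whose 1-based position falls in a region (BED convention:
#' 0-based half-open, i.e. pos-1 in [start, end)) is unflagged with
#' `excluded_reason = "cnv_region"`.
#'
#' @param calls data.frame with chrom, pos, is_ase, excluded_reason.
#' @param regions data.frame with chrom, start, end (0-based half-open) and
#'   optional label, e.g. from [read_bed_regions()].
#' @return `calls` with exclusions applied.
#' @export
exclude_regions <- function(calls, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(calls)
  hits <- GenomicRanges::findOverlaps(positions_to_granges(calls),
                                      regions_to_granges(regions))
  idx <- unique(S4Vectors::queryHits(hits))
  calls$is_ase[idx] <- FALSE
  calls$excluded_reason[idx] <- "cnv_region"
  calls
}

#' Annotate SNPs with the region labels containing them
#'
#' Used to place ASE SNPs inside QTL intervals: each SNP receives every
#' label whose region contains it; a SNP inside several overlapping regions
#' still counts once in the "annotated" total.
#'
#' @param snps data.frame with chrom, pos.
#' @param regions data.frame with chrom, start, end (0-based half-open),
#'   label.
#' @return list: `snps` (input plus a `labels` list-column and `n_labels`),
#'   `n_annotated` (SNPs with >= 1 label), `per_label` (named counts).
#' @export
annotate_regions <- function(snps, regions) {
  labs <- vector("list", nrow(snps))
  if (!is.null(regions) && nrow(regions) > 0) {
    gr <- regions_to_granges(regions)
    hits <- GenomicRanges::findOverlaps(positions_to_granges(snps), gr)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    for (i in unique(q)) labs[[i]] <- unique(gr$label[s[q == i]])
  }
  snps$labels <- labs
  snps$n_labels <- lengths(labs)
  tab <- table(unlist(labs))
  list(snps = snps, n_annotated = sum(snps$n_labels > 0),
       per_label = stats::setNames(as.integer(tab), names(tab)))
}

#' Chromosomal distribution of ASE SNPs
#'
#' Spearman rank correlation of the per-chromosome ASE-SNP count against
#' chromosome size, gene number and expressed-gene number.
#'
#' @param ase_per_chrom named integer vector of ASE-SNP counts per
#'   chromosome.
#' @param chrom_size,n_genes,n_expressed_genes numeric vectors aligned with
#'   `ase_per_chrom`.
#' @return data.frame: covariate, rho, p_value (NA with a warning when a
#'   vector is constant).
#' @export
chromosome_distribution <- function(ase_per_chrom, chrom_size, n_genes,
                                    n_expressed_genes) {
  if (length(ase_per_chrom) < 3) stop("need >= 3 chromosomes")
  covs <- list(chrom_size = chrom_size, n_genes = n_genes,
               n_expressed_genes = n_expressed_genes)
  out <- lapply(names(covs), function(nm) {
    x <- covs[[nm]]
    if (length(unique(x)) < 2 || length(unique(ase_per_chrom)) < 2) {
      warning("constant vector for ", nm, ": correlation undefined")
      return(data.frame(covariate = nm, rho = NA_real_, p_value = NA_real_))
    }
    r <- spearman_test(ase_per_chrom, x)
    data.frame(covariate = nm, rho = r$rho, p_value = r$p_value)
  })
  do.call(rbind, out)
}
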