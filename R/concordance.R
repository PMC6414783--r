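PAIR_CLASSES <- c("BH", "Bh", "Hh", "hH")

#' Classify a DNA/RNA genotype pair
#'
#' `BH` = both homozygous, `Bh` = both heterozygous, `Hh` = homozygous in
#' DNA and heterozygous in RNA (compatible with RNA editing), `hH` =
#' heterozygous in DNA and homozygous in RNA (compatible with imprinting /
#' mono-allelic expression).
#'
#' @param dna_gt,rna_gt character vectors in `hom_ref`/`het`/`hom_alt`.
#' @return character vector of classes.
#' @export
classify_pair <- function(dna_gt, rna_gt) {
  ok <- c(GT_LEVELS)
  if (any(is.na(dna_gt)) || any(is.na(rna_gt)) ||
      !all(dna_gt %in% ok) || !all(rna_gt %in% ok)) {
    stop("missing or invalid genotype; route single-assay sites to ",
         "dna_only/rna_only before classification")
  }
  dna_het <- dna_gt == "het"
  rna_het <- rna_gt == "het"
  out <- character(length(dna_gt))
  out[!dna_het & !rna_het] <- "BH"
  out[dna_het & rna_het] <- "Bh"
  out[!dna_het & rna_het] <- "Hh"
  out[dna_het & !rna_het] <- "hH"
  out
}

#' Pair DNA and RNA genotype calls per site and individual
#'
#' Joins two long-format call tables on (chrom, pos, individual). Sites
#' called in only one assay are tallied as `dna_only`/`rna_only` and never
#' classified; pairs whose ref/alt alleles disagree between assays
#' (multi-allelic) are dropped with a message.
#'
#' @param dna_calls,rna_calls data.frames with columns chrom, pos,
#'   ref_allele, alt_allele, individual, gt (as from [genotype_calls()] or
#'   [read_genotype_vcf()]).
#' @return data.frame of pairs: chrom, pos, individual, dna_gt, rna_gt,
#'   class (one of BH/Bh/Hh/hH/dna_only/rna_only).
#' @export
pair_genotypes <- function(dna_calls, rna_calls) {
  key <- function(d) paste(d$chrom, d$pos, d$individual, sep = "\r")
  dna_calls <- dna_calls[!is.na(dna_calls$gt), ]
  rna_calls <- rna_calls[!is.na(rna_calls$gt), ]
  kd <- key(dna_calls); kr <- key(rna_calls)
  m <- merge(
    data.frame(k = kd, chrom = dna_calls$chrom, pos = dna_calls$pos,
               individual = dna_calls$individual,
               dna_gt = dna_calls$gt, dna_ref = dna_calls$ref_allele,
               dna_alt = dna_calls$alt_allele),
    data.frame(k = kr, rna_gt = rna_calls$gt,
               rna_ref = rna_calls$ref_allele,
               rna_alt = rna_calls$alt_allele),
    by = "k", all = TRUE
  )
  multi <- !is.na(m$dna_gt) & !is.na(m$rna_gt) &
    (m$dna_ref != m$rna_ref | m$dna_alt != m$rna_alt)
  if (any(multi)) {
    message("dropping ", sum(multi),
            " pair(s) with discordant alleles (multi-allelic)")
    m <- m[!multi, ]
  }
  only_rna <- is.na(m$dna_gt)
  if (any(only_rna)) {
    rr <- rna_calls[match(m$k[only_rna], kr), ]
    m$chrom[only_rna] <- rr$chrom
    m$pos[only_rna] <- rr$pos
    m$individual[only_rna] <- rr$individual
  }
  cls <- rep(NA_character_, nrow(m))
  both <- !is.na(m$dna_gt) & !is.na(m$rna_gt)
  cls[both] <- classify_pair(m$dna_gt[both], m$rna_gt[both])
  cls[is.na(m$rna_gt) & !is.na(m$dna_gt)] <- "dna_only"
  cls[only_rna] <- "rna_only"
  out <- data.frame(chrom = m$chrom, pos = m$pos, individual = m$individual,
                    dna_gt = m$dna_gt, rna_gt = m$rna_gt, class = cls)
  out[order(out$individual, out$chrom, out$pos), , drop = FALSE]
}

#' Summarize DNA/RNA concordance for one individual
#'
#' @param pairs classified pairs from [pair_genotypes()], or a data.frame
#'   with a `class` column.
#' @param individual optional individual id to subset to.
#' @return one-row data.frame: individual, dna_only, rna_only, overlap, BH,
#'   Bh, Hh, hH, concordant_rate, discordant_rate,
#'   hh_fraction_of_discordant (all rates in percent, full precision; use
#'   [round_half_up()] at the reporting boundary).
#' @export
summarize_concordance <- function(pairs, individual = NULL) {
  if (!is.null(individual)) {
    pairs <- pairs[pairs$individual == individual, , drop = FALSE]
  } else {
    individual <- if (nrow(pairs)) as.character(pairs$individual[1]) else NA
  }
  n <- function(cl) sum(pairs$class == cl)
  counts <- vapply(PAIR_CLASSES, n, 0L)
  overlap <- sum(counts)
  if (overlap == 0) {
    warning("no overlapping DNA/RNA pairs for individual ", individual,
            ": concordance rates undefined")
    rates <- c(NA_real_, NA_real_, NA_real_)
  } else {
    conc <- 100 * (counts[["BH"]] + counts[["Bh"]]) / overlap
    disc <- 100 - conc
    hh <- counts[["Hh"]] + counts[["hH"]]
    rates <- c(conc, disc,
               if (hh > 0) 100 * counts[["Hh"]] / hh else NA_real_)
  }
  data.frame(individual = individual,
             dna_only = n("dna_only"), rna_only = n("rna_only"),
             overlap = overlap,
             BH = counts[["BH"]], Bh = counts[["Bh"]],
             Hh = counts[["Hh"]], hH = counts[["hH"]],
             concordant_rate = rates[1], discordant_rate = rates[2],
             hh_fraction_of_discordant = rates[3])
}

#' Per-individual concordance table
#'
#' One [summarize_concordance()] row per individual, in the shape of the
#' classic DNA/RNA SNP-comparison table.
#'
#' @param pairs classified pairs.
#' @return data.frame, one row per individual.
#' @export
concordance_table <- function(pairs) {
  out <- do.call(rbind, lapply(sort(unique(pairs$individual)),
                               function(i) summarize_concordance(pairs, i)))
  rownames(out) <- NULL
  out
}

#' Cohort-level concordance averages
#'
#' Two distinct cohort rates are computed and both reported: the unweighted
#' mean of per-individual concordance rates, and the pooled rate from the
#' mean class counts (which weights individuals by their overlap size).
#' They generally differ and neither is "the" concordance.
#'
#' @param summaries data.frame with columns BH, Bh, Hh, hH and
#'   concordant_rate (one row per individual), as from
#'   [concordance_table()].
#' @return list: mean_counts (named), mean_concordant_rate,
#'   pooled_concordant_rate, bh_share_of_concordant,
#'   hh_fraction_of_discordant (percent).
#' @export
cohort_concordance <- function(summaries) {
  if (is.null(nrow(summaries)) || nrow(summaries) == 0) {
    stop("need at least one individual summary")
  }
  mc <- vapply(c(PAIR_CLASSES, "overlap"),
               function(cl) mean(summaries[[cl]]), 0)
  list(
    mean_counts = mc,
    mean_concordant_rate = mean(summaries$concordant_rate),
    pooled_concordant_rate =
      100 * (mc[["BH"]] + mc[["Bh"]]) / mc[["overlap"]],
    bh_share_of_concordant = 100 * mc[["BH"]] / (mc[["BH"]] + mc[["Bh"]]),
    hh_fraction_of_discordant = 100 * mc[["Hh"]] / (mc[["Hh"]] + mc[["hH"]])
  )
}

#' Heterozygous-concordant candidate sites for ASE testing
#'
#' Allelic imbalance is only interpretable where DNA and RNA agree the
#' individual is heterozygous; discordant sites (possible imprinting,
#' editing or genotyping error) are removed here.
#'
#' @param pairs classified pairs.
#' @return data.frame: chrom, pos, individual — exactly the `Bh` pairs.
#' @export
select_ase_candidates <- function(pairs) {
  out <- pairs[pairs$class == "Bh", c("chrom", "pos", "individual")]
  rownames(out) <- NULL
  out
}
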