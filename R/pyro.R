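#' Pyrosequencing ASE ratio
#'
#' ASE ratio = (allele1% / allele2%) in cDNA divided by (allele1% /
#' allele2%) in genomic DNA. A ratio of 1 means the cDNA allele balance
#' simply mirrors the genomic one (no allelic imbalance); a ratio of 1.8
#' means 1.8-fold more transcript carrying allele 1 than expected from the
#' genomic balance.
#'
#' @param gdna,cdna length-2 numeric vectors of (allele1%, allele2%) from
#'   the genomic-DNA and cDNA templates; all four values must be > 0.
#' @param favour `"allele1"` (default): report the ratio as written, > 1
#'   meaning allele 1 enriched in RNA; `"enriched"`: orient the ratio in
#'   favour of whichever allele is RNA-enriched, so it is always >= 1.
#' @return the ASE ratio.
#' @examples
#' ase_ratio(gdna = c(47, 53), cdna = c(33, 67), favour = "enriched") # 1.80
#' @export
ase_ratio <- function(gdna, cdna, favour = c("allele1", "enriched")) {
  favour <- match.arg(favour)
  stopifnot(length(gdna) == 2, length(cdna) == 2)
  if (any(c(gdna, cdna) <= 0)) {
    stop("zero allele percentage: ratio undefined ",
         "(template may be homozygous)")
  }
  r <- (cdna[1] / cdna[2]) / (gdna[1] / gdna[2])
  if (favour == "enriched" && r < 1) r <- 1 / r
  unname(r)
}

#' Replicate variation of pyrosequencing allele percentages
#'
#' @param allele1_pct numeric vector of allele-1 percentages across
#'   technical replicates of one SNP/template (>= 2 replicates).
#' @return list: `mean_abs_diff` (mean absolute pairwise difference), `sd`
#'   (sample standard deviation), `n`.
#' @export
replicate_variation <- function(allele1_pct) {
  n <- length(allele1_pct)
  if (n < 2) stop("need >= 2 replicates")
  d <- abs(outer(allele1_pct, allele1_pct, "-"))
  list(mean_abs_diff = mean(d[upper.tri(d)]),
       sd = stats::sd(allele1_pct), n = n)
}

#' Pyrosequencing validation decision for one SNP
#'
#' Heterozygosity is confirmed when the genomic-DNA allele-1 percentage
#' lies inside the het band; the SNP is validated when it is heterozygous
#' and the cDNA-vs-gDNA allele-1 shift exceeds the instrument's
#' detectability limit (replicate variation bounds shifts below ~4% as
#' indistinguishable from technical noise).
#'
#' @param gdna_allele1_pct,cdna_allele1_pct allele-1 percentages in the two
#'   templates.
#' @param detect_threshold_pct minimal detectable allele-frequency shift in
#'   percent (default 4).
#' @param gdna_het_band length-2 vector: gDNA allele-1 band consistent with
#'   heterozygosity (default 30-70).
#' @return list: `heterozygous_confirmed`, `shift_pct`, `validated`.
#' @export
validate_snp <- function(gdna_allele1_pct, cdna_allele1_pct,
                         detect_threshold_pct = 4,
                         gdna_het_band = c(30, 70)) {
  het <- gdna_allele1_pct >= gdna_het_band[1] &
    gdna_allele1_pct <= gdna_het_band[2]
  shift <- abs(cdna_allele1_pct - gdna_allele1_pct)
  list(heterozygous_confirmed = het, shift_pct = shift,
       validated = het && shift > detect_threshold_pct)
}

#' Analyse a table of pyrosequencing measurements
#'
#' Measurements carry one row per SNP, individual, template (gDNA/cDNA)
#' and replicate. Replicates are averaged per template before the ratio;
#' replicate variation is reported per template. When measurements were
#' read on the complementary strand (e.g. a C/T assay reported for a G/A
#' variant), set `complemented = TRUE` on those rows — allele percentages
#' are strand-independent, the flag only documents orientation and is
#' carried through, never silently re-complemented.
#'
#' @param measurements data.frame: snp, individual, template ("gDNA" or
#'   "cDNA"), replicate, allele1_pct, allele2_pct, optional complemented.
#' @param detect_threshold_pct,gdna_het_band passed to [validate_snp()].
#' @param favour passed to [ase_ratio()].
#' @return data.frame, one row per snp/individual: ase_ratio, gdna_pct,
#'   cdna_pct, gdna_sd, cdna_sd, heterozygous_confirmed, validated.
#' @export
pyro_analyze <- function(measurements, detect_threshold_pct = 4,
                         gdna_het_band = c(30, 70), favour = "allele1") {
  tol <- 0.5
  bad <- abs(measurements$allele1_pct + measurements$allele2_pct - 100) > tol
  if (any(bad)) {
    stop("allele percentages must sum to 100 (within ", tol,
         "%): offending row ", which(bad)[1])
  }
  keys <- unique(measurements[, c("snp", "individual")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    m <- measurements[measurements$snp == keys$snp[i] &
                        measurements$individual == keys$individual[i], ]
    g <- m[m$template == "gDNA", ]
    c_ <- m[m$template == "cDNA", ]
    if (nrow(g) == 0 || nrow(c_) == 0) {
      stop("snp ", keys$snp[i], ": need both gDNA and cDNA measurements")
    }
    g1 <- mean(g$allele1_pct); g2 <- mean(g$allele2_pct)
    c1 <- mean(c_$allele1_pct); c2 <- mean(c_$allele2_pct)
    v <- validate_snp(g1, c1, detect_threshold_pct, gdna_het_band)
    data.frame(
      snp = keys$snp[i], individual = keys$individual[i],
      ase_ratio = ase_ratio(c(g1, g2), c(c1, c2), favour),
      gdna_pct = g1, cdna_pct = c1,
      gdna_sd = if (nrow(g) > 1) stats::sd(g$allele1_pct) else NA_real_,
      cdna_sd = if (nrow(c_) > 1) stats::sd(c_$allele1_pct) else NA_real_,
      heterozygous_confirmed = v$heterozygous_confirmed,
      validated = v$validated
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
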