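#' Simulate reads covering a variant site
#'
#' Error-free fixed-length reads copied from the reference, with the site
#' base set to the reference or alternate allele. Used to demonstrate
#' reference-mapping bias and its removal by N-masking.
#'
#' @param reference contig sequence (character scalar), carrying the
#'   reference allele at `site_pos`.
#' @param site_pos 1-based variant position on the contig.
#' @param depth number of reads.
#' @param alt_fraction probability a read carries the alternate allele.
#' @param alt_allele single base.
#' @param read_length read length (nt); reads always overlap the site.
#' @param extra_mismatches number of additional non-site mismatches planted
#'   per read (0 = error-free outside the variant).
#' @param seed optional integer seed.
#' @return data.frame: `seq`, `start` (1-based on the contig), `allele`
#'   ("ref"/"alt").
#' @export
simulate_site_reads <- function(reference, site_pos, depth,
                                alt_fraction = 0.5, alt_allele,
                                read_length = 20, extra_mismatches = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reference <- normalize_dna(reference)
  contig_len <- nchar(reference)
  stopifnot(site_pos >= 1, site_pos <= contig_len)
  lo <- max(1L, site_pos - read_length + 1L)
  hi <- min(site_pos, contig_len - read_length + 1L)
  starts <- sample(lo:hi, depth, replace = TRUE)
  is_alt <- stats::runif(depth) < alt_fraction
  seqs <- substring(reference, starts, starts + read_length - 1L)
  site_off <- site_pos - starts + 1L
  ref_base <- substr(reference, site_pos, site_pos)
  substr(seqs, site_off, site_off) <- ifelse(is_alt, alt_allele, ref_base)
  if (extra_mismatches > 0) {
    for (k in seq_len(depth)) {
      free <- setdiff(seq_len(read_length), site_off[k])
      flip <- sample(free, min(extra_mismatches, length(free)))
      for (j in flip) {
        b <- substr(seqs[k], j, j)
        substr(seqs[k], j, j) <- setdiff(DNA_BASES, b)[1]
      }
    }
  }
  data.frame(seq = seqs, start = starts,
             allele = ifelse(is_alt, "alt", "ref"))
}

#' Map simulated reads against a plain or N-masked reference
#'
#' Each read is compared, ungapped, at its known position against the
#' reference — either as-is (carrying the reference allele at the site) or
#' with the site base replaced by N (masking). A read is retained iff its
#' mismatch count is within `max_mismatches`; an N position matches any
#' base. Retained reads are tallied by the allele they carry at the site.
#' With an unmasked reference and a zero-mismatch threshold, every
#' alternate-allele read is discarded — the reference-mapping bias that
#' motivates N-masking.
#'
#' @param reference contig sequence carrying the reference allele at
#'   `site_pos`.
#' @param reads data.frame with `seq` and `start` columns (as from
#'   [simulate_site_reads()]); every read must overlap the site.
#' @param site_pos 1-based variant position.
#' @param ref_allele,alt_allele single bases.
#' @param masked logical: use the N-masked reference at the site?
#' @param max_mismatches maximum mismatches for a read to be retained
#'   (default 0).
#' @return list: `ref_count`, `alt_count`, `n_discarded`, `alt_fraction`.
#' @export
simulate_read_mapping <- function(reference, reads, site_pos, ref_allele,
                                  alt_allele, masked = FALSE,
                                  max_mismatches = 0) {
  reference <- normalize_dna(reference)
  if (substr(reference, site_pos, site_pos) != ref_allele) {
    stop("reference base at site_pos is not the stated reference allele")
  }
  if (masked) substr(reference, site_pos, site_pos) <- "N"
  ends <- reads$start + nchar(reads$seq) - 1L
  if (any(reads$start > site_pos | ends < site_pos)) {
    stop("every read must overlap the variant site")
  }
  ref_count <- 0L; alt_count <- 0L; discarded <- 0L
  for (k in seq_len(nrow(reads))) {
    rseq <- strsplit(reads$seq[k], "")[[1]]
    tseq <- strsplit(substr(reference, reads$start[k], ends[k]), "")[[1]]
    mism <- sum(rseq != tseq & tseq != "N" & rseq != "N")
    if (mism > max_mismatches) {
      discarded <- discarded + 1L
      next
    }
    base <- rseq[site_pos - reads$start[k] + 1L]
    if (base == ref_allele) ref_count <- ref_count + 1L
    else if (base == alt_allele) alt_count <- alt_count + 1L
  }
  total <- ref_count + alt_count
  list(ref_count = ref_count, alt_count = alt_count,
       n_discarded = discarded,
       alt_fraction = if (total > 0) alt_count / total else NA_real_)
}

#' Plant an allele-broken miRNA target site in a 3'UTR sequence
#'
#' Inserts the full reverse complement of the miRNA into the sequence so
#' that the seed complement (miRNA positions 2-8) starts at `position`; one
#' allele then carries a SNP opposite seed position 5 chosen so it neither
#' Watson-Crick pairs nor G:U wobbles with the miRNA, destroying the seed
#' match for that allele only.
#'
#' @param utr_sequence target sequence (DNA or RNA alphabet).
#' @param mirna_sequence miRNA, 5'->3'.
#' @param position 1-based start of the seed-complement 7-mer on the target.
#' @param broken_by which allele destroys the site: `"alt"` (default) or
#'   `"ref"`.
#' @return list: `ref_seq`, `alt_seq`, `snp_offset` (1-based position of the
#'   SNP on both sequences), `ref_base`, `alt_base`, `site_start` (start of
#'   the seed complement).
#' @export
plant_seed_site <- function(utr_sequence, mirna_sequence, position,
                            broken_by = c("alt", "ref")) {
  broken_by <- match.arg(broken_by)
  utr <- normalize_dna(utr_sequence)
  mirna <- normalize_dna(mirna_sequence)
  L <- nchar(mirna)
  site_lo <- position + 8L - L      # pairs miRNA position L
  site_hi <- position + 7L          # pairs miRNA position 1
  if (site_lo < 1 || site_hi > nchar(utr)) {
    stop("position out of range: planted site [", site_lo, ",", site_hi,
         "] exceeds sequence of length ", nchar(utr))
  }
  substr(utr, site_lo, site_hi) <- revcomp(mirna)

  snp_offset <- position + 3L       # opposite miRNA seed position 5
  m5 <- substr(mirna, 5, 5)
  matched <- complement_base(m5)
  wobble <- switch(m5, G = "T", T = "G", NULL)
  broken <- setdiff(DNA_BASES, c(matched, wobble))[1]

  intact <- utr
  disrupted <- utr
  substr(disrupted, snp_offset, snp_offset) <- broken
  if (broken_by == "alt") {
    list(ref_seq = intact, alt_seq = disrupted, snp_offset = snp_offset,
         ref_base = matched, alt_base = broken, site_start = position)
  } else {
    list(ref_seq = disrupted, alt_seq = intact, snp_offset = snp_offset,
         ref_base = broken, alt_base = matched, site_start = position)
  }
}
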