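#' Extract per-allele flanking sequences around a SNP
#'
#' Builds the two versions of the sequence around a variant — one carrying
#' the reference allele, one the alternate — for regulatory-site scanning
#' (radius 100 nt for miRNA target scans, 10 nt for TFBS scans).
#'
#' @param genome a named character vector, `Biostrings::DNAStringSet`, or
#'   path to a FASTA file.
#' @param chrom contig name.
#' @param pos 1-based SNP position.
#' @param ref_allele,alt_allele single bases; `ref_allele` must match the
#'   genome base at `pos`.
#' @param radius flank radius in bp (>= 1).
#' @return list: `ref_sequence`, `alt_sequence` (length <= 2*radius + 1),
#'   `snp_offset` (1-based offset of the SNP within both), `truncated`
#'   (TRUE when the window was clipped at a contig end).
#' @export
extract_flanks <- function(genome, chrom, pos, ref_allele, alt_allele,
                           radius = 100) {
  stopifnot(radius >= 1)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome),
                              sub("\\s.*", "", names(genome)))
  }
  if (!chrom %in% names(genome)) stop("contig '", chrom, "' not in genome")
  contig <- genome[[chrom]]
  if (pos < 1 || pos > nchar(contig)) {
    stop("SNP position ", pos, " outside contig '", chrom, "' (length ",
         nchar(contig), ")")
  }
  base <- substr(contig, pos, pos)
  if (base != ref_allele) {
    stop("reference allele mismatch at ", chrom, ":", pos, ": genome has '",
         base, "', variant says '", ref_allele, "'")
  }
  lo <- max(1L, pos - radius)
  hi <- min(nchar(contig), pos + radius)
  window <- substr(contig, lo, hi)
  off <- pos - lo + 1L
  alt_window <- window
  substr(alt_window, off, off) <- alt_allele
  list(ref_sequence = window, alt_sequence = alt_window, snp_offset = off,
       truncated = (lo > pos - radius) || (hi < pos + radius))
}

# TRUE where target base t (DNA alphabet) Watson-Crick pairs miRNA base m
wc_pairs <- function(t, m) {
  !is.na(t) & t != "N" & m != "N" & t == chartr("ACGT", "TGCA", m)
}

# G:U wobble between target base and miRNA base
gu_pairs <- function(t, m) {
  !is.na(t) & ((m == "G" & t == "T") | (m == "T" & t == "G"))
}

#' Scan a target sequence for miRNA seed sites
#'
#' Seed-plus-extension scheme: a candidate site requires perfect
#' Watson-Crick complementarity of miRNA positions 2-8 (the seed) to the
#' target, in the antiparallel orientation (the target site is the reverse
#' complement of the seed). The full ungapped duplex is then scored over
#' every miRNA position: +`match_score` per Watson-Crick pair,
#' +`wobble_score` per G:U wobble, `mismatch_score` per mismatch
#' (positions running off the target end count as mismatches; N never
#' pairs). Site class is `8mer` when the target presents an A opposite
#' miRNA position 1, else `7mer-m8`; with the perfect-seed requirement the
#' weaker 7mer-A1/6mer classes cannot arise. A hit passes iff its score
#' reaches `min_score`.
#'
#' @param target target sequence (DNA or RNA alphabet; U == T).
#' @param mirna miRNA sequence 5'->3', 18-26 nt.
#' @param min_score passing-score threshold (default 60).
#' @param match_score,wobble_score,mismatch_score duplex scoring weights.
#' @return data.frame of candidate sites: `position` (1-based start of the
#'   seed complement on the target), `t1_base`, `class`, `score`,
#'   `passes_threshold`.
#' @export
mirna_scan <- function(target, mirna, min_score = 60, match_score = 5,
                       wobble_score = 1, mismatch_score = -3) {
  target <- normalize_dna(target)
  mirna <- normalize_dna(mirna)
  L <- nchar(mirna)
  if (L < 18 || L > 26) stop("miRNA must be 18-26 nt (got ", L, ")")
  if (nchar(target) < 7) stop("target shorter than the seed")
  tb <- strsplit(target, "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  seed_rc <- revcomp(substr(mirna, 2, 8))
  hits <- list()
  for (i in seq_len(nchar(target) - 6)) {
    if (substr(target, i, i + 6) != seed_rc) next
    if (grepl("N", seed_rc, fixed = TRUE)) next   # N never pairs
    # miRNA position p pairs target position i + 8 - p
    jj <- i + 8 - seq_len(L)
    t_at <- rep(NA_character_, L)
    inb <- jj >= 1 & jj <= length(tb)
    t_at[inb] <- tb[jj[inb]]
    score <- sum(ifelse(wc_pairs(t_at, mb), match_score,
                        ifelse(gu_pairs(t_at, mb), wobble_score,
                               mismatch_score)))
    t1 <- if (i + 7 <= length(tb)) tb[i + 7] else NA
    hits[[length(hits) + 1]] <- data.frame(
      position = i,
      t1_base = ifelse(is.na(t1), "", t1),
      class = if (!is.na(t1) && t1 == "A") "8mer" else "7mer-m8",
      score = score,
      passes_threshold = score >= min_score
    )
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(), t1_base = character(),
                      class = character(), score = numeric(),
                      passes_threshold = logical()))
  }
  do.call(rbind, hits)
}

#' Partition regulatory sites by the allele that retains them
#'
#' Presence is binary per flank: a regulator "binds" an allele iff it has
#' at least one passing hit anywhere on that allele's flank. Regulators are
#' partitioned into those binding only the reference allele, only the
#' alternate allele, or both.
#'
#' @param ref_hits,alt_hits named lists of hit data.frames (one element per
#'   regulator id; any data.frame with a `passes_threshold` column), from
#'   scanning the same SNP's two flanks.
#' @return list: `ref_only`, `alt_only`, `both` (sorted id vectors; always
#'   disjoint).
#' @export
differential_sites <- function(ref_hits, alt_hits) {
  binds <- function(h) !is.null(h) && nrow(h) > 0 && any(h$passes_threshold)
  ids <- union(names(ref_hits), names(alt_hits))
  r <- vapply(ids, function(id) binds(ref_hits[[id]]), TRUE)
  a <- vapply(ids, function(id) binds(alt_hits[[id]]), TRUE)
  list(ref_only = sort(ids[r & !a]),
       alt_only = sort(ids[!r & a]),
       both = sort(ids[r & a]))
}

#' Scan a miRNA panel against both alleles of a SNP
#'
#' @param flanks an [extract_flanks()] result (or any list with
#'   `ref_sequence` and `alt_sequence`).
#' @param mirnas named character vector of miRNA sequences.
#' @param ... scan parameters passed to [mirna_scan()].
#' @return [differential_sites()] partition of the panel.
#' @export
scan_mirna_panel <- function(flanks, mirnas, ...) {
  ref_hits <- lapply(mirnas, function(m) mirna_scan(flanks$ref_sequence,
                                                    m, ...))
  alt_hits <- lapply(mirnas, function(m) mirna_scan(flanks$alt_sequence,
                                                    m, ...))
  differential_sites(ref_hits, alt_hits)
}

#' Score PWM matches on both strands of a sequence
#'
#' Windows whose log-odds score reaches `score_fraction * max attainable
#' score` are reported. N positions score -Inf (an N can never support a
#' match).
#'
#' @param sequence target sequence.
#' @param pwm 4 x width numeric matrix of log-odds scores, rownames
#'   A, C, G, T.
#' @param score_fraction fraction of the maximum score required
#'   (default 0.85).
#' @return data.frame: start (1-based, on the forward strand), strand
#'   (+/-), score, score_fraction, passes_threshold.
#' @export
pwm_match <- function(sequence, pwm, score_fraction = 0.85) {
  if (nrow(pwm) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  sequence <- normalize_dna(sequence)
  W <- ncol(pwm)
  if (W > nchar(sequence)) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric(), score_fraction = numeric(),
                      passes_threshold = logical()))
  }
  max_score <- sum(apply(pwm, 2, max))
  score_windows <- function(seq_chars) {
    n <- length(seq_chars) - W + 1
    vapply(seq_len(n), function(i) {
      win <- seq_chars[i:(i + W - 1)]
      if (any(win == "N")) return(-Inf)
      sum(pwm[cbind(match(win, DNA_BASES), seq_len(W))])
    }, 0)
  }
  fwd <- score_windows(strsplit(sequence, "")[[1]])
  rev_scores <- score_windows(strsplit(revcomp(sequence), "")[[1]])
  n <- length(fwd)
  out <- data.frame(
    start = c(seq_len(n), nchar(sequence) - W + 2 - seq_len(n)),
    strand = rep(c("+", "-"), each = n),
    score = c(fwd, rev_scores)
  )
  out$score_fraction <- out$score / max_score
  out$passes_threshold <- out$score >= score_fraction * max_score
  out[out$passes_threshold, , drop = FALSE]
}

#' Differential TFBS matches between the two alleles of a SNP
#'
#' @param flanks an [extract_flanks()] result (radius 10 is the usual TFBS
#'   scan window).
#' @param pwms named list of 4 x width PWMs.
#' @param score_fraction threshold passed to [pwm_match()].
#' @return list: `ref_only`, `alt_only`, `both` motif ids.
#' @export
scan_pwm_panel <- function(flanks, pwms, score_fraction = 0.85) {
  hit_list <- function(seq) {
    lapply(pwms, function(p) {
      m <- pwm_match(seq, p, score_fraction)
      data.frame(passes_threshold = m$passes_threshold)
    })
  }
  differential_sites(hit_list(flanks$ref_sequence),
                     hit_list(flanks$alt_sequence))
}
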