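#' Write a genotype matrix as a VCF file
#'
#' Minimal VCF 4.2 with a GT FORMAT field, 1-based positions; dosage 0/1/2
#' maps to 0/0, 0/1, 1/1 and NA to ./..
#'
#' @param sites data.frame with chrom, pos, ref, alt (rows aligned with
#'   `dosage`).
#' @param dosage site x individual matrix of alternate-allele dosages.
#' @param path output path.
#' @param source_tag free-text `##source=` tag (e.g. the assay name).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(sites, dosage, path, source_tag = "asecow") {
  gt_str <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], nrow(dosage))
  gt_str[is.na(gt_str)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_tag),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosage)), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read diploid genotypes from a VCF file
#'
#' Bi-allelic SNPs only; multi-allelic records are dropped with a message.
#'
#' @param path VCF path (plain text or gzipped).
#' @param assay label attached to the long-format calls ("DNA"/"RNA").
#' @return list: `sites` (chrom, pos, ref, alt), `dosage` (site x
#'   individual matrix, NA = missing), `calls` (long data.frame compatible
#'   with [pair_genotypes()]).
#' @export
read_genotype_vcf <- function(path, assay = "DNA") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (any(!keep)) {
    message("dropping ", sum(!keep), " multi-allelic/indel record(s)")
  }
  gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  to_dosage <- function(g) {
    g <- gsub("\\|", "/", g)
    unname(c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)[g])
  }
  dosage <- matrix(to_dosage(gt), nrow(gt), ncol(gt),
                   dimnames = list(paste0(fix$CHROM, ":", fix$POS),
                                   colnames(gt)))
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT)
  calls <- data.frame(
    chrom = rep(sites$chrom, ncol(dosage)),
    pos = rep(sites$pos, ncol(dosage)),
    ref_allele = rep(sites$ref, ncol(dosage)),
    alt_allele = rep(sites$alt, ncol(dosage)),
    individual = rep(colnames(dosage), each = nrow(dosage)),
    gt = dosage_to_gt(as.vector(dosage)),
    assay = assay
  )
  list(sites = sites, dosage = dosage, calls = calls)
}

#' Read genomic regions from a BED file
#'
#' @param path BED path (0-based half-open intervals).
#' @return data.frame: chrom, start (0-based), end, label.
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(gr$name)) as.character(gr$name) else
    paste0("region", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             label = lab)
}

#' Write genomic regions to a BED file
#'
#' @param regions data.frame: chrom, start (0-based), end, optional label.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_regions <- function(regions, path) {
  gr <- regions_to_granges(regions)
  names(gr) <- gr$label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read/write a transcript count matrix as TSV
#'
#' @param mat transcript x individual matrix.
#' @param path file path.
#' @return the matrix (read) or `path` invisibly (write).
#' @export
write_counts_tsv <- function(mat, path) {
  utils::write.table(data.frame(transcript = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Read/write per-site per-individual allele counts as TSV
#'
#' Columns: chrom, pos, individual, ref_count, alt_count.
#'
#' @param counts data.frame of allele counts.
#' @param path file path.
#' @return the data.frame (read) or `path` invisibly (write).
#' @export
write_allele_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_allele_counts_tsv
#' @export
read_allele_counts_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Read/write named sequences as FASTA
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path file path.
#' @return named character vector (read) or `path` invisibly (write).
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), sub("\\s.*", "", names(s)))
}
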