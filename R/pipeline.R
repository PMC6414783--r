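#' Configuration for the end-to-end ASE pipeline
#'
#' Bundles all stage parameters with either a synthetic-cohort simulation
#' config or paths to real input files. Every threshold applied by a stage
#' lives here so a run is auditable.
#'
#' @param sim a [sim_config()]; used to generate the cohort unless file
#'   `inputs` are supplied.
#' @param inputs optional named list of file paths: `dna_vcf`, `rna_vcf`,
#'   `allele_counts_tsv`, `expression_tsv`, and optionally `cnv_bed`,
#'   `qtl_bed`.
#' @param out_dir output directory (created if absent).
#' @param alpha per-site binomial significance threshold (default 0.05).
#' @param min_reads depth-filter threshold (default 10).
#' @param r2_min LD partner threshold (default 0.75, inclusive).
#' @param rho_min,q_max correlation significance filter (defaults 0.6,
#'   0.05).
#' @param min_expressed_individuals expressed-transcript filter
#'   (default 3).
#' @param mirna_radius,tfbs_radius flank radii in bp (defaults 100, 10).
#' @param min_score miRNA duplex score threshold (default 60).
#' @param pwm_fraction PWM max-score fraction threshold (default 0.85).
#' @param detect_threshold_pct pyro detectability limit in percent
#'   (default 4).
#' @param seed pipeline seed; overrides `sim$seed` when given.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            out_dir = tempfile("asecow_run_"),
                            alpha = 0.05, min_reads = 10, r2_min = 0.75,
                            rho_min = 0.6, q_max = 0.05,
                            min_expressed_individuals = 3,
                            mirna_radius = 100, tfbs_radius = 10,
                            min_score = 60, pwm_fraction = 0.85,
                            detect_threshold_pct = 4, seed = NULL) {
  if (!is.null(inputs)) {
    needed <- c("dna_vcf", "rna_vcf", "allele_counts_tsv", "expression_tsv")
    missing_paths <- setdiff(needed, names(inputs))
    if (length(missing_paths)) {
      stop("inputs must name: ", paste(missing_paths, collapse = ", "))
    }
    absent <- !vapply(unlist(inputs), file.exists, TRUE)
    if (any(absent)) {
      stop("input file not found: ", unlist(inputs)[absent][1])
    }
  }
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(sim = sim, inputs = inputs, out_dir = out_dir,
              alpha = alpha, min_reads = min_reads, r2_min = r2_min,
              rho_min = rho_min, q_max = q_max,
              min_expressed_individuals = min_expressed_individuals,
              mirna_radius = mirna_radius, tfbs_radius = tfbs_radius,
              min_score = min_score, pwm_fraction = pwm_fraction,
              detect_threshold_pct = detect_threshold_pct)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys map to [pipeline_config()] arguments; an optional `sim`
#' block maps to [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- if (is.null(y$sim)) list() else y$sim
  if (!is.null(sim_args$chrom_lengths)) {
    sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
  }
  if (!is.null(sim_args$alt_allele_freq_range)) {
    sim_args$alt_allele_freq_range <- unlist(sim_args$alt_allele_freq_range)
  }
  sim <- do.call(sim_config, sim_args)
  y$sim <- NULL
  if (!is.null(y$chrom_lengths)) {
    stop("chrom_lengths belongs in the sim block")
  }
  do.call(pipeline_config, c(list(sim = sim), y))
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

#' Run the full ASE pipeline
#'
#' Stage order: cohort acquisition (simulation or file input), DNA/RNA
#' genotype concordance, heterozygous-concordant candidate selection,
#' depth-filtered exact binomial ASE detection with CNV exclusion and QTL
#' annotation, median-of-ratios normalization and LD-aware
#' genotype-expression correlation, and allele-specific miRNA site
#' differencing on the cohort's planted 3'UTR loci (simulated cohorts
#' only). All stage outputs are written under `config$out_dir` as
#' VCF/TSV/JSON; the returned report records every record count and
#' threshold, so reruns with the same config are reproducible.
#'
#' @param config a [pipeline_config()].
#' @param cnv_regions,qtl_regions optional region data.frames (chrom,
#'   start, end, label; 0-based half-open) overriding any BED paths in
#'   `config$inputs`.
#' @return a `run_report` list; see Details in the package vignette.
#' @export
run_pipeline <- function(config, cnv_regions = NULL, qtl_regions = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("asecow")),
                 config_hash = config_hash(config[setdiff(names(config),
                                                          "out_dir")]),
                 stages = list())
  tally <- function(stage, n_in, n_out, note = "") {
    report$stages[[stage]] <<- list(n_in = n_in, n_out = n_out, note = note)
  }

  ## --- stage 0: cohort ----------------------------------------------------
  if (is.null(config$inputs)) {
    cohort <- generate_cohort(config$sim)
    write_genotype_vcf(cohort$sites, cohort$dna_genotypes,
                       file.path(config$out_dir, "dna.vcf"), "asecow-DNA")
    write_genotype_vcf(cohort$sites, cohort$rna_genotypes,
                       file.path(config$out_dir, "rna.vcf"), "asecow-RNA")
    write_allele_counts_tsv(cohort$allele_counts,
                            file.path(config$out_dir, "allele_counts.tsv"))
    write_counts_tsv(cohort$expression,
                     file.path(config$out_dir, "expression.tsv"))
    jsonlite::write_json(cohort$sites,
                         file.path(config$out_dir, "truth.json"))
    dna_calls <- genotype_calls(cohort, "DNA")
    rna_calls <- genotype_calls(cohort, "RNA")
    dna_dosage <- cohort$dna_genotypes
    snp_chrom <- stats::setNames(cohort$sites$chrom,
                                 rownames(cohort$dna_genotypes))
    allele_counts <- cohort$allele_counts
    expression <- cohort$expression
    snp_transcripts <- data.frame(snp = cohort$cis_truth$cis_snp,
                                  transcript = cohort$cis_truth$transcript)
    sequences <- cohort$sequences
  } else {
    dna <- read_genotype_vcf(config$inputs$dna_vcf, "DNA")
    rna <- read_genotype_vcf(config$inputs$rna_vcf, "RNA")
    dna_calls <- dna$calls; rna_calls <- rna$calls
    dna_dosage <- dna$dosage
    snp_chrom <- stats::setNames(dna$sites$chrom, rownames(dna$dosage))
    allele_counts <- read_allele_counts_tsv(config$inputs$allele_counts_tsv)
    expression <- read_counts_tsv(config$inputs$expression_tsv)
    snp_transcripts <- NULL
    sequences <- list()
    if (is.null(cnv_regions) && !is.null(config$inputs$cnv_bed)) {
      cnv_regions <- read_bed_regions(config$inputs$cnv_bed)
    }
    if (is.null(qtl_regions) && !is.null(config$inputs$qtl_bed)) {
      qtl_regions <- read_bed_regions(config$inputs$qtl_bed)
    }
  }

  ## --- stage 1: concordance ----------------------------------------------
  pairs <- pair_genotypes(dna_calls, rna_calls)
  conc_tab <- concordance_table(pairs)
  utils::write.table(conc_tab, file.path(config$out_dir, "concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cohort_conc <- cohort_concordance(conc_tab)
  candidates <- select_ase_candidates(pairs)
  tally("concordance", nrow(pairs), nrow(candidates),
        "heterozygous-concordant (Bh) pairs retained")

  ## --- stage 2: ASE detection ---------------------------------------------
  counts <- merge(allele_counts, candidates,
                  by = c("chrom", "pos", "individual"))
  counts <- counts[counts$ref_count + counts$alt_count > 0, ]
  calls <- cbind(counts[, c("chrom", "pos", "individual")],
                 binomial_ase_test(counts$ref_count, counts$alt_count,
                                   alpha = config$alpha,
                                   min_reads = config$min_reads))
  calls <- exclude_regions(calls, cnv_regions)
  utils::write.table(calls, file.path(config$out_dir, "ase_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ase_calls <- calls[calls$is_ase, ]
  ase_sites <- unique(ase_calls[, c("chrom", "pos")])
  per_ind <- table(factor(ase_calls$individual,
                          levels = sort(unique(calls$individual))))
  qtl_ann <- annotate_regions(ase_sites, qtl_regions)
  tally("ase", nrow(calls), nrow(ase_calls),
        paste0("flagged in >=1 individual at ", nrow(ase_sites),
               " distinct sites; excluded low_depth=",
               sum(calls$excluded_reason == "low_depth", na.rm = TRUE),
               " cnv_region=",
               sum(calls$excluded_reason == "cnv_region", na.rm = TRUE)))

  ## --- stage 3: correlation -----------------------------------------------
  norm <- median_of_ratios_normalize(expression)
  expressed <- expressed_transcripts(expression,
                                     config$min_expressed_individuals)
  expr_norm <- norm$normalized[expressed, , drop = FALSE]
  corr <- NULL
  if (!is.null(snp_transcripts) && nrow(ase_sites) > 0) {
    ase_keys <- intersect(site_key(ase_sites$chrom, ase_sites$pos),
                          rownames(dna_dosage))
    partners <- ld_partners(ase_keys, dna_dosage, snp_chrom,
                            r2_min = config$r2_min)
    corr <- correlate_partners(partners, dna_dosage, expr_norm,
                               snp_transcripts, config$rho_min,
                               config$q_max)
    utils::write.table(corr, file.path(config$out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tally("correlation",
        if (is.null(corr)) 0L else nrow(corr),
        if (is.null(corr)) 0L else sum(corr$significant),
        "significant under the |rho|/q filter")

  ## --- stage 4: binding ---------------------------------------------------
  binding <- lapply(sequences, function(locus) {
    panel <- stats::setNames(locus$mirna_seq, locus$mirna_id)
    diff <- scan_mirna_panel(
      list(ref_sequence = locus$ref_seq, alt_sequence = locus$alt_seq),
      panel, min_score = config$min_score)
    list(mirnas_ref_only = diff$ref_only, mirnas_alt_only = diff$alt_only,
         mirnas_both = diff$both)
  })
  tally("binding", length(sequences),
        sum(vapply(binding, function(b) {
          length(b$mirnas_ref_only) + length(b$mirnas_alt_only)
        }, 0L)), "allele-differential miRNA bindings across planted loci")

  report$concordance <- cohort_conc
  report$concordance_table <- conc_tab
  report$ase_summary <- list(
    n_tested = nrow(calls), n_calls = nrow(ase_calls),
    n_sites = nrow(ase_sites),
    per_individual = stats::setNames(as.integer(per_ind), names(per_ind)),
    n_in_qtl = qtl_ann$n_annotated)
  report$correlation_summary <- if (is.null(corr)) NULL else list(
    n_tested = nrow(corr), n_significant = sum(corr$significant),
    n_negative_rho = sum(corr$significant & corr$rho < 0))
  report$binding <- binding
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(config$out_dir, "report.txt"))
  report
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat("asecow run report (package", x$package_version, ", config",
      substr(x$config_hash, 1, 8), ")\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-12s in %6d  out %6d  %s\n", s, st$n_in, st$n_out,
                st$note))
  }
  cat(sprintf("  concordance: mean rate %.1f%% (pooled %.1f%%), Hh share of discordant %.1f%%\n",
              x$concordance$mean_concordant_rate,
              x$concordance$pooled_concordant_rate,
              x$concordance$hh_fraction_of_discordant))
  cat(sprintf("  ASE: %d calls at %d distinct sites (%d in QTL regions)\n",
              x$ase_summary$n_calls, x$ase_summary$n_sites,
              x$ase_summary$n_in_qtl))
  if (!is.null(x$correlation_summary)) {
    cat(sprintf("  correlation: %d pairs tested, %d significant (%d negative rho)\n",
                x$correlation_summary$n_tested,
                x$correlation_summary$n_significant,
                x$correlation_summary$n_negative_rho))
  }
  invisible(x)
}
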