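toy_genome <- function(seed = 55, len = 500) {
  set.seed(seed)
  c(chrA = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""))
}

test_that("flank extraction substitutes alleles and handles contig edges", {
  gen <- toy_genome()
  ref <- substr(gen[["chrA"]], 250, 250)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  fl <- extract_flanks(gen, "chrA", 250, ref, alt, radius = 100)
  expect_equal(nchar(fl$ref_sequence), 201)
  expect_equal(nchar(fl$alt_sequence), 201)
  expect_equal(fl$snp_offset, 101)
  expect_false(fl$truncated)
  d <- which(strsplit(fl$ref_sequence, "")[[1]] !=
               strsplit(fl$alt_sequence, "")[[1]])
  expect_equal(d, 101)
  expect_equal(substr(fl$alt_sequence, 101, 101), alt)

  fl10 <- extract_flanks(gen, "chrA", 250, ref, alt, radius = 10)
  expect_equal(nchar(fl10$ref_sequence), 21)

  # 5 bases before the SNP exist: window clipped to length 106
  ref6 <- substr(gen[["chrA"]], 6, 6)
  fl_edge <- extract_flanks(gen, "chrA", 6, ref6,
                            setdiff(c("A", "C", "G", "T"), ref6)[1],
                            radius = 100)
  expect_equal(nchar(fl_edge$ref_sequence), 106)
  expect_true(fl_edge$truncated)
  expect_equal(fl_edge$snp_offset, 6)

  expect_error(extract_flanks(gen, "chrA", 600, "A", "C"), "outside")
  expect_error(extract_flanks(gen, "chrB", 10, "A", "C"), "not in genome")
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(extract_flanks(gen, "chrA", 250, wrong, ref), "mismatch")
})

test_that("a perfect duplex scores maximally and classes follow t1", {
  set.seed(66)
  mirna <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                 collapse = "")
  target <- paste0("GGGG", revcomp(mirna), "GGGG")
  hits <- mirna_scan(target, mirna)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 5 * 22)
  expect_true(hits$passes_threshold)
  # seed complement of positions 2-8 starts 14 nt into the site
  expect_equal(hits$position, 4 + 22 - 8 + 1)

  # force an A opposite miRNA position 1 -> 8mer; anything else -> 7mer-m8
  mir_t1 <- paste0("T", substr(mirna, 2, 22))
  t8 <- paste0("GGGG", revcomp(mir_t1), "GGGG")
  h8 <- mirna_scan(t8, mir_t1)
  expect_equal(h8$class, "8mer")
  expect_equal(h8$t1_base, "A")

  expect_error(mirna_scan(target, "ACGT"), "18-26")
  expect_error(mirna_scan("ACGTB", mirna), "non-nucleotide")
})

test_that("duplex scores follow the +5/+1/-3 arithmetic", {
  mirna <- paste(rep("A", 22), collapse = "")        # seed complement TTTTTTT
  # target: seed complement only, all other paired positions equal the
  # miRNA base itself, which can neither WC-pair nor wobble
  L <- 22
  target_v <- rep("A", 40)
  i <- 20
  target_v[i:(i + 6)] <- "T"                        # seed complement
  target <- paste(target_v, collapse = "")
  hits <- mirna_scan(target, mirna, min_score = 36)
  at_site <- hits[hits$position == i, ]
  expect_equal(nrow(at_site), 1)
  expect_equal(at_site$score, 7 * 5 + (L - 7) * -3)
  expect_false(at_site$passes_threshold)

  # one G:U wobble outside the seed changes the score by +1 - (-3) = 4
  mirna2 <- paste0(paste(rep("A", 8), collapse = ""), "G",
                   paste(rep("A", 13), collapse = ""))
  # miRNA position 9 pairs target position i - 1; give it a T for a wobble
  target_v2 <- target_v
  target_v2[i - 1] <- "T"
  h_mm <- mirna_scan(target, mirna2, min_score = 0)
  h_wb <- mirna_scan(paste(target_v2, collapse = ""), mirna2, min_score = 0)
  expect_equal(h_wb$score[h_wb$position == i] -
                 h_mm$score[h_mm$position == i], 4)
})

test_that("scanning agrees with a brute-force pairing oracle", {
  brute_scan <- function(target, mirna, match = 5, wobble = 1, mm = -3) {
    tb <- strsplit(target, "")[[1]]
    mb <- strsplit(mirna, "")[[1]]
    out <- NULL
    for (i in seq_len(nchar(target) - 6)) {
      seed_ok <- TRUE
      for (p in 2:8) {
        j <- i + 8 - p
        if (tb[j] != chartr("ACGT", "TGCA", mb[p])) seed_ok <- FALSE
      }
      if (!seed_ok) next
      sc <- 0
      for (p in seq_along(mb)) {
        j <- i + 8 - p
        b <- if (j >= 1 && j <= length(tb)) tb[j] else "X"
        if (b == chartr("ACGT", "TGCA", mb[p])) sc <- sc + match
        else if ((mb[p] == "G" && b == "T") ||
                 (mb[p] == "T" && b == "G")) sc <- sc + wobble
        else sc <- sc + mm
      }
      out <- rbind(out, data.frame(position = i, score = sc))
    }
    out
  }
  set.seed(88)
  for (rep in 1:20) {
    mirna <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                   collapse = "")
    target <- paste0(
      paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = ""),
      revcomp(substr(mirna, 2, 8)),
      paste(sample(c("A", "C", "G", "T"), 13, replace = TRUE), collapse = ""))
    got <- mirna_scan(target, mirna, min_score = -1000)
    want <- brute_scan(target, mirna)
    expect_equal(got$position, want$position)
    expect_equal(got$score, want$score)
  }
})

test_that("differential sites partition by allele and swap symmetrically", {
  hit <- function(pass) data.frame(passes_threshold = pass)
  ref_hits <- list(m1 = hit(TRUE), m2 = hit(c(FALSE, TRUE)),
                   m3 = hit(FALSE), m4 = hit(TRUE))
  alt_hits <- list(m1 = hit(FALSE), m2 = hit(TRUE), m3 = hit(FALSE),
                   m4 = hit(TRUE))
  d <- differential_sites(ref_hits, alt_hits)
  expect_equal(d$ref_only, "m1")
  expect_equal(d$alt_only, character(0))
  expect_equal(d$both, c("m2", "m4"))
  expect_length(intersect(d$ref_only, d$both), 0)
  swapped <- differential_sites(alt_hits, ref_hits)
  expect_equal(swapped$alt_only, d$ref_only)
  expect_equal(swapped$ref_only, d$alt_only)
})

test_that("a 9-vs-5 planted miRNA panel is recovered exactly", {
  panel <- mirna_diff_panel(n_ref = 9, n_alt = 5)
  diff <- scan_mirna_panel(panel$flanks, panel$mirnas)
  expect_equal(diff$ref_only, sort(panel$ref_ids))
  expect_equal(diff$alt_only, sort(panel$alt_ids))
  expect_length(diff$ref_only, 9)
  expect_length(diff$alt_only, 5)
  # swapping the alleles swaps the lists exactly
  swapped_flanks <- list(ref_sequence = panel$flanks$alt_sequence,
                         alt_sequence = panel$flanks$ref_sequence)
  swapped <- scan_mirna_panel(swapped_flanks, panel$mirnas)
  expect_equal(swapped$ref_only, diff$alt_only)
  expect_equal(swapped$alt_only, diff$ref_only)
})

test_that("sites away from the SNP appear for both alleles", {
  set.seed(99)
  utr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  mirna <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                 collapse = "")
  planted <- plant_seed_site(utr, mirna, position = 50)
  # SNP far away at position 250 leaves the planted site intact
  ref_seq <- planted$ref_seq
  alt_seq <- ref_seq
  b <- substr(alt_seq, 250, 250)
  substr(alt_seq, 250, 250) <- setdiff(c("A", "C", "G", "T"), b)[1]
  d <- scan_mirna_panel(list(ref_sequence = ref_seq, alt_sequence = alt_seq),
                        c(mir = mirna))
  expect_equal(d$both, "mir")
  expect_length(d$ref_only, 0)
})

test_that("PWM matching scores both strands and honours the threshold", {
  # toy motif: consensus ACGTCA with one highly informative position
  pwm <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("A", "C", "G", "T", "C", "A")
  for (j in 1:6) pwm[cons[j], j] <- 2
  pwm["G", 3] <- 10                                  # informative position
  seq_cons <- "TTACGTCATT"
  m <- pwm_match(seq_cons, pwm, score_fraction = 1)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 3)
  expect_equal(m$strand, "+")
  expect_equal(m$score_fraction, 1)

  # the reverse complement of the consensus matches on the minus strand
  m_rc <- pwm_match(paste0("TT", revcomp("ACGTCA"), "TT"), pwm,
                    score_fraction = 1)
  expect_equal(m_rc$strand, "-")
  expect_equal(m_rc$start, 3)

  expect_equal(nrow(pwm_match("NNNNNNNNNN", pwm)), 0)
  expect_error(pwm_match("ACGT", pwm[1:3, ]), "4 rows")

  # breaking the informative base drops below 0.85 of max (20); breaking a
  # weak base only costs 2 and still matches
  flanks <- list(ref_sequence = "TTACGTCATT", alt_sequence = "TTACTTCATT")
  d <- scan_pwm_panel(flanks, list(motif1 = pwm), score_fraction = 0.85)
  expect_equal(d$ref_only, "motif1")
  flanks2 <- list(ref_sequence = "TTACGTCATT", alt_sequence = "TTCCGTCATT")
  d2 <- scan_pwm_panel(flanks2, list(motif1 = pwm), score_fraction = 0.85)
  expect_equal(d2$both, "motif1")
})
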