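# helper: a linear gene with a chosen RBS pattern planted at a chosen
# spacing upstream of an ATG at position `start`
planted_rbs_gene <- function(pattern_rna, spacing, start = 40L,
                             n_codons = 50L, filler = "C") {
  model <- sd_model()
  pat <- chartr("U", "T", pattern_rna)
  t1 <- as.integer(regexpr(pat, model$template_dna, fixed = TRUE))
  stopifnot(t1 > 0)
  anchor_pos <- start - spacing - 2L
  pat_start <- anchor_pos - (model$anchor_index - t1)
  bases <- rep(filler, start + 3L * (n_codons + 1L))
  bases[pat_start:(pat_start + nchar(pat) - 1L)] <- strsplit(pat, "")[[1]]
  orf <- paste0("ATG", paste(rep("GCA", n_codons - 1L), collapse = ""), "TAA")
  bases[start:(start + nchar(orf) - 1L)] <- strsplit(orf, "")[[1]]
  genome(paste(bases, collapse = ""), topology = "linear")
}

test_that("the printed anti-SD tail pairs position-wise with the template", {
  model <- sd_model()
  tail_b <- strsplit(model$antisd, "")[[1]]
  tmpl_b <- strsplit(model$template_rna, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  expect_identical(unname(comp[tmpl_b]), tail_b)
  expect_true(grepl("AGGAGG", model$template_rna))
})

test_that("a planted AAGGAGGU core is found at its printed spacing", {
  g <- planted_rbs_gene("AAGGAGGU", 10L)
  hit <- scan_rbs(g, 40L, "+")
  expect_equal(hit$pattern, "AAGGAGGU")
  expect_equal(hit$spacing, 10L)
  expect_equal(hit$category, "canonical")
  expect_equal(hit$n_mismatch, 0L)
})

test_that("an internal mismatch renders lowercase in the pattern", {
  g <- planted_rbs_gene("GGAGGU", 10L)
  # corrupt the template A inside the core: GG?GGU
  hit0 <- scan_rbs(g, 40L, "+")
  off <- hit0$genome_offset + 2L     # the A of GGAGGU
  s <- g$seq
  substr(s, off, off) <- "G"
  g2 <- genome(s, topology = "linear")
  hit <- scan_rbs(g2, 40L, "+")
  expect_equal(hit$pattern, "GGgGGU")
  expect_equal(hit$n_mismatch, 1L)
  expect_equal(hit$category, "canonical")
  # rendered uppercase positions pair with the 16S tail at aligned offsets
  expect_equal(sum(grepl("[a-z]", strsplit(hit$pattern, "")[[1]])), 1L)
})

test_that("a poly-A upstream window yields no site", {
  bases <- rep("A", 200)
  orf <- paste0("ATG", paste(rep("GCA", 49), collapse = ""), "TAA")
  bases[40:(39 + nchar(orf))] <- strsplit(orf, "")[[1]]
  g <- genome(paste(bases, collapse = ""), topology = "linear")
  expect_null(scan_rbs(g, 40L, "+"))
})

test_that("scanner equals the exhaustive-offset argmax oracle on random windows", {
  set.seed(55)
  model <- sd_model()
  n_hit <- 0
  for (rep in 1:300) {
    win <- random_dna(25, prob = c(0.35, 0.15, 0.35, 0.15)) # A/G rich
    g <- genome(paste0(win, "ATG", paste(rep("GCA", 49), collapse = ""),
                       "TAA"), topology = "linear")
    got <- scan_rbs(g, 26L, "+", model)
    want <- oracle_rbs(win, model)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_hit <- n_hit + 1
      expect_false(is.null(got))
      expect_equal(got$n_paired, want$np)
      expect_equal(got$n_mismatch, want$mm)
      expect_equal(got$spacing, want$spacing)
    }
  }
  expect_gt(n_hit, 50)   # the comparison actually exercised matches
})

test_that("planted RBSs are recovered exactly across seeds and spacings", {
  for (sp in 8:14) {
    g <- planted_rbs_gene("AAGGAGGU", sp)
    hit <- scan_rbs(g, 40L, "+")
    expect_equal(hit$pattern, "AAGGAGGU")
    expect_equal(hit$spacing, sp)
  }
  set.seed(60)
  for (seed in 1:30) {
    sp <- sample(8:14, 1)
    pat <- sample(c("AAGGAGGU", "AGGAGGU", "GGAGGU", "AAAGGAG"), 1)
    sg <- synth_genome(genome_spec(length = 2500, seed = seed,
      orfs = list(list(position = 601, length_aa = 50,
                       rbs_pattern = pat, spacing = sp))))
    hit <- scan_rbs(sg$genome, 601L, "+")
    expect_equal(hit$pattern, pat)
    expect_equal(hit$spacing, sp)
    expect_equal(hit$category, "canonical")
  }
})

test_that("reported spacing stays in range and widening the range is monotone", {
  set.seed(61)
  for (rep in 1:40) {
    win <- random_dna(25, prob = c(0.3, 0.2, 0.3, 0.2))
    g <- genome(paste0(win, "ATG", paste(rep("GCA", 49), collapse = ""),
                       "TAA"), topology = "linear")
    hit <- scan_rbs(g, 26L, "+")
    if (!is.null(hit)) {
      expect_gte(hit$spacing, 8L)
      expect_lte(hit$spacing, 14L)
      wide <- scan_rbs(g, 26L, "+", sd_model(spacing_range = c(5L, 18L)))
      expect_false(is.null(wide))   # widening never removes a match
    }
  }
})

test_that("dual starts with their own RBS are reported with aa offsets", {
  model <- sd_model()
  # main gene with internal ATG at codon 10 carrying its own planted RBS
  start <- 40L
  bases <- rep("C", 220)
  orf <- c("ATG", rep("GCA", 49), "TAA")
  bases[start:(start + 152L)] <- unlist(strsplit(orf, ""))
  # main RBS
  pat <- "AAGGAGGT"
  t1 <- as.integer(regexpr(pat, model$template_dna, fixed = TRUE))
  ps <- (start - 10L - 2L) - (model$anchor_index - t1)
  bases[ps:(ps + 7L)] <- strsplit(pat, "")[[1]]
  # internal ATG at codon 10 (offset 27) with its own RBS inside the body;
  # the pattern lands across codons 5-7, which stay start/stop-free
  int_pos <- start + 27L
  bases[int_pos:(int_pos + 2L)] <- c("A", "T", "G")
  ps2 <- (int_pos - 10L - 2L) - (model$anchor_index - t1)
  bases[ps2:(ps2 + 7L)] <- strsplit(pat, "")[[1]]
  g <- genome(paste(bases, collapse = ""), topology = "linear")
  calls <- scan_orfs(g, min_aa = 45)
  main <- calls[calls$start == start, ]
  expect_equal(nrow(main), 1L)
  duals <- detect_dual_starts(main, g)
  expect_true(9L %in% duals$offset_aa)

  # two initiation codons a few codons apart sharing one RBS region, like a
  # holin gene pair: spacing 8 for the first AUG makes it 14 for an AUG two
  # codons downstream
  bases2 <- rep("C", 220)
  orf2 <- c("ATG", "GCA", "ATG", rep("GCA", 47), "TAA")
  bases2[start:(start + 152L)] <- unlist(strsplit(orf2, ""))
  pat2 <- "AAAGGAG"
  t1b <- as.integer(regexpr(pat2, model$template_dna, fixed = TRUE))
  ps3 <- (start - 8L - 2L) - (model$anchor_index - t1b)
  bases2[ps3:(ps3 + 6L)] <- strsplit(pat2, "")[[1]]
  g2 <- genome(paste(bases2, collapse = ""), topology = "linear")
  calls2 <- scan_orfs(g2, min_aa = 45)
  main2 <- calls2[calls2$start == start, ]
  duals2 <- detect_dual_starts(main2, g2)
  expect_true(2L %in% duals2$offset_aa)
  expect_equal(duals2$spacing[duals2$offset_aa == 2L], 14L)

  # no internal in-frame ATG -> empty
  g3 <- planted_rbs_gene("AAGGAGGU", 10L)
  calls3 <- scan_orfs(g3, min_aa = 45)
  expect_equal(nrow(detect_dual_starts(calls3[1, ], g3)), 0L)
})

test_that("anchor calibration recovers the model anchor on planted data", {
  sg <- synth_genome(genome_spec(length = 4000, seed = 8,
    orfs = list(list(position = 801, length_aa = 50, spacing = 9),
                list(position = 1601, length_aa = 50, spacing = 12),
                list(position = 2401, length_aa = 50, spacing = 14))))
  ref <- data.frame(start_nt = sg$orfs$start, rbs = sg$orfs$rbs_pattern,
                    spacing = sg$orfs$spacing)
  cal <- calibrate_anchor(sg$genome, ref)
  expect_equal(cal$anchor_index[1], sd_model()$anchor_index)
  expect_equal(cal$n_agree[1], 3L)
})
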