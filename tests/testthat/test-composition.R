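test_that("GC and purine content count correctly", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(purine_content("AGAG"), 100)
  set.seed(17)
  for (rep in 1:25) {
    s <- random_dna(sample(50:500, 1))
    b <- strsplit(s, "")[[1]]
    expect_equal(gc_content(s), 100 * mean(b %in% c("G", "C")))
    expect_equal(purine_content(s), 100 * mean(b %in% c("A", "G")))
  }
})

test_that("a planted poly-AT insert forms exactly one island", {
  set.seed(23)
  bg <- random_dna(2000, prob = c(0.25, 0.25, 0.25, 0.25))
  at <- paste(sample(c("A", "T"), 60, TRUE), collapse = "")
  s <- paste0(substr(bg, 1, 1000), at, substr(bg, 1001, 2000))
  g <- genome(s, topology = "linear")
  isl <- at_islands(g, window = 50, threshold = 0.9)
  expect_equal(nrow(isl), 1L)
  expect_lte(isl$start, 1001)
  expect_gte(isl$end, 1060)
})

test_that("a uniform genome at a strict threshold has (almost) no islands", {
  n_isl <- 0
  for (seed in 1:10) {
    set.seed(seed)
    g <- genome(random_dna(5000), topology = "circular")
    n_isl <- n_isl + nrow(at_islands(g, window = 50, threshold = 0.9))
  }
  expect_lte(n_isl, 1)
})

test_that("islands are invariant under rotation of a circular genome", {
  set.seed(29)
  bg <- random_dna(1500)
  at <- paste(sample(c("A", "T"), 70, TRUE), collapse = "")
  s <- paste0(substr(bg, 1, 700), at, substr(bg, 701, 1500))
  g <- genome(s, topology = "circular")
  base <- at_islands(g, window = 50, threshold = 0.85)
  L <- g$length
  for (off in c(300L, 760L)) {
    rot <- paste0(substr(s, off + 1, L), substr(s, 1, off))
    isl <- at_islands(genome(rot, topology = "circular"),
                      window = 50, threshold = 0.85)
    back <- function(p) ((p + off - 1) %% L) + 1
    expect_setequal(back(isl$start), base$start)
    expect_setequal(back(isl$end), base$end)
  }
})

test_that("codon usage counts stops in the End family and fractions sum to 1", {
  cu <- codon_usage("ATGAAATAA")
  tab <- cu$table
  expect_equal(tab$fraction[tab$codon == "AAA"], 1)
  expect_equal(tab$fraction[tab$codon == "UAA"], 1)
  expect_equal(cu$total, 3L)

  set.seed(31)
  seqs <- vapply(1:10, function(i) {
    n <- sample(20:60, 1)
    paste0("ATG", paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                       c("TAA", "TAG", "TGA")),
                               n, TRUE), collapse = ""), "TGA")
  }, character(1))
  cu2 <- codon_usage(seqs)
  # dictionary-count oracle
  all_cod <- unlist(lapply(seqs, function(s) {
    st <- seq(1, nchar(s), 3)
    substring(s, st, st + 2)
  }))
  want <- table(all_cod)
  got <- cu2$counts[chartr("U", "T", names(want))]
  expect_equal(unname(got), as.integer(want))
  # families sum to 1 wherever observed
  fam_sum <- tapply(cu2$table$fraction, cu2$table$aa, sum)
  expect_true(all(abs(fam_sum[!is.na(fam_sum)] - 1) < 1e-9))
  expect_equal(cu2$total, sum(vapply(seqs, nchar, 1L)) / 3)
})

test_that("the printed Lys counts give the printed AAA fraction", {
  t4 <- spp1_codon_table()
  lys <- t4[t4$aa == "Lys", ]
  cu <- codon_usage_from_counts(setNames(t4$spp1_count, t4$codon))
  aaa <- cu$table$fraction[cu$table$codon == "AAA"]
  expect_equal(round(aaa, 2), 0.62)
  expect_equal(lys$spp1_count[lys$codon == "AAA"], 760L)
  expect_equal(lys$spp1_count[lys$codon == "AAG"], 460L)
})

test_that("usage comparison flags divergent and rare codons as printed", {
  t4 <- spp1_codon_table()
  a <- data.frame(codon = t4$codon, fraction = t4$spp1_fraction)
  b <- data.frame(codon = t4$codon, fraction = t4$bs_fraction)
  cmp <- compare_usage(a, b)
  # His CAU: 0.53 vs 0.67 -> divergent
  expect_true(cmp$divergent[cmp$codon == "CAU"])
  # recomputed flags match the table's printed highlighting everywhere
  expect_equal(cmp$divergent,
               t4$divergent[match(cmp$codon, t4$codon)] == "yes")
  # identical tables -> no divergence
  cmp0 <- compare_usage(a, a)
  expect_false(any(cmp0$divergent))
  # rare flags: below 0.1, per the legend's definition
  expect_true(cmp$rare_a[cmp$codon == "CCC"])
  expect_false(cmp$rare_a[cmp$codon == "UCG"])  # 0.10 is not below 0.1
})

test_that("protein mass is an exact sum over the packaged residue table", {
  masses <- read.delim(system.file("extdata", "aa_masses.tsv",
                                   package = "phannot"))
  m <- setNames(masses$mass, masses$aa)
  expect_equal(protein_mass("MK"), m[["M"]] + m[["K"]] + 18.01524)
  for (n in c(1, 10, 100)) {
    g <- paste(rep("G", n), collapse = "")
    expect_equal(protein_mass(g), n * m[["G"]] + 18.01524)
  }
  expect_error(protein_mass(""), "empty")
  expect_error(protein_mass("MXK"), "unknown residue")
})

test_that("the packaged ORF table reproduces the published summaries", {
  t3 <- spp1_orf_table()
  s <- summarize_orf_table(
    data.frame(start_nt = t3$start_nt, stop_nt = t3$stop_nt,
               start_codon = t3$start_codon, stop_codon = t3$stop_codon,
               length_aa = t3$length_aa, mass_kda = t3$mass_kda,
               rbs_category = t3$rbs_category),
    L = 44016, topology = "circular")
  expect_equal(s$n, 80L)
  expect_equal(s$coverage_pct_rounded, 94)
  expect_equal(as.integer(s$start_tally["AUG"]), 72L)
  expect_equal(round(mean(t3$length_aa)), 179)
  expect_equal(round(s$mean_mass_kda, 1), 20.3)
  expect_equal(round(s$sd_length_aa), 197)
  expect_equal(round(s$sd_mass_kda, 1), 21.9)
  expect_equal(s$n_canonical_rbs, 77L)
  # stop fractions match the codon table's End family
  expect_equal(as.integer(s$stop_tally[c("UGA", "UAG", "UAA")]),
               c(31L, 9L, 40L))
  expect_equal(sum(s$stop_fractions), 1)
})

test_that("coverage equals a per-base bitmap on random (wrapping) intervals", {
  # a single full-genome ORF covers 100%
  s1 <- summarize_orf_table(
    data.frame(start_nt = 1, stop_nt = 300, start_codon = "AUG",
               stop_codon = "UAA", length_aa = 99),
    L = 300, topology = "circular")
  expect_equal(s1$coverage_pct, 100)

  set.seed(37)
  for (rep in 1:20) {
    L <- sample(200:2000, 1)
    n <- sample(1:12, 1)
    st <- sample(L, n, TRUE)
    en <- sample(L, n, TRUE)
    s <- summarize_orf_table(
      data.frame(start_nt = st, stop_nt = en,
                 start_codon = "AUG", stop_codon = "UAA",
                 length_aa = rep(10, n)),
      L = L, topology = "circular")
    expect_equal(s$coverage_pct, oracle_coverage(st, en, L))
    expect_lte(s$coverage_pct, 100)
    # idempotence: summarising the same rows again gives the same union
    s2 <- summarize_orf_table(
      data.frame(start_nt = st, stop_nt = en, start_codon = "AUG",
                 stop_codon = "UAA", length_aa = rep(10, n)),
      L = L, topology = "circular")
    expect_equal(s2$coverage_pct, s$coverage_pct)
  }
})
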