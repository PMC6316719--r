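# Genome and ORF-set composition statistics: GC and purine content, AT-rich
# islands, codon usage bias, protein mass, and ORF-table summaries.

#' GC content of a sequence or genome
#'
#' @param x A [genome] or a DNA string.
#' @return Percent G+C (0-100).
#' @export
gc_content <- function(x) {
  s <- if (inherits(x, "genome")) x$seq else toupper(x)
  b <- strsplit(s, "")[[1L]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' Purine (A+G) content of a sequence or genome strand
#'
#' The heavy strand of a phage DNA molecule is the denser one in isopycnic
#' separation, which tracks its purine excess; comparing the two strands'
#' purine content identifies it.
#'
#' @param x A [genome] (forward strand) or a DNA string.
#' @return Percent A+G (0-100).
#' @export
purine_content <- function(x) {
  s <- if (inherits(x, "genome")) x$seq else toupper(x)
  b <- strsplit(s, "")[[1L]]
  100 * sum(b %in% c("A", "G")) / length(b)
}

#' Which strand is the heavy (purine-rich) strand?
#'
#' @param g A [genome].
#' @return `"+"` if the stored strand has the higher purine content, else
#'   `"-"`.
#' @export
heavy_strand <- function(g) {
  if (purine_content(g) >= 50) "+" else "-"
}

#' Locate A+T-rich islands
#'
#' Slides a window along the genome (circular-aware), marks windows whose
#' A+T fraction reaches the threshold, and merges overlapping qualifying
#' windows into maximal islands. Such islands mark intergenic regulatory
#' regions and replication origins.
#'
#' @param g A [genome].
#' @param window Window width in nt (default 50).
#' @param threshold Minimum A+T fraction of a qualifying window (default
#'   0.75).
#' @return Data frame `start`, `end`, `wraps`, `at_fraction` (fraction over
#'   the merged island).
#' @export
at_islands <- function(g, window = 50L, threshold = 0.75) {
  stopifnot(inherits(g, "genome"))
  L <- g$length
  circular <- g$topology == "circular"
  s <- if (circular) paste0(g$seq, substr(g$seq, 1L, min(window - 1L, L)))
       else g$seq
  b <- strsplit(s, "")[[1L]]
  at <- as.integer(b %in% c("A", "T"))
  cs <- c(0L, cumsum(at))
  n_win <- length(b) - window + 1L
  if (n_win < 1L) return(data.frame(start = integer(), end = integer(),
                                    wraps = logical(), at_fraction = numeric()))
  frac <- (cs[(1:n_win) + window] - cs[1:n_win]) / window
  ok <- which(frac >= threshold)
  if (!length(ok)) return(data.frame(start = integer(), end = integer(),
                                     wraps = logical(), at_fraction = numeric()))
  covered <- logical(L)
  for (w in ok) covered[circ_pos(w:(w + window - 1L), L)] <- TRUE

  # runs of covered positions; on a circular genome merge across the origin
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  wraps <- rep(FALSE, nrow(iv))
  if (circular && nrow(iv) >= 2L && covered[1L] && covered[L]) {
    first <- 1L; last <- nrow(iv)
    iv$start[first] <- iv$start[last]
    wraps[first] <- TRUE
    iv <- iv[-last, , drop = FALSE]
    wraps <- wraps[-last]
  } else if (circular && nrow(iv) == 1L && all(covered)) {
    wraps <- FALSE
  }
  atf <- vapply(seq_len(nrow(iv)), function(i) {
    p <- iv_positions(iv$start[i], iv$end[i], L, wraps[i])
    bb <- strsplit(g$seq, "")[[1L]][p]
    sum(bb %in% c("A", "T")) / length(bb)
  }, numeric(1))
  data.frame(start = iv$start, end = iv$end, wraps = wraps,
             at_fraction = atf)
}

.CODONS <- {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# amino-acid family per codon; stops form the "End" family
.codon_family <- function() {
  fam <- Biostrings::GENETIC_CODE[.CODONS]
  fam[fam == "*"] <- "End"
  fam
}

#' Codon usage of a set of coding sequences
#'
#' Counts every codon, including each CDS's terminal stop (the stop family is
#' reported as "End"), and computes within-synonymous-family usage fractions.
#'
#' @param seqs Character vector of CDS DNA sequences, each of length
#'   divisible by 3 and ending in a stop codon.
#' @return Object of class `codon_usage`: list with `counts` (named integer,
#'   64 codons, RNA names), `table` (data frame `aa`, `codon`, `count`,
#'   `fraction`) and `total`.
#' @export
codon_usage <- function(seqs) {
  counts <- setNames(integer(length(.CODONS)), .CODONS)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n %% 3 != 0) stop("CDS length not divisible by 3")
    st <- seq.int(1L, n, by = 3L)
    cod <- substring(s, st, st + 2L)
    if (!cod[length(cod)] %in% STOP_CODONS) {
      stop("CDS does not end in a stop codon")
    }
    t <- table(cod)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  codon_usage_from_counts(counts)
}

#' Build a codon usage table from raw codon counts
#'
#' @param counts Named integer vector; names are codons in DNA or RNA
#'   alphabet (all 64 need not be present).
#' @return A `codon_usage` object (see [codon_usage]).
#' @export
codon_usage_from_counts <- function(counts) {
  nm <- chartr("U", "T", toupper(names(counts)))
  full <- setNames(integer(length(.CODONS)), .CODONS)
  full[nm] <- as.integer(counts)
  fam <- .codon_family()
  fam_tot <- tapply(full, fam, sum)
  frac <- ifelse(fam_tot[fam] > 0, full / fam_tot[fam], NA_real_)
  tab <- data.frame(aa = unname(fam),
                    codon = chartr("T", "U", .CODONS),
                    count = unname(full),
                    fraction = unname(frac),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aa, tab$codon), ]
  rownames(tab) <- NULL
  structure(list(counts = full, table = tab, total = sum(full)),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("<codon_usage> ", x$total, " codons\n", sep = "")
  print(utils::head(x$table, 12L))
  cat("...\n")
  invisible(x)
}

#' Compare codon usage between two tables
#'
#' Flags a codon "divergent" when its within-family usage fractions differ by
#' more than `diff`, and "rare" (per table) when its fraction is below
#' `rare`.
#'
#' @param a,b `codon_usage` objects, or data frames with `codon` and
#'   `fraction` columns.
#' @param diff Divergence threshold on the absolute fraction difference
#'   (default 0.1, strict inequality).
#' @param rare Rarity threshold (default 0.1, strict inequality).
#' @return Data frame `codon`, `aa`, `fraction_a`, `fraction_b`, `divergent`,
#'   `rare_a`, `rare_b`.
#' @export
compare_usage <- function(a, b, diff = 0.1, rare = 0.1) {
  fa <- .usage_fractions(a)
  fb <- .usage_fractions(b)
  key <- chartr("T", "U", toupper(fa$codon))
  fb <- fb[match(key, chartr("T", "U", toupper(fb$codon))), ]
  fam <- .codon_family()
  names(fam) <- chartr("T", "U", .CODONS)
  out <- data.frame(codon = key,
                    aa = unname(fam[key]),
                    fraction_a = fa$fraction,
                    fraction_b = fb$fraction,
                    stringsAsFactors = FALSE)
  out$divergent <- !is.na(out$fraction_a) & !is.na(out$fraction_b) &
    abs(out$fraction_a - out$fraction_b) > diff
  out$rare_a <- !is.na(out$fraction_a) & out$fraction_a < rare
  out$rare_b <- !is.na(out$fraction_b) & out$fraction_b < rare
  out
}

.usage_fractions <- function(x) {
  if (inherits(x, "codon_usage")) {
    data.frame(codon = x$table$codon, fraction = x$table$fraction,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("codon", "fraction") %in% names(x)))
    data.frame(codon = x$codon, fraction = x$fraction,
               stringsAsFactors = FALSE)
  }
}

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water, using the packaged residue
#' mass table.
#'
#' @param aa Amino-acid sequence (one-letter code).
#' @return Mass in Da.
#' @export
protein_mass <- function(aa) {
  if (!is.character(aa) || length(aa) != 1L || !nzchar(aa)) {
    stop("empty protein sequence")
  }
  tab <- .aa_masses()
  b <- strsplit(toupper(aa), "")[[1L]]
  unknown <- setdiff(b, names(tab))
  if (length(unknown)) stop("unknown residue: ", unknown[1L])
  sum(tab[b]) + 18.01524
}

.aa_mass_cache <- new.env(parent = emptyenv())
.aa_masses <- function() {
  if (is.null(.aa_mass_cache$tab)) {
    f <- system.file("extdata", "aa_masses.tsv", package = "phannot",
                     mustWork = TRUE)
    d <- utils::read.delim(f, stringsAsFactors = FALSE)
    .aa_mass_cache$tab <- setNames(d$mass, d$aa)
  }
  .aa_mass_cache$tab
}

#' Summary statistics over an ORF table
#'
#' Computes (i) the percent of the genome covered by the union of the ORF
#' intervals (circular-aware), (ii) start-codon and (iii) stop-codon tallies
#' with fractions, (iv) mean/SD product length and (v) mean/SD molecular
#' mass. SDs are sample SDs (divisor n-1).
#'
#' @param rows Data frame with columns `start_nt`, `stop_nt`, `start_codon`,
#'   `stop_codon`, `length_aa` and optionally `mass_kda` and `rbs_category`.
#' @param L Genome length.
#' @param topology Genome topology.
#' @return List with `n`, `coverage_pct`, `coverage_pct_rounded`,
#'   `start_tally`, `stop_tally`, `stop_fractions`, `mean_length_aa`,
#'   `sd_length_aa`, `mean_mass_kda`, `sd_mass_kda`, `n_canonical_rbs`.
#' @export
summarize_orf_table <- function(rows, L, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  covered <- logical(L)
  for (i in seq_len(nrow(rows))) {
    s <- rows$start_nt[i]; e <- rows$stop_nt[i]
    wraps <- s > e
    if (wraps && topology != "circular") stop("wrapping ORF on linear genome")
    covered[iv_positions(s, e, L, wraps)] <- TRUE
  }
  cov <- 100 * sum(covered) / L
  start_tally <- table(factor(chartr("T", "U", rows$start_codon),
                              levels = c("AUG", "GUG", "UUG")))
  stop_tally <- table(factor(chartr("T", "U", rows$stop_codon),
                             levels = c("UAA", "UAG", "UGA")))
  list(
    n = nrow(rows),
    coverage_pct = cov,
    coverage_pct_rounded = round(cov),
    start_tally = start_tally,
    stop_tally = stop_tally,
    stop_fractions = stop_tally / sum(stop_tally),
    mean_length_aa = mean(rows$length_aa),
    sd_length_aa = stats::sd(rows$length_aa),
    mean_mass_kda = if ("mass_kda" %in% names(rows)) mean(rows$mass_kda)
                    else NA_real_,
    sd_mass_kda = if ("mass_kda" %in% names(rows)) stats::sd(rows$mass_kda)
                  else NA_real_,
    n_canonical_rbs = if ("rbs_category" %in% names(rows))
      sum(rows$rbs_category == "canonical") else NA_integer_
  )
}
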