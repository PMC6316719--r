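# Seeded synthetic genomes with planted, ground-truthed features.
#
# The generator emulates the statistical structure of a small phage genome:
# an i.i.d. background at a target GC (default 43.7%) with a heavy-strand
# purine excess (default 58.4%), planted ORFs carrying anti-SD RBSs at
# chosen spacings in 8-14 nt, planted stem-loop + U-tract terminators, and
# planted slippery heptamers. Plants are written so that the analysis
# scanners can recover them exactly: each planted ORF gets an in-frame
# guard stop upstream and a start-codon-free leader, terminator flanks are
# chosen so the stem cannot extend, and -1 sites control their shifted
# frame out to a planted stop.

GEN_VERSION <- "phannot-synth/1"

#' Specification for a synthetic genome
#'
#' @param length Genome length in nt.
#' @param gc Target GC fraction (default 0.437, the phage/host-like value the
#'   generator emulates).
#' @param purine Target A+G fraction of the stored (heavy) strand (default
#'   0.584).
#' @param topology `"circular"` or `"linear"`.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param orfs List of ORF plants: each a list with `position` (start-codon
#'   coordinate), `length_aa`, and optional `start_codon` ("ATG"),
#'   `stop_codon` ("TAA"), `rbs_pattern` ("AAGGAGGU", uppercase RNA, a
#'   contiguous block of the mRNA-side template), `spacing` (10),
#'   `plus1_ext` (codons of +1 extension to plant after the stop, 0 = none),
#'   `minus1_at` (codon index for a planted UUUUUUC -1 site, 0 = none) with
#'   `minus1_ext` (open -1 codons, default 15).
#' @param terminators List of plants: `position` (first base of the 5' stem
#'   arm), `stem` (5' arm sequence), and optional `loop` ("GAAA"),
#'   `u_len` (7).
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(length = 20000L, gc = 0.437, purine = 0.584,
                        topology = c("circular", "linear"), seed = 1L,
                        orfs = list(), terminators = list()) {
  topology <- match.arg(topology)
  stopifnot(length >= 100L, gc > 0, gc < 1, purine > 0, purine < 1)
  spec <- structure(list(length = as.integer(length), gc = gc,
                         purine = purine, topology = topology,
                         seed = as.integer(seed), orfs = orfs,
                         terminators = terminators),
                    class = "genome_spec")
  .validate_spec(spec)
  spec
}

.orf_defaults <- function(o) {
  o$start_codon <- toupper(o$start_codon %||% "ATG")
  o$stop_codon <- toupper(o$stop_codon %||% "TAA")
  o$rbs_pattern <- toupper(o$rbs_pattern %||% "AAGGAGGU")
  o$spacing <- o$spacing %||% 10L
  o$plus1_ext <- o$plus1_ext %||% 0L
  o$minus1_at <- o$minus1_at %||% 0L
  o$minus1_ext <- o$minus1_ext %||% 15L
  o
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.term_defaults <- function(t) {
  t$loop <- toupper(t$loop %||% "GAAA")
  t$u_len <- t$u_len %||% 7L
  t
}

# occupied range of each plant (for overlap checking), in coding order
.orf_extent <- function(o, model) {
  o <- .orf_defaults(o)
  guard_lead <- o$spacing + 2L + nchar(o$rbs_pattern) + 14L # RBS + guard stop
  body <- 3L * (o$length_aa + 1L)
  tail <- if (o$plus1_ext > 0L) 3L * o$plus1_ext + 4L else 0L
  c(o$position - guard_lead, o$position + body - 1L + tail)
}

.validate_spec <- function(spec) {
  model <- sd_model()
  ranges <- list()
  for (o in spec$orfs) {
    o <- .orf_defaults(o)
    if (o$spacing < 8L || o$spacing > 14L) {
      stop("ORF plant spacing must be in 8-14")
    }
    if (!grepl(chartr("U", "T", o$rbs_pattern), model$template_dna,
               fixed = TRUE)) {
      stop("rbs_pattern must be a contiguous block of the anti-SD template")
    }
    ranges[[length(ranges) + 1L]] <- .orf_extent(o, model)
  }
  for (t in spec$terminators) {
    t <- .term_defaults(t)
    s <- nchar(t$stem)
    ranges[[length(ranges) + 1L]] <-
      c(t$position - 3L, t$position + 2L * s + nchar(t$loop) + t$u_len)
  }
  if (length(ranges) >= 2L) {
    m <- do.call(rbind, ranges)
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (any(m[-1L, 1L] <= m[-nrow(m), 2L])) {
      stop("planted features overlap")
    }
  }
  for (r in ranges) {
    if (r[1L] < 1L || r[2L] > spec$length) {
      stop("planted feature exceeds genome bounds (infeasible packing)")
    }
  }
  invisible(spec)
}

NON_STOP_CODONS <- setdiff(.CODONS, STOP_CODONS)
BODY_LEADER_CODONS <- setdiff(NON_STOP_CODONS, c("ATG", "GTG", "TTG"))

#' Generate a synthetic genome with planted features
#'
#' Deterministic for a fixed spec (including its seed). Background bases are
#' drawn i.i.d. at the target GC and purine bias; planted features are then
#' written over the background with guard context that makes them exactly
#' recoverable by the scanners.
#'
#' @param spec A [genome_spec].
#' @return List of class `synthetic_genome`: `genome`, `orfs` (truth table),
#'   `terminators`, `slippery`, `spec`, `version`.
#' @export
synth_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  L <- spec$length
  pG <- pC <- spec$gc / 2
  pA <- spec$purine - pG
  pT <- 1 - spec$gc - pA
  stopifnot(pA > 0, pT > 0)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(pA, pC, pG, pT))

  model <- sd_model()
  truth_orfs <- list()
  truth_terms <- list()
  truth_slip <- list()

  for (o in spec$orfs) {
    o <- .orf_defaults(o)
    p <- o$position
    pat_dna <- chartr("U", "T", o$rbs_pattern)
    t1 <- as.integer(regexpr(pat_dna, model$template_dna, fixed = TRUE))
    anchor_pos <- p - o$spacing - 2L
    pat_start <- anchor_pos - (model$anchor_index - t1)
    pat_end <- pat_start + nchar(pat_dna) - 1L
    # guard stop: an in-frame codon wholly 5' of the RBS pattern, leaving
    # room for the mismatching flank bases just before the pattern
    depth <- 4L  # max_mismatch + 1 flank positions, plus one spare
    q <- p - 3L * as.integer(ceiling((p - pat_start + depth + 3L) / 3))
    bases[q:(q + 2L)] <- c("T", "A", "A")
    bases[pat_start:pat_end] <- strsplit(pat_dna, "")[[1L]]
    # force mismatches at the max_mismatch+1 template positions flanking the
    # pattern on each side: no stretch can bridge past them, so the
    # scanner's best stretch is exactly the planted one
    tmpl <- strsplit(model$template_dna, "")[[1L]]
    t2 <- t1 + nchar(pat_dna) - 1L
    for (d in seq_len(model$max_mismatch + 1L)) {
      if (t1 - d >= 1L) {
        bases[pat_start - d] <- if (tmpl[t1 - d] == "C") "A" else "C"
      }
      if (t2 + d <= length(tmpl)) {
        bases[pat_end + d] <- if (tmpl[t2 + d] == "C") "A" else "C"
      }
    }
    # scrub start codons from in-frame leader codons between guard and start
    cod_starts <- seq.int(q + 3L, p - 3L, by = 3L)
    for (cs in cod_starts) {
      idx <- cs:(cs + 2L)
      cod <- paste(bases[idx], collapse = "")
      if (cod %in% c("ATG", "GTG", "TTG", STOP_CODONS)) {
        free <- idx[idx < pat_start | idx > pat_end]
        if (!length(free)) stop("infeasible plant: start codon inside RBS")
        # rewriting the middle base breaks start and stop alike; fall back to
        # whichever codon position is outside the pattern
        tgt <- if ((cs + 1L) %in% free) cs + 1L else free[1L]
        bases[tgt] <- "C"
      }
    }
    # re-check pattern intact
    stopifnot(identical(paste(bases[pat_start:pat_end], collapse = ""), pat_dna))

    body <- c(strsplit(o$start_codon, "")[[1L]])
    n_lead <- min(15L, o$length_aa - 1L)
    lead <- sample(BODY_LEADER_CODONS, n_lead, replace = TRUE)
    rest <- sample(NON_STOP_CODONS, o$length_aa - 1L - n_lead, replace = TRUE)
    codons <- c(lead, rest)

    if (o$minus1_at > 0L) {
      # heptamer TTTTTTC with first base on the third position of ORF codon
      # n; `codons` holds ORF codons 2..length_aa, hence the n-1 indexing
      n <- o$minus1_at
      ext <- o$minus1_ext
      stopifnot(n >= 2L, ext >= 2L, n + ext + 2L <= o$length_aa)
      codons[n - 1L] <- "GCT"       # third base T = first X of the heptamer
      codons[n] <- "TTT"
      codons[n + 1L] <- "TTC"
      if (ext >= 3L) {
        codons[seq.int(n + 2L, n + ext - 1L)] <- "GCA" # -1 frame reads AGC
      }
      codons[n + ext] <- "GCT"      # with the next codon, -1 frame reads TAA
      codons[n + ext + 1L] <- "AAG"
      truth_slip[[length(truth_slip) + 1L]] <- data.frame(
        kind = "minus1", position = p + 3L * n - 1L,
        orf_position = p, shared_prefix_aa = n + 1L, ext_aa = ext,
        stringsAsFactors = FALSE)
    }

    body <- c(body, unlist(strsplit(codons, "")))
    if (o$plus1_ext > 0L) {
      # final sense codon becomes the rare CCC proline, stop becomes UAA
      body <- c(body[1:(3L * (o$length_aa - 1L))],
                strsplit("CCCTAA", "")[[1L]])
      stop_codon <- "TAA"
    } else {
      body <- c(body, strsplit(o$stop_codon, "")[[1L]])
      stop_codon <- o$stop_codon
    }
    bases[p:(p + length(body) - 1L)] <- body
    end <- p + length(body) - 1L

    if (o$plus1_ext > 0L) {
      # the +1 frame starts one base into the ORF's UAA, so its first codon
      # is AAx; lay the remaining ext-1 codons and the +1-frame stop on the
      # shifted grid
      E <- o$plus1_ext
      ext_codons <- sample(NON_STOP_CODONS, E - 1L, replace = TRUE)
      ext_seq <- c("A", unlist(strsplit(ext_codons, "")), c("T", "A", "A"))
      bases[(end + 1L):(end + length(ext_seq))] <- ext_seq
      truth_slip[[length(truth_slip) + 1L]] <- data.frame(
        kind = "plus1", position = end - 5L, orf_position = p,
        shared_prefix_aa = o$length_aa, ext_aa = o$plus1_ext,
        stringsAsFactors = FALSE)
    }

    truth_orfs[[length(truth_orfs) + 1L]] <- data.frame(
      start = p, end = end, length_aa = o$length_aa,
      start_codon = o$start_codon, stop_codon = stop_codon,
      rbs_pattern = o$rbs_pattern, spacing = o$spacing,
      stringsAsFactors = FALSE)
  }

  for (t in spec$terminators) {
    t <- .term_defaults(t)
    stem5 <- toupper(t$stem)
    s <- nchar(stem5)
    stem3 <- revcomp(stem5)
    # 5' wall of three C's: C pairs neither U nor itself, so the stem cannot
    # extend outward across the single allowed mismatch
    seqv <- c("C", "C", "C",
              strsplit(stem5, "")[[1L]],
              strsplit(t$loop, "")[[1L]],
              strsplit(stem3, "")[[1L]],
              rep("T", t$u_len), "G")
    p0 <- t$position - 3L
    bases[p0:(p0 + length(seqv) - 1L)] <- seqv
    truth_terms[[length(truth_terms) + 1L]] <- data.frame(
      start = t$position, end = t$position + 2L * s + nchar(t$loop) - 1L,
      stem_len = s, loop_len = nchar(t$loop), u_len = t$u_len,
      stringsAsFactors = FALSE)
  }

  g <- genome(paste(bases, collapse = ""),
              id = sprintf("synthetic seed=%d %s", spec$seed, GEN_VERSION),
              topology = spec$topology)
  structure(list(
    genome = g,
    orfs = if (length(truth_orfs)) do.call(rbind, truth_orfs) else
      data.frame(start = integer(), end = integer(), length_aa = integer(),
                 start_codon = character(), stop_codon = character(),
                 rbs_pattern = character(), spacing = integer(),
                 stringsAsFactors = FALSE),
    terminators = if (length(truth_terms)) do.call(rbind, truth_terms) else
      data.frame(start = integer(), end = integer(), stem_len = integer(),
                 loop_len = integer(), u_len = integer(),
                 stringsAsFactors = FALSE),
    slippery = if (length(truth_slip)) do.call(rbind, truth_slip) else
      data.frame(kind = character(), position = integer(),
                 orf_position = integer(), shared_prefix_aa = integer(),
                 ext_aa = integer(), stringsAsFactors = FALSE),
    spec = spec, version = GEN_VERSION
  ), class = "synthetic_genome")
}

#' Write the packaged reference tables and seeded synthetic fixtures
#'
#' Writes the phage reference tables (ORFs, terminators, codon usage) as TSV
#' plus three seeded synthetic genomes (FASTA + truth tables as GFF3/TSV)
#' into a directory. Re-running reproduces identical files.
#'
#' @param outdir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
make_fixture_suite <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (f in c("spp1_orfs.tsv", "spp1_terminators.tsv",
              "spp1_codon_usage.tsv")) {
    src <- system.file("extdata", f, package = "phannot", mustWork = TRUE)
    dst <- file.path(outdir, f)
    file.copy(src, dst, overwrite = TRUE)
    files <- c(files, dst)
  }
  for (seed in 1:3) {
    spec <- .demo_spec(seed)
    sg <- synth_genome(spec)
    fa <- file.path(outdir, sprintf("synthetic_%d.fasta", seed))
    write_genome_fasta(sg$genome, fa)
    tsv <- file.path(outdir, sprintf("synthetic_%d_truth.tsv", seed))
    utils::write.table(sg$orfs, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gff <- file.path(outdir, sprintf("synthetic_%d_truth.gff3", seed))
    feats <- data.frame(
      seqid = sg$genome$id, source = "phannot-synth", type = "CDS",
      start = sg$orfs$start, end = sg$orfs$end, score = ".", strand = "+",
      phase = "0",
      attributes = sprintf("ID=plant%02d", seq_len(nrow(sg$orfs))),
      stringsAsFactors = FALSE)
    write_gff3(feats, gff, L = sg$genome$length,
               circular = sg$genome$topology == "circular")
    files <- c(files, fa, tsv, gff)
  }
  invisible(files)
}

# a standard plant layout used by the fixture suite and tests
.demo_spec <- function(seed) {
  genome_spec(
    length = 6000L, seed = seed,
    orfs = list(
      list(position = 501L, length_aa = 60L),
      list(position = 1201L, length_aa = 80L, start_codon = "TTG",
           rbs_pattern = "AGGAGGU", spacing = 12L),
      list(position = 2001L, length_aa = 90L, minus1_at = 20L),
      list(position = 3001L, length_aa = 70L, plus1_ext = 20L)
    ),
    terminators = list(
      list(position = 4001L, stem = "CCGACG"),
      list(position = 4501L, stem = "GGCGCTC", loop = "GCAA", u_len = 6L)
    )
  )
}
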