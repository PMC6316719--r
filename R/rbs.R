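# Anti-Shine-Dalgarno matching.
#
# The 3' tail of the B. subtilis 16S rRNA is written here as printed,
# UCUUUCCUCCACUAG, read 3'->5'; its position-wise Watson-Crick partner on the
# mRNA side, read 5'->3', is AGAAAGGAGGUGAUC, which carries the AGGAGG core.
# Matches are scored by sliding this template ungapped across the window
# upstream of an initiation codon. Spacing is counted between the anchor base
# (the template position pairing the central U of the 16S tail) and the base
# preceding the initiation codon, exclusive on both sides, and must fall in
# 8-14 nt.

#' Shine-Dalgarno scanning model
#'
#' @param antisd 16S rRNA 3' tail as printed (RNA, 3'->5').
#' @param anchor_index Template position whose 16S partner is the central U of
#'   the anti-SD (defines the spacing reference). Default 8.
#' @param spacing_range Allowed spacing (nt) between anchor and the base
#'   preceding the start codon.
#' @param min_paired Minimum paired bases for a canonical match.
#' @param max_mismatch Maximum internal mismatches in a canonical match.
#' @param weak_min_paired Minimum paired bases for a weak (non-canonical,
#'   G-rich) site report.
#' @param core Template positions forming the AGGAGGUG core; any reported
#'   match must pair at least `min_core_paired` bases here.
#' @param min_core_paired See `core`.
#' @return A list of class `sd_model`.
#' @export
sd_model <- function(antisd = "UCUUUCCUCCACUAG", anchor_index = 8L,
                     spacing_range = c(8L, 14L), min_paired = 4L,
                     max_mismatch = 2L, weak_min_paired = 3L,
                     core = 5:12, min_core_paired = 3L) {
  antisd <- toupper(antisd)
  stopifnot(spacing_range[1] <= spacing_range[2],
            anchor_index >= 1L, anchor_index <= nchar(antisd))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  tail_bases <- strsplit(antisd, "")[[1L]]
  if (!all(tail_bases %in% names(comp))) stop("antisd must be RNA over ACGU")
  template_rna <- paste(comp[tail_bases], collapse = "")
  template_dna <- chartr("U", "T", template_rna)
  structure(list(
    antisd = antisd,
    template_rna = template_rna, template_dna = template_dna,
    anchor_index = as.integer(anchor_index),
    spacing_range = as.integer(spacing_range),
    min_paired = as.integer(min_paired),
    max_mismatch = as.integer(max_mismatch),
    weak_min_paired = as.integer(weak_min_paired),
    core = as.integer(core), min_core_paired = as.integer(min_core_paired)
  ), class = "sd_model")
}

#' Render an RBS alignment in the reference-table style
#'
#' The aligned stretch from the first to the last paired base is reported,
#' paired bases uppercase and mismatched positions lowercase, in the RNA
#' alphabet. The printed letters are the mRNA bases.
#'
#' @param window_seq DNA bases of the aligned window region (character
#'   scalar), same length as `matched`.
#' @param matched Logical vector marking paired positions.
#' @return Pattern string, or `NA` if nothing pairs.
#' @export
render_pattern <- function(window_seq, matched) {
  if (!any(matched)) return(NA_character_)
  b <- strsplit(chartr("T", "U", toupper(window_seq)), "")[[1L]]
  stopifnot(length(b) == length(matched))
  from <- which(matched)[1L]
  to <- max(which(matched))
  b <- b[from:to]
  m <- matched[from:to]
  b[!m] <- tolower(b[!m])
  paste(b, collapse = "")
}

#' Scan upstream of a start codon for an anti-SD complementary RBS
#'
#' Slides the mRNA-side template ungapped over the `window` nucleotides
#' preceding the start codon, scores each placement by paired-base count, and
#' returns the best placement whose anchor-derived spacing lies in the
#' model's spacing range. Ties are broken by fewer mismatches, then smaller
#' spacing.
#'
#' @param g A [genome].
#' @param start_pos Coordinate of the first base of the start codon (on the
#'   coding strand).
#' @param strand `"+"` or `"-"`.
#' @param model An [sd_model].
#' @param window Upstream window width in nt (default 25).
#' @return One-row data frame with `pattern`, `spacing`, `n_paired`,
#'   `n_mismatch`, `category` and `genome_offset` (coordinate of the first
#'   paired base on the coding strand), or `NULL` when no placement
#'   qualifies.
#' @export
scan_rbs <- function(g, start_pos, strand = "+", model = sd_model(),
                     window = 25L) {
  stopifnot(inherits(g, "genome"))
  L <- g$length
  m <- nchar(model$template_dna)

  if (g$topology == "circular") {
    win <- circ_substr(g, start_pos - window, window)
    W <- window
    win_start <- start_pos - window  # may be <= 0; circ_pos maps it
  } else {
    lo <- max(1L, start_pos - window)
    if (lo > start_pos - 1L) return(NULL)
    if (start_pos - window < 1L) {
      warning("window truncated at the 5' end of a linear genome")
    }
    win <- substr(g$seq, lo, start_pos - 1L)
    W <- nchar(win)
    win_start <- lo
  }
  if (strand == "-") {
    # coding strand runs downwards; upstream window lies at higher plus
    # coordinates and must be read as the reverse complement
    win <- if (g$topology == "circular") {
      revcomp(circ_substr(g, start_pos + 1L, window))
    } else {
      hi <- min(L, start_pos + window)
      if (start_pos + window > L)
        warning("window truncated at the 5' end of a linear genome")
      revcomp(substr(g$seq, start_pos + 1L, hi))
    }
    W <- nchar(win)
  }
  if (W < m) return(NULL)

  tmpl <- strsplit(model$template_dna, "")[[1L]]
  wchr <- strsplit(win, "")[[1L]]
  best <- NULL
  for (o in seq_len(W - m + 1L)) {
    seg <- wchr[o:(o + m - 1L)]
    matched <- seg == tmpl
    if (!any(matched)) next
    a <- o + model$anchor_index - 1L          # anchor index in window
    spacing <- W - a - 1L
    if (spacing < model$spacing_range[1] || spacing > model$spacing_range[2])
      next
    # the reported site is the best qualifying contiguous stretch of this
    # placement: maximal net pairing (paired - mismatched) among stretches
    # with at most max_mismatch internal mismatches that pair enough core
    # bases, mirroring how reference tables print RBS patterns
    stretch <- .best_stretch(matched, model)
    if (is.null(stretch)) next
    category <- if (stretch$n_paired >= model$min_paired) "canonical"
                else "weak"
    cand <- list(o = o, n_paired = stretch$n_paired,
                 n_mismatch = stretch$n_mismatch,
                 net = stretch$n_paired - stretch$n_mismatch,
                 spacing = spacing, matched = matched,
                 from = stretch$from, to = stretch$to, category = category)
    if (is.null(best) ||
        cand$net > best$net ||
        (cand$net == best$net && cand$n_mismatch < best$n_mismatch) ||
        (cand$net == best$net && cand$n_mismatch == best$n_mismatch &&
         cand$spacing < best$spacing)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  region <- paste(wchr[(best$o + best$from - 1L):(best$o + best$to - 1L)],
                  collapse = "")
  pat <- render_pattern(region, best$matched[best$from:best$to])
  first_idx <- best$o + best$from - 1L       # window index of first paired base
  offset <- if (strand == "+") {
    circ_pos(if (g$topology == "circular") win_start + first_idx - 1L
             else win_start + first_idx - 1L, L)
  } else {
    circ_pos(start_pos + (W - first_idx + 1L), L)
  }
  data.frame(pattern = pat, spacing = best$spacing,
             n_paired = best$n_paired, n_mismatch = best$n_mismatch,
             category = best$category, genome_offset = offset,
             stringsAsFactors = FALSE)
}

# best qualifying contiguous stretch of matched positions: starts and ends
# on a match, carries at most max_mismatch internal mismatches, pairs at
# least min_core_paired bases of the template core and weak_min_paired bases
# overall; maximises paired - mismatched (ties: fewer mismatches)
.best_stretch <- function(matched, model) {
  idx <- which(matched)
  if (!length(idx)) return(NULL)
  best <- NULL
  for (i in idx) {
    for (j in idx[idx >= i]) {
      mm <- sum(!matched[i:j])
      if (mm > model$max_mismatch) next
      np <- sum(matched[i:j])
      if (np < model$weak_min_paired) next
      core_hit <- sum(intersect(idx, model$core) %in% i:j)
      if (core_hit < model$min_core_paired) next
      net <- np - mm
      if (is.null(best) || net > best$net ||
          (net == best$net && mm < best$n_mismatch)) {
        best <- list(from = i, to = j, n_paired = np, n_mismatch = mm,
                     net = net)
      }
    }
  }
  best
}

#' Scan RBSs for every ORF call
#'
#' @param g A [genome].
#' @param orfs An `orf_calls` data frame.
#' @param model An [sd_model].
#' @param window Upstream window in nt.
#' @return Data frame with one row per ORF: `orf_id`, `pattern`, `spacing`,
#'   `n_paired`, `n_mismatch`, `category` (`"none"` when no site qualifies).
#' @export
scan_rbs_all <- function(g, orfs, model = sd_model(), window = 25L) {
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    hit <- scan_rbs(g, orfs$start[i], orfs$strand[i], model, window)
    if (is.null(hit)) {
      data.frame(orf_id = orfs$orf_id[i], pattern = NA_character_,
                 spacing = NA_integer_, n_paired = NA_integer_,
                 n_mismatch = NA_integer_, category = "none",
                 stringsAsFactors = FALSE)
    } else {
      cbind(data.frame(orf_id = orfs$orf_id[i], stringsAsFactors = FALSE),
            hit[, c("pattern", "spacing", "n_paired", "n_mismatch",
                    "category")])
    }
  })
  do.call(rbind, rows)
}

#' Detect dual-start motifs within an ORF
#'
#' Genes with two initiation codons for the same frame, each preceded by its
#' own canonical RBS and spaced by a few codons, produce long and short
#' protein forms (a holin/antiholin-type arrangement). This reports in-frame
#' AUG codons within the first `k` codons of an ORF that carry their own
#' qualifying RBS.
#'
#' @param orf One row of an `orf_calls` data frame.
#' @param g A [genome].
#' @param k Number of leading codons searched (default 15).
#' @param model An [sd_model].
#' @return Data frame with `offset_aa`, `position`, `pattern`, `spacing`;
#'   zero rows when there is no internal dual start.
#' @export
detect_dual_starts <- function(orf, g, k = 15L, model = sd_model()) {
  out <- list()
  n_check <- min(k, orf$length_aa)
  for (i in 2:n_check) {
    off <- 3L * (i - 1L)
    pos <- if (orf$strand == "+") circ_pos(orf$start + off, g$length)
           else circ_pos(orf$start - off, g$length)
    cod <- if (orf$strand == "+") circ_substr(g, pos, 3L)
           else revcomp(circ_substr(g, pos - 2L, 3L))
    if (cod != "ATG") next
    hit <- scan_rbs(g, pos, orf$strand, model)
    if (!is.null(hit) && hit$category == "canonical") {
      out[[length(out) + 1L]] <- data.frame(
        orf_id = orf$orf_id, offset_aa = i - 1L, position = pos,
        pattern = hit$pattern, spacing = hit$spacing,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(orf_id = character(), offset_aa = integer(),
                      position = integer(), pattern = character(),
                      spacing = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Calibrate the spacing anchor against a reference ORF table
#'
#' The position of the anchor base inside the anti-SD tail is a typographic
#' convention; this routine scans a genome with every possible anchor index
#' and counts agreement with a reference table of (pattern, spacing) pairs,
#' reporting the anchor that maximises agreement.
#'
#' @param g A [genome].
#' @param ref Data frame with columns `start_nt` (start-codon coordinate),
#'   `rbs` (pattern) and `spacing`.
#' @param model Base [sd_model]; all fields except `anchor_index` are kept.
#' @return Data frame with `anchor_index` and `n_agree`, sorted by agreement.
#' @export
calibrate_anchor <- function(g, ref, model = sd_model()) {
  m <- nchar(model$template_dna)
  res <- lapply(seq_len(m), function(a) {
    mod <- sd_model(antisd = model$antisd, anchor_index = a,
                    spacing_range = model$spacing_range,
                    min_paired = model$min_paired,
                    max_mismatch = model$max_mismatch)
    agree <- 0L
    for (i in seq_len(nrow(ref))) {
      hit <- scan_rbs(g, ref$start_nt[i], "+", mod)
      if (!is.null(hit) && !is.na(ref$spacing[i]) &&
          identical(hit$pattern, ref$rbs[i]) &&
          hit$spacing == ref$spacing[i]) {
        agree <- agree + 1L
      }
    }
    data.frame(anchor_index = a, n_agree = agree)
  })
  res <- do.call(rbind, res)
  res[order(-res$n_agree), ]
}
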