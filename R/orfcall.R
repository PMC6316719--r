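# ORF calling.
#
# An ORF runs from an accepted initiation codon (AUG/GUG/UUG by default) to
# the next in-frame stop, with no internal stop and a product of at least
# `min_aa` amino acids. For every (frame, stop codon) segment one maximal ORF
# is emitted -- the most-upstream valid start -- and the remaining in-segment
# starts are kept as internal candidates for embedded-ORF bookkeeping and
# dual-start detection. Annotation is restricted to the purine-rich heavy
# (coding) strand by default; both-strand scanning is available for general
# use.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a genome for open reading frames
#'
#' @param g A [genome].
#' @param min_aa Minimum product length in amino acids (the initiator counts;
#'   the stop codon does not). Default 45.
#' @param starts Accepted initiation codons (DNA alphabet).
#' @param strand_mode `"heavy"` scans only the forward (heavy/coding) strand;
#'   `"both"` also scans the reverse complement.
#' @return A data frame of class `orf_calls`, sorted by start coordinate, with
#'   columns `orf_id`, `strand`, `start`, `end`, `wraps`, `start_codon`,
#'   `stop_codon`, `length_aa`, and a list column `internal_starts` of
#'   genome coordinates of valid in-segment alternative starts.
#' @export
scan_orfs <- function(g, min_aa = 45L, starts = c("ATG", "GTG", "TTG"),
                      strand_mode = c("heavy", "both")) {
  stopifnot(inherits(g, "genome"))
  strand_mode <- match.arg(strand_mode)
  if (min_aa < 1L) stop("min_aa must be >= 1")
  starts <- toupper(starts)

  res <- .scan_strand(g$seq, g$length, g$topology == "circular", starts,
                      min_aa, "+")
  if (strand_mode == "both") {
    rc <- revcomp(g$seq)
    res_m <- .scan_strand(rc, g$length, g$topology == "circular", starts,
                          min_aa, "-")
    if (nrow(res_m)) {
      # map reverse-strand coordinates back onto the forward strand; start/end
      # stay in coding (5'->3') orientation
      L <- g$length
      tmp_start <- L - res_m$start + 1L
      tmp_end <- L - res_m$end + 1L
      res_m$start <- tmp_start
      res_m$end <- tmp_end
      res_m$internal_starts <- lapply(res_m$internal_starts,
                                      function(p) L - p + 1L)
      res <- rbind(res, res_m)
    }
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  if (nrow(res)) {
    res$orf_id <- sprintf("orf_%03d", seq_len(nrow(res)))
  }
  rownames(res) <- NULL
  structure(res, genome_id = g$id, genome_length = g$length,
            topology = g$topology, class = c("orf_calls", class(res)))
}

# Scan one strand given as a plain string; coordinates are positions on that
# strand. Circular genomes are scanned on the doubled sequence and calls are
# deduplicated by the genomic position of their stop codon.
.scan_strand <- function(seqchr, L, circular, starts, min_aa, strand) {
  s2 <- if (circular) paste0(seqchr, seqchr) else seqchr
  n2 <- nchar(s2)
  out <- list()
  seen <- new.env(parent = emptyenv())

  for (f in 0:2) {
    pos <- seq.int(1L + f, n2 - 2L, by = 3L)
    if (!length(pos)) next
    cod <- substring(s2, pos, pos + 2L)
    stop_i <- which(cod %in% STOP_CODONS)
    start_i <- which(cod %in% starts)
    if (!length(stop_i)) next
    prev <- if (circular) stop_i[-length(stop_i)] else c(0L, stop_i[-length(stop_i)])
    term <- if (circular) stop_i[-1L] else stop_i
    for (k in seq_along(term)) {
      j <- term[k]
      p <- prev[k]
      cand <- start_i[start_i > p & start_i < j]
      cand <- cand[(j - cand) >= min_aa]
      if (!length(cand)) next
      span <- 3L * (j - cand[1L] + 1L)
      if (circular && span > L) {
        cand <- cand[3L * (j - cand + 1L) <= L]
        if (!length(cand)) next
      }
      k0 <- cand[1L]
      g_start <- circ_pos(pos[k0], L)
      g_stop_end <- circ_pos(pos[j] + 2L, L)
      key <- paste0(strand, ":", circ_pos(pos[j], L))
      prev_len <- get0(key, envir = seen, ifnotfound = -1L)
      len_aa <- j - k0
      if (len_aa <= prev_len) next
      assign(key, len_aa, envir = seen)
      out[[key]] <- data.frame(
        orf_id = NA_character_, strand = strand,
        start = g_start, end = g_stop_end,
        wraps = g_start > g_stop_end - 2L && circular && pos[k0] <= L,
        start_codon = cod[k0], stop_codon = cod[j],
        length_aa = len_aa, stringsAsFactors = FALSE
      )
      out[[key]]$internal_starts <- list(vapply(cand[-1L], function(kk)
        circ_pos(pos[kk], L), integer(1)))
    }
  }
  if (!length(out)) {
    return(data.frame(orf_id = character(), strand = character(),
                      start = integer(), end = integer(), wraps = logical(),
                      start_codon = character(), stop_codon = character(),
                      length_aa = integer(),
                      internal_starts = I(list()), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # a call wraps when its coding span crosses the origin
  res$wraps <- res$start > res$end
  res
}

#' Extract the coding sequence of an ORF call (stop codon included)
#'
#' @param g A [genome].
#' @param orf One row of an `orf_calls` data frame.
#' @return DNA string of length `3 * (length_aa + 1)`.
#' @export
orf_cds <- function(g, orf) {
  span <- 3L * (orf$length_aa + 1L)
  if (orf$strand == "+") {
    circ_substr(g, orf$start, span)
  } else {
    revcomp(circ_substr(g, orf$end, span))
  }
}

#' Eliminate embedded ORFs without a ribosome binding site
#'
#' An ORF fully contained in a longer retained ORF and lacking any RBS is
#' most likely untranslated and is removed. Non-nested ORFs without an RBS
#' are retained but flagged (`no_rbs`): well-characterised genes can lack a
#' canonical RBS when their initiation is coupled to the upstream gene's
#' termination.
#'
#' @param orfs An `orf_calls` data frame.
#' @param rbs_results Data frame with columns `orf_id` and `category`
#'   (`"canonical"`, `"weak"` or `"none"`), one row per ORF.
#' @return The retained calls with a logical `no_rbs` column; removed calls
#'   (with their `embedded_in` parent id) are kept in the `"removed"`
#'   attribute.
#' @export
filter_embedded <- function(orfs, rbs_results) {
  stopifnot(all(orfs$orf_id %in% rbs_results$orf_id))
  L <- attr(orfs, "genome_length")
  cat_by_id <- setNames(rbs_results$category, rbs_results$orf_id)
  has_rbs <- cat_by_id[orfs$orf_id] != "none"

  posl <- lapply(seq_len(nrow(orfs)), function(i)
    iv_positions(orfs$start[i], orfs$end[i], L, orfs$wraps[i]))
  # orient minus-strand footprints onto plus coordinates
  posl <- lapply(seq_along(posl), function(i) {
    p <- posl[[i]]
    if (orfs$strand[i] == "-") sort(circ_pos(p, L)) else p
  })

  removed <- logical(nrow(orfs))
  parent <- rep(NA_character_, nrow(orfs))
  ord <- order(-orfs$length_aa)
  for (i in seq_len(nrow(orfs))) {
    if (has_rbs[i]) next
    pi <- posl[[i]]
    for (j in ord) {
      if (j == i || orfs$length_aa[j] <= orfs$length_aa[i] || removed[j]) next
      if (all(pi %in% posl[[j]])) {
        removed[i] <- TRUE
        parent[i] <- orfs$orf_id[j]
        break
      }
    }
  }
  out <- orfs[!removed, , drop = FALSE]
  out$no_rbs <- !has_rbs[!removed]
  rem <- orfs[removed, , drop = FALSE]
  rem$embedded_in <- parent[removed]
  attr(out, "removed") <- rem
  attr(out, "genome_length") <- L
  attr(out, "topology") <- attr(orfs, "topology")
  attr(out, "genome_id") <- attr(orfs, "genome_id")
  out
}

#' Detect translational coupling between adjacent ORFs
#'
#' Reports adjacent same-strand pairs whose downstream initiation codon
#' either overlaps the upstream termination codon by one base (the AUGA
#' arrangement) or begins at most `max_gap` nucleotides after it (e.g. the
#' UAAG-AUG arrangement with a single intervening base).
#'
#' @param orfs An `orf_calls` data frame (sorted output of [scan_orfs]).
#' @param g A [genome].
#' @param max_gap Maximum nucleotide gap reported (default 1).
#' @return Data frame with `upstream`, `downstream`, `arrangement`.
#' @export
detect_translational_coupling <- function(orfs, g, max_gap = 1L) {
  out <- list()
  for (str in unique(orfs$strand)) {
    sub <- orfs[orfs$strand == str, , drop = FALSE]
    if (nrow(sub) < 2L) next
    ord <- order(if (str == "+") sub$start else -sub$start)
    sub <- sub[ord, , drop = FALSE]
    L <- g$length
    idx <- seq_len(nrow(sub))
    nxt <- c(idx[-1L], if (g$topology == "circular") 1L else NA_integer_)
    for (k in idx) {
      k2 <- nxt[k]
      if (is.na(k2) || k2 == k) next
      up <- sub[k, ]; dn <- sub[k2, ]
      # distance of the downstream start from the upstream stop codon, along
      # the coding direction; the minus strand runs down the plus coordinates
      if (str == "+") {
        stop_first <- up$end - 2L
        d_overlap <- (stop_first - dn$start) %% L
        gap <- (dn$start - up$end - 1L) %% L
      } else {
        stop_first <- up$end + 2L
        d_overlap <- (dn$start - stop_first) %% L
        gap <- (up$end - dn$start - 1L) %% L
      }
      if (d_overlap == 1L && dn$start_codon == "ATG") {
        out[[length(out) + 1L]] <- data.frame(
          upstream = up$orf_id, downstream = dn$orf_id,
          arrangement = "overlap -1", stringsAsFactors = FALSE)
      } else if (gap <= max_gap) {
        out[[length(out) + 1L]] <- data.frame(
          upstream = up$orf_id, downstream = dn$orf_id,
          arrangement = paste("gap", gap), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(upstream = character(), downstream = character(),
                      arrangement = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
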