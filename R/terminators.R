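# Rho-independent terminator detection.
#
# A terminator candidate is an RNA stem-loop followed by a U-rich tract on
# the coding strand. Hairpins are enumerated exhaustively (stem length,
# loop length, position), allowing at most one internal stem mismatch in the
# default profile, and scored with a nearest-neighbor stacking model whose
# parameter tables ship as editable TSV files. Reported free energies are a
# ranking/sanity score for hairpin stability; they are not calibrated to any
# particular folding program's output.

#' Nearest-neighbor RNA hairpin parameters
#'
#' Loads the packaged Watson-Crick stack free energies (kcal/mol, 37 C,
#' keyed by the top-strand 5'->3' dinucleotide of each stacked pair step) and
#' hairpin loop initiation penalties. Both tables are plain TSV and can be
#' replaced.
#'
#' @param stack_file,loop_file Optional paths overriding the packaged tables.
#' @param terminal_au Destabilisation applied per terminal A-U pair of the
#'   stem (kcal/mol).
#' @return List with `stack` (named numeric), `loop` (named numeric, by loop
#'   length) and `terminal_au`.
#' @export
rna_params <- function(stack_file = NULL, loop_file = NULL,
                       terminal_au = 0.45) {
  if (is.null(stack_file)) {
    stack_file <- system.file("extdata", "rna_stack_params.tsv",
                              package = "phannot", mustWork = TRUE)
  }
  if (is.null(loop_file)) {
    loop_file <- system.file("extdata", "rna_loop_params.tsv",
                             package = "phannot", mustWork = TRUE)
  }
  st <- utils::read.delim(stack_file, stringsAsFactors = FALSE)
  lo <- utils::read.delim(loop_file, stringsAsFactors = FALSE)
  list(stack = setNames(st$dg, st$step),
       loop = setNames(lo$dg, as.character(lo$loop_len)),
       terminal_au = terminal_au)
}

.RNA_PAIR <- c(A = "U", C = "G", G = "C", U = "A")

# valid stem pairs: Watson-Crick, optionally G-U wobble
.pair_ok <- function(x, y, allow_gu = TRUE) {
  wc <- .RNA_PAIR[x] == y
  if (!allow_gu) return(wc)
  wc | (x == "G" & y == "U") | (x == "U" & y == "G")
}

# loop initiation penalty, Jacobson-Stockmayer extrapolation beyond the table
.loop_penalty <- function(loop_len, params) {
  if (loop_len < 3L) stop("loop_len < 3: sterically impossible hairpin")
  tab <- params$loop
  if (as.character(loop_len) %in% names(tab)) {
    unname(tab[as.character(loop_len)])
  } else {
    mx <- max(as.integer(names(tab)))
    unname(tab[as.character(mx)]) + 1.75 * 0.616 * log(loop_len / mx)
  }
}

#' Free energy of a hairpin stem-loop
#'
#' Sums nearest-neighbor stacking terms over consecutive Watson-Crick pair
#' steps of the stem and adds the loop initiation penalty and terminal A-U
#' penalties. Mismatched (non-WC) positions contribute nothing and interrupt
#' stacking.
#'
#' @param stem5 5' arm of the stem, 5'->3' (DNA or RNA alphabet).
#' @param stem3 3' arm of the stem, 5'->3'; base i of `stem5` pairs with base
#'   `n - i + 1` of `stem3`.
#' @param loop_len Loop length in nt (>= 3).
#' @param params Parameter list from [rna_params].
#' @param allow_gu Count G-U wobbles as pairs (they hold the stem together
#'   but contribute no stacking term in this model).
#' @return Free energy in kcal/mol (negative = stable).
#' @export
hairpin_energy <- function(stem5, stem3, loop_len, params = rna_params(),
                           allow_gu = TRUE) {
  s5 <- strsplit(chartr("T", "U", toupper(stem5)), "")[[1L]]
  s3 <- strsplit(chartr("T", "U", toupper(stem3)), "")[[1L]]
  n <- length(s5)
  if (n < 1L) stop("empty stem")
  if (length(s3) != n) stop("stem arms differ in length")
  paired <- .RNA_PAIR[s5] == rev(s3)    # WC pairs drive stacking
  dg <- .loop_penalty(loop_len, params)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (paired[i] && paired[i + 1L]) {
        step <- paste0(s5[i], s5[i + 1L])
        dg <- dg + unname(params$stack[step])
      }
    }
  }
  if (paired[1L] && s5[1L] %in% c("A", "U")) dg <- dg + params$terminal_au
  if (paired[n] && s5[n] %in% c("A", "U")) dg <- dg + params$terminal_au
  dg
}

#' Length of the U-rich tract downstream of a stem
#'
#' The score is the largest number of U (T) residues in any run within the
#' window that contains at most one single-base interruption and starts and
#' ends on a U.
#'
#' @param seq Sequence immediately downstream of the stem (DNA or RNA).
#' @param window Number of leading nt considered (default 8).
#' @return Integer count of U residues in the best run.
#' @export
u_tract_score <- function(seq, window = 8L) {
  s <- strsplit(chartr("U", "T", toupper(substr(seq, 1L, window))), "")[[1L]]
  n <- length(s)
  if (!n) return(0L)
  best <- 0L
  for (a in seq_len(n)) {
    if (s[a] != "T") next
    gaps <- 0L
    count <- 0L
    run_best <- 0L
    for (b in a:n) {
      if (s[b] == "T") {
        count <- count + 1L
        run_best <- max(run_best, count)
      } else {
        gaps <- gaps + 1L
        if (gaps > 1L) break
      }
    }
    best <- max(best, run_best)
  }
  best
}

#' Detect Rho-independent terminator candidates
#'
#' Enumerates stem-loop decompositions on the coding strand (stem length,
#' loop length, at most `max_mismatch` internal stem mismatches with intact
#' terminal pairs), requires a downstream U-rich tract and negative hairpin
#' free energy, and collapses overlapping candidates to the lowest-energy
#' representative.
#'
#' @param g A [genome].
#' @param min_stem,max_stem Stem length bounds (bp).
#' @param loop_range Loop length bounds (nt).
#' @param max_mismatch Maximum internal non-paired stem positions.
#' @param min_u Minimum U-tract score within `u_window` nt downstream.
#' @param u_window U-tract search window (nt).
#' @param params Energy parameters from [rna_params].
#' @param allow_gu Accept G-U wobble pairs in stems (default TRUE).
#' @param collapse Collapse overlapping candidates (default TRUE).
#' @return Data frame of class `terminator_calls`: `start`, `end` (hairpin
#'   bounds), `stem_len`, `loop_len`, `mismatches`, `u_len`, `dg`, sorted by
#'   coordinate.
#' @export
find_terminators <- function(g, min_stem = 4L, max_stem = 15L,
                             loop_range = c(3L, 10L), max_mismatch = 1L,
                             min_u = 3L, u_window = 8L,
                             params = rna_params(), allow_gu = TRUE,
                             collapse = TRUE) {
  stopifnot(inherits(g, "genome"))
  L <- g$length
  circular <- g$topology == "circular"
  ext <- if (circular) 2L * max_stem + loop_range[2] + u_window else 0L
  s <- if (circular) paste0(g$seq, substr(g$seq, 1L, min(ext, L))) else g$seq
  ch <- strsplit(chartr("T", "U", s), "")[[1L]]
  n <- length(ch)
  is_u <- ch == "U"
  cum_u <- cumsum(is_u)

  # candidate stem3'-end positions: >= min_u U's in the downstream window
  e_max <- n - u_window
  if (e_max < 2L * min_stem + loop_range[1]) {
    return(.empty_terminators())
  }
  e_cand <- which((cum_u[(1:e_max) + u_window] - cum_u[1:e_max]) >= min_u)
  e_cand <- e_cand[e_cand > 2L * min_stem + loop_range[1]]

  rows <- list()
  for (e in e_cand) {
    tract <- paste(ch[(e + 1L):(e + u_window)], collapse = "")
    u_len <- u_tract_score(tract, u_window)
    if (u_len < min_u) next
    for (stem in min_stem:max_stem) {
      i3 <- (e - stem + 1L):e
      if (i3[1L] < 1L) break
      arm3 <- ch[i3]
      for (loop in loop_range[1]:loop_range[2]) {
        i5 <- (e - stem - loop - stem + 1L):(e - stem - loop)
        if (i5[1L] < 1L) next
        arm5 <- ch[i5]
        paired <- .pair_ok(arm5, rev(arm3), allow_gu)
        if (!paired[1L] || !paired[stem]) next
        mm <- sum(!paired)
        if (mm > max_mismatch) next
        dg <- hairpin_energy(paste(arm5, collapse = ""),
                             paste(arm3, collapse = ""), loop, params,
                             allow_gu)
        if (dg >= 0) next
        start <- i5[1L]
        if (start > L) next  # wrap duplicate; canonical copy starts in 1..L
        rows[[length(rows) + 1L]] <- data.frame(
          start = circ_pos(start, L), end = circ_pos(e, L),
          stem_len = stem, loop_len = loop, mismatches = mm,
          u_len = u_len, dg = dg,
          raw_start = start, raw_end = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.empty_terminators())
  res <- do.call(rbind, rows)

  if (collapse) {
    ord <- order(res$dg, res$mismatches, res$raw_end - res$raw_start)
    keep <- logical(nrow(res))
    taken <- integer(0)
    for (i in ord) {
      span <- res$raw_start[i]:res$raw_end[i]
      if (!any(span %in% taken)) {
        keep[i] <- TRUE
        taken <- c(taken, span)
      }
    }
    res <- res[keep, , drop = FALSE]
  }
  res <- res[order(res$raw_start), , drop = FALSE]
  res$raw_start <- NULL
  res$raw_end <- NULL
  rownames(res) <- NULL
  class(res) <- c("terminator_calls", class(res))
  res
}

.empty_terminators <- function() {
  structure(data.frame(start = integer(), end = integer(),
                       stem_len = integer(), loop_len = integer(),
                       mismatches = integer(), u_len = integer(),
                       dg = numeric(), stringsAsFactors = FALSE),
            class = c("terminator_calls", "data.frame"))
}
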