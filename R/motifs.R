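# Programmed ribosomal frameshift motifs.
#
# Two recoding signals are searched within called ORFs: a +1 shift at a rare
# CCC proline codon directly followed by a UAA stop (the CCCUAA signal,
# where pausing ribosomes slip onto the overlapping frequent CCU codon), and
# a -1 shift at a slippery heptamer (UUUUUUC, or generically X XXY YYZ with
# X, Y in {A, U}). A site is only reported when the shifted frame stays open
# for at least `min_ext` codons up to a downstream stop, since spurious
# shifts with no room to extend produce no alternative protein.

# walk codons in a genome frame starting at coding-strand position `pos`
# (first codon base); returns number of open codons before the first stop,
# or NA if no stop is found within `limit` codons
.open_codons_to_stop <- function(g, pos, strand, limit) {
  for (i in seq_len(limit)) {
    p <- if (strand == "+") circ_pos(pos + 3L * (i - 1L), g$length)
         else circ_pos(pos - 3L * (i - 1L), g$length)
    cod <- if (strand == "+") circ_substr(g, p, 3L)
           else revcomp(circ_substr(g, p - 2L, 3L))
    if (cod %in% STOP_CODONS) return(i - 1L)
  }
  NA_integer_
}

#' Detect +1 frameshift sites at an ORF's terminal CCC-UAA signal
#'
#' @param orf One row of an `orf_calls` data frame.
#' @param g A [genome].
#' @param min_ext Minimum open extension in the +1 frame (codons).
#' @return Data frame of class rows `orf_id`, `kind`, `position` (coordinate
#'   of the CCC codon's first base), `motif`, `ext_aa` (codons gained),
#'   `shared_prefix_aa`; zero rows when the signal is absent.
#' @export
find_plus1_sites <- function(orf, g, min_ext = 10L) {
  span <- 3L * (orf$length_aa + 1L)
  cds <- orf_cds(g, orf)
  last6 <- substr(cds, span - 5L, span)
  if (last6 != "CCCTAA") return(.empty_sites())
  # the slip re-reads CCU (one base into the stop) and continues +1
  stop_start_off <- span - 2L                 # offset of T of TAA within cds
  ext_start_off <- stop_start_off + 1L        # first +1-frame codon after CCU
  ext_pos <- if (orf$strand == "+") circ_pos(orf$start + ext_start_off - 1L, g$length)
             else circ_pos(orf$start - (ext_start_off - 1L), g$length)
  ext <- .open_codons_to_stop(g, ext_pos, orf$strand,
                              floor(g$length / 3) - 1L)
  if (is.na(ext) || ext < min_ext) return(.empty_sites())
  ccc_pos <- if (orf$strand == "+") circ_pos(orf$start + span - 6L, g$length)
             else circ_pos(orf$start - (span - 6L), g$length)
  # the re-read CCU proline replaces the original CCC one, so the shifted
  # product is longer by exactly the open +1 extension
  data.frame(orf_id = orf$orf_id, kind = "plus1", position = ccc_pos,
             motif = "CCCUAA", ext_aa = ext,
             shared_prefix_aa = orf$length_aa, stringsAsFactors = FALSE)
}

#' Detect -1 frameshift sites at slippery heptamers within an ORF
#'
#' @param orf One row of an `orf_calls` data frame.
#' @param g A [genome].
#' @param heptamers DNA heptamer patterns accepted as slippery sites;
#'   default is TTTTTTC plus the generic X XXY YYZ pattern with X, Y in
#'   {A, T}.
#' @param min_ext Minimum open extension in the -1 frame (codons).
#' @return Data frame rows `orf_id`, `kind`, `position`, `motif`, `ext_aa`,
#'   `shared_prefix_aa`.
#' @export
find_minus1_sites <- function(orf, g, heptamers = NULL, min_ext = 10L) {
  cds <- orf_cds(g, orf)
  body_len <- 3L * orf$length_aa
  body <- substr(cds, 1L, body_len)
  hits <- integer(0)
  motifs <- character(0)
  if (is.null(heptamers)) {
    pats <- c(fixed = "TTTTTTC")
    generic <- TRUE
  } else {
    pats <- toupper(heptamers)
    generic <- FALSE
  }
  for (p in pats) {
    m <- gregexpr(p, body, fixed = TRUE)[[1L]]
    if (m[1L] != -1L) { hits <- c(hits, m); motifs <- c(motifs, rep(p, length(m))) }
  }
  if (generic) {
    m <- gregexpr("([AT])\\1\\1([AT])\\2\\2[ACGT]", body, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      for (o in as.integer(m)) {
        if (!o %in% hits) {
          hits <- c(hits, o)
          motifs <- c(motifs, substr(body, o, o + 6L))
        }
      }
    }
  }
  if (!length(hits)) return(.empty_sites())
  ord <- order(hits)
  hits <- hits[ord]; motifs <- motifs[ord]

  rows <- list()
  for (k in seq_along(hits)) {
    o <- hits[k]
    if (o %% 3L != 0L) next          # X must sit on a codon's third base
    if (o + 6L > body_len) next      # heptamer must fit inside the body
    n <- o %/% 3L                    # codon carrying the first X
    # -1 frame resumes at offset 3n+3 (the last base of codon XXY)
    shift_off <- 3L * n + 3L
    shift_pos <- if (orf$strand == "+") circ_pos(orf$start + shift_off - 1L, g$length)
                 else circ_pos(orf$start - (shift_off - 1L), g$length)
    ext <- .open_codons_to_stop(g, shift_pos, orf$strand,
                                floor(g$length / 3) - 1L)
    if (is.na(ext) || ext < min_ext) next
    site_pos <- if (orf$strand == "+") circ_pos(orf$start + o - 1L, g$length)
                else circ_pos(orf$start - (o - 1L), g$length)
    rows[[length(rows) + 1L]] <- data.frame(
      orf_id = orf$orf_id, kind = "minus1", position = site_pos,
      motif = chartr("T", "U", motifs[k]), ext_aa = ext,
      shared_prefix_aa = n + 1L, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_sites())
  do.call(rbind, rows)
}

.empty_sites <- function() {
  data.frame(orf_id = character(), kind = character(), position = integer(),
             motif = character(), ext_aa = integer(),
             shared_prefix_aa = integer(), stringsAsFactors = FALSE)
}

#' Predict the two protein products of a frameshift site
#'
#' For each site, emits the unshifted product, the shifted (fusion) product,
#' and the length of their identical amino-terminal region.
#'
#' @param orf One row of an `orf_calls` data frame.
#' @param g A [genome].
#' @param sites Data frame from [find_plus1_sites] or [find_minus1_sites].
#' @return Data frame `orf_id`, `kind`, `shared_prefix_aa`, `len_a`, `len_b`,
#'   `protein_a`, `protein_b`.
#' @export
predict_fusion_products <- function(orf, g, sites) {
  if (!nrow(sites)) {
    return(data.frame(orf_id = character(), kind = character(),
                      shared_prefix_aa = integer(), len_a = integer(),
                      len_b = integer(), protein_a = character(),
                      protein_b = character(), stringsAsFactors = FALSE))
  }
  cds <- orf_cds(g, orf)
  prot_a <- translate_cds(cds)$protein
  rows <- lapply(seq_len(nrow(sites)), function(k) {
    s <- sites[k, ]
    if (s$kind == "plus1") {
      span <- 3L * (orf$length_aa + 1L)
      # shifted read: common prefix through codon length_aa - 1, then CCU,
      # then the +1 extension up to and excluding its stop
      shift_off <- span - 4L                  # offset of first CCU base
      n_shift <- s$ext_aa                     # CCU plus downstream codons
      shifted <- .read_frame(g, orf, shift_off, n_shift + 1L)
      prot_b <- paste0(substr(prot_a, 1L, orf$length_aa - 1L),
                       translate_cds(shifted, initiator_met = FALSE)$protein)
    } else {
      n_pre <- s$shared_prefix_aa
      shift_off <- 3L * n_pre                 # last base of codon XXY
      shifted <- .read_frame(g, orf, shift_off, s$ext_aa)
      prot_b <- paste0(substr(prot_a, 1L, n_pre),
                       translate_cds(shifted, initiator_met = FALSE)$protein)
    }
    data.frame(orf_id = orf$orf_id, kind = s$kind,
               shared_prefix_aa = s$shared_prefix_aa,
               len_a = nchar(prot_a), len_b = nchar(prot_b),
               protein_a = prot_a, protein_b = prot_b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# read n_codons + their terminating stop from a coding-strand offset within
# an ORF (1-based; may run past the ORF end into downstream sequence)
.read_frame <- function(g, orf, offset, n_codons) {
  len <- 3L * n_codons + 3L
  if (orf$strand == "+") {
    circ_substr(g, circ_pos(orf$start + offset - 1L, g$length), len)
  } else {
    p <- circ_pos(orf$start - (offset - 1L) - (len - 1L), g$length)
    revcomp(circ_substr(g, p, len))
  }
}
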