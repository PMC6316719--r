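# Genome container and circular-coordinate arithmetic.
#
# All coordinates in this package are 1-based and inclusive, and the stop
# coordinate of a coding feature includes the last base of the termination
# codon. Sequences are stored as DNA (T, not U); report-facing strings that
# describe mRNA context (RBS patterns, codons) are rendered with U.

#' Construct a genome object
#'
#' A genome is a single DNA record plus a topology flag. Phage genomes as
#' packaged are terminally redundant and circularly permuted, so the molecule
#' that matters for annotation is circular; topology therefore defaults to
#' circular.
#'
#' @param seq Character scalar of A/C/G/T (case-insensitive). Ambiguity codes
#'   are rejected.
#' @param id Record identifier.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `genome` with fields `id`, `seq` (uppercase),
#'   `topology` and `length`.
#' @export
genome <- function(seq, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop("non-ACGT residue '", substr(seq, bad, bad), "' at position ", bad)
  }
  structure(
    list(id = id, seq = seq, topology = topology, length = nchar(seq)),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' Read a genome from a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one DNA record.
#' @param topology Topology to assign (`"circular"` by default).
#' @return A [genome] object.
#' @export
read_genome_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L) {
    stop("expected single record, found ", length(set), " in ", path)
  }
  genome(as.character(set[[1L]]), id = names(set)[1L], topology = topology)
}

#' Write a genome to FASTA
#'
#' @param g A [genome].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_genome_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  set <- Biostrings::DNAStringSet(g$seq)
  names(set) <- g$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Feature span in nucleotides, circular-aware
#'
#' A non-wrapping feature spans `end - start + 1` bases; a feature crossing
#' the origin of a circular genome spans `(L - start + 1) + end`. For a
#' coding feature the span equals `3 * (length_aa + 1)` because the stop
#' codon is included.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param L Genome length.
#' @param topology `"circular"` or `"linear"`.
#' @return Integer span (>= 1).
#' @export
span_length <- function(start, end, L, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(start >= 1, start <= L, end >= 1, end <= L)
  if (start <= end) {
    as.integer(end - start + 1)
  } else {
    if (topology != "circular") {
      stop("start > end on a linear genome")
    }
    as.integer((L - start + 1) + end)
  }
}

#' Extract a subsequence, wrapping across the origin when needed
#'
#' @param g A [genome].
#' @param start,end 1-based inclusive coordinates.
#' @param wraps Set `TRUE` for a feature that crosses the origin of a
#'   circular genome; the result concatenates `start..L` with `1..end`.
#' @return Character scalar.
#' @export
subsequence <- function(g, start, end, wraps = FALSE) {
  stopifnot(inherits(g, "genome"))
  L <- g$length
  stopifnot(start >= 1, start <= L, end >= 1, end <= L)
  if (!wraps) {
    if (start > end) stop("start > end; set wraps = TRUE on a circular genome")
    substr(g$seq, start, end)
  } else {
    if (g$topology != "circular") stop("wrapping interval on a linear genome")
    paste0(substr(g$seq, start, L), substr(g$seq, 1L, end))
  }
}

# Map any (possibly out-of-range) position onto 1..L.
circ_pos <- function(p, L) ((p - 1L) %% L) + 1L

# Substring of length `len` starting at circular position `start`; the genome
# sequence is treated as infinitely repeated when circular.
circ_substr <- function(g, start, len) {
  L <- g$length
  start <- circ_pos(start, L)
  end <- start + len - 1L
  if (end <= L) {
    substr(g$seq, start, end)
  } else {
    if (g$topology != "circular") stop("window extends past the sequence end")
    paste0(substr(g$seq, start, L),
           paste(rep(g$seq, ceiling((end - L) / L)), collapse = ""))  |>
      substr(1L, len)
  }
}

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over A/C/G/T.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a coding sequence with the bacterial code
#'
#' Translates a complete CDS (length divisible by 3, ending in a stop codon),
#' excluding the terminal stop from the protein and reporting its identity.
#' All accepted initiation codons (ATG/GTG/TTG) translate to the initiator
#' methionine, as in the annotated proteins.
#'
#' @param seq DNA coding sequence including the terminal stop codon.
#' @param initiator_met Force the first residue to `M` when the first codon is
#'   a recognised start (default TRUE).
#' @return List with `protein` (character) and `stop_codon` (DNA codon).
#' @export
translate_cds <- function(seq, initiator_met = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length ", n, " is not divisible by 3")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("unrecognised codon at codon index ", which(is.na(aa))[1L])
  n_cod <- length(codons)
  if (aa[n_cod] != "*") stop("sequence does not end in a stop codon")
  internal <- which(aa[-n_cod] == "*")
  if (length(internal)) {
    stop("internal stop codon at codon index ", internal[1L])
  }
  prot <- aa[-n_cod]
  if (initiator_met && length(prot) &&
      codons[1L] %in% c("ATG", "GTG", "TTG")) {
    prot[1L] <- "M"
  }
  list(protein = paste(prot, collapse = ""), stop_codon = codons[n_cod])
}

# Genome positions covered by an interval (coding-strand orientation aware
# only in span; returns plus-strand positions).
iv_positions <- function(start, end, L, wraps = FALSE) {
  if (!wraps) start:end else c(start:L, 1:end)
}
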