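# Minimal GFF3 (version 3) writing. Coordinates are 1-based inclusive per
# the standard. GFF3 has no native representation of a feature spanning the
# origin of a circular genome, so a wrapping feature is serialised as two
# part lines sharing an ID attribute.

#' Write features to a GFF3 file
#'
#' @param features Data frame with the nine GFF3 columns `seqid`, `source`,
#'   `type`, `start`, `end`, `score`, `strand`, `phase`, `attributes`.
#'   Rows with `start > end` are treated as origin-wrapping and split in two.
#' @param path Output path.
#' @param L Genome length (required to split wrapping features).
#' @param circular Whether the genome is circular.
#' @return Invisible `path`.
#' @export
write_gff3 <- function(features, path, L, circular = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    writeLines(sprintf("##sequence-region %s 1 %d", features$seqid[1L], L),
               con)
  }
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (f$start <= f$end) {
      writeLines(.gff3_line(f, f$start, f$end), con)
    } else {
      if (!circular) stop("start > end on a linear genome")
      writeLines(.gff3_line(f, f$start, L), con)
      writeLines(.gff3_line(f, 1L, f$end), con)
    }
  }
  invisible(path)
}

.gff3_line <- function(f, start, end) {
  sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
          f$seqid, f$source, f$type, start, end,
          as.character(f$score), f$strand, as.character(f$phase),
          f$attributes)
}
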