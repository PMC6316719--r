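# Annotate-everything orchestration: composition -> ORF calling -> RBS ->
# embedded-ORF elimination -> dual starts -> translational coupling ->
# terminators -> frameshift motifs -> codon usage -> summary.

#' Annotation profile (threshold bundle)
#'
#' All tunable thresholds of the pipeline in one declarative object. The
#' shipped default profile, `"spp1-2018"`, holds the values used for the
#' phage SPP1 re-annotation: >= 45-aa products starting at AUG/GUG/UUG on
#' the heavy strand, anti-SD spacing 8-14 nt, and stem-loop + U-tract
#' terminators on the coding strand.
#'
#' @param name Profile name.
#' @param min_aa Minimum ORF product length (aa).
#' @param starts Accepted initiation codons.
#' @param strand_mode `"heavy"` or `"both"`.
#' @param rbs An [sd_model].
#' @param rbs_window Upstream RBS search window (nt).
#' @param dual_start_k Leading codons searched for dual starts.
#' @param coupling_max_gap Maximum coupling gap (nt).
#' @param term_min_stem,term_max_stem,term_loop_range,term_max_mismatch,term_min_u
#'   Terminator thresholds (see [find_terminators]).
#' @param at_window,at_threshold AT-island parameters.
#' @param min_ext Minimum open extension for frameshift sites (codons).
#' @return List of class `annotation_profile`.
#' @export
annotation_profile <- function(name = "spp1-2018",
                               min_aa = 45L,
                               starts = c("ATG", "GTG", "TTG"),
                               strand_mode = "heavy",
                               rbs = sd_model(),
                               rbs_window = 25L,
                               dual_start_k = 15L,
                               coupling_max_gap = 1L,
                               term_min_stem = 4L,
                               term_max_stem = 15L,
                               term_loop_range = c(3L, 10L),
                               term_max_mismatch = 1L,
                               term_min_u = 3L,
                               at_window = 50L,
                               at_threshold = 0.75,
                               min_ext = 10L) {
  structure(list(
    name = name, min_aa = min_aa, starts = starts, strand_mode = strand_mode,
    rbs = rbs, rbs_window = rbs_window, dual_start_k = dual_start_k,
    coupling_max_gap = coupling_max_gap, term_min_stem = term_min_stem,
    term_max_stem = term_max_stem, term_loop_range = term_loop_range,
    term_max_mismatch = term_max_mismatch, term_min_u = term_min_u,
    at_window = at_window, at_threshold = at_threshold, min_ext = min_ext
  ), class = "annotation_profile")
}

#' Annotate a genome
#'
#' Runs the full pipeline on a genome and collects every result in one
#' report object. Deterministic for fixed input and profile.
#'
#' @param x A [genome], or a path to a single-record FASTA file.
#' @param profile An [annotation_profile].
#' @param topology Topology used when `x` is a path.
#' @param verbose Log each stage's feature counts.
#' @return Object of class `phage_annotation`: a list with `genome_id`,
#'   `length`, `topology`, `composition` (gc/purine/AT islands), `orfs`
#'   (retained calls with RBS columns), `removed_orfs`, `coupling`,
#'   `dual_starts`, `terminators`, `slippery`, `codon_usage`, `summary`,
#'   `profile`.
#' @export
annotate <- function(x, profile = annotation_profile(),
                     topology = c("circular", "linear"), verbose = FALSE) {
  topology <- match.arg(topology)
  g <- if (inherits(x, "genome")) x else read_genome_fasta(x, topology)
  say <- function(stage, n) if (verbose) message(stage, ": ", n)

  comp <- list(
    gc_pct = gc_content(g),
    purine_pct_fwd = purine_content(g),
    purine_pct_rev = 100 - purine_content(g),
    heavy_strand = heavy_strand(g),
    at_islands = at_islands(g, profile$at_window, profile$at_threshold)
  )
  say("at_islands", nrow(comp$at_islands))

  orfs <- scan_orfs(g, min_aa = profile$min_aa, starts = profile$starts,
                    strand_mode = profile$strand_mode)
  say("orfs", nrow(orfs))

  rbs <- scan_rbs_all(g, orfs, profile$rbs, profile$rbs_window)
  orfs <- filter_embedded(orfs, rbs)
  removed <- attr(orfs, "removed")
  say("orfs_retained", nrow(orfs))
  orfs_rbs <- merge(orfs, rbs, by = "orf_id", sort = FALSE)
  orfs_rbs <- orfs_rbs[order(orfs_rbs$start), , drop = FALSE]
  rownames(orfs_rbs) <- NULL

  coupling <- detect_translational_coupling(orfs, g,
                                            profile$coupling_max_gap)
  say("coupling_pairs", nrow(coupling))

  duals <- lapply(seq_len(nrow(orfs)), function(i)
    detect_dual_starts(orfs[i, ], g, profile$dual_start_k, profile$rbs))
  duals <- do.call(rbind, duals)
  say("dual_starts", if (is.null(duals)) 0L else nrow(duals))

  terms <- find_terminators(g, min_stem = profile$term_min_stem,
                            max_stem = profile$term_max_stem,
                            loop_range = profile$term_loop_range,
                            max_mismatch = profile$term_max_mismatch,
                            min_u = profile$term_min_u)
  say("terminators", nrow(terms))

  slips <- lapply(seq_len(nrow(orfs)), function(i) {
    rbind(find_plus1_sites(orfs[i, ], g, profile$min_ext),
          find_minus1_sites(orfs[i, ], g, min_ext = profile$min_ext))
  })
  slips <- do.call(rbind, slips)
  say("slippery_sites", if (is.null(slips)) 0L else nrow(slips))

  cds <- vapply(seq_len(nrow(orfs)), function(i) orf_cds(g, orfs[i, ]),
                character(1))
  usage <- if (length(cds)) codon_usage(cds) else NULL

  # footprint orientation for the coverage union: minus-strand calls list
  # their coding 5' end first, so swap them onto plus coordinates
  minus <- orfs$strand == "-"
  s_nt <- ifelse(minus, orfs$end, orfs$start)
  e_nt <- ifelse(minus, orfs$start, orfs$end)
  summ_rows <- data.frame(start_nt = s_nt, stop_nt = e_nt,
                          start_codon = orfs$start_codon,
                          stop_codon = orfs$stop_codon,
                          length_aa = orfs$length_aa,
                          rbs_category = rbs$category[match(orfs$orf_id,
                                                            rbs$orf_id)],
                          stringsAsFactors = FALSE)
  summ_rows$mass_kda <- vapply(cds, function(s)
    protein_mass(translate_cds(s)$protein) / 1000, numeric(1),
    USE.NAMES = FALSE)
  summ <- if (nrow(summ_rows)) {
    summarize_orf_table(summ_rows, g$length, g$topology)
  } else NULL

  structure(list(
    genome_id = g$id, length = g$length, topology = g$topology,
    composition = comp,
    orfs = orfs_rbs, removed_orfs = removed,
    coupling = coupling,
    dual_starts = if (is.null(duals)) .empty_duals() else duals,
    terminators = terms,
    slippery = if (is.null(slips)) .empty_sites() else slips,
    codon_usage = usage,
    summary = summ,
    profile = profile$name
  ), class = "phage_annotation")
}

.empty_duals <- function() {
  data.frame(orf_id = character(), offset_aa = integer(),
             position = integer(), pattern = character(),
             spacing = integer(), stringsAsFactors = FALSE)
}

#' @export
print.phage_annotation <- function(x, ...) {
  cat(sprintf("<phage_annotation> %s (%s bp, %s; profile %s)\n",
              x$genome_id, format(x$length, big.mark = ","), x$topology,
              x$profile))
  cat(sprintf("  GC %.1f%% | purines fwd %.1f%% rev %.1f%% (heavy: %s)\n",
              x$composition$gc_pct, x$composition$purine_pct_fwd,
              x$composition$purine_pct_rev, x$composition$heavy_strand))
  cat(sprintf("  %d ORFs retained (%d removed as embedded, RBS-less)\n",
              nrow(x$orfs),
              if (is.null(x$removed_orfs)) 0L else nrow(x$removed_orfs)))
  cat(sprintf("  %d terminators | %d slippery sites | %d dual starts | %d coupled pairs\n",
              nrow(x$terminators), nrow(x$slippery), nrow(x$dual_starts),
              nrow(x$coupling)))
  if (!is.null(x$summary)) {
    cat(sprintf("  coverage %.1f%% | mean product %.0f aa / %.1f kDa\n",
                x$summary$coverage_pct, x$summary$mean_length_aa,
                x$summary$mean_mass_kda))
  }
  invisible(x)
}

#' @export
summary.phage_annotation <- function(object, ...) {
  print(object)
  if (!is.null(object$summary)) {
    cat("  start codons: ",
        paste(names(object$summary$start_tally),
              as.integer(object$summary$start_tally), collapse = " | "),
        "\n")
    cat("  stop codons:  ",
        paste(names(object$summary$stop_tally),
              as.integer(object$summary$stop_tally), collapse = " | "),
        "\n")
  }
  invisible(object)
}

#' Export an annotation report
#'
#' Writes GFF3 (CDS with phase 0, terminators, recoding signals; wrapping
#' features as two part-lines sharing an ID), a TSV ORF table mirroring the
#' reference-table column order, and a JSON serialisation of the whole
#' report.
#'
#' @param report A `phage_annotation`.
#' @param dir Output directory.
#' @param formats Subset of `c("gff3", "tsv", "json")`.
#' @return Invisible named vector of paths written.
#' @export
export_report <- function(report, dir, formats = c("gff3", "tsv", "json")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  if ("gff3" %in% formats) {
    p <- file.path(dir, "annotation.gff3")
    feats <- .report_features(report)
    write_gff3(feats, p, L = report$length,
               circular = report$topology == "circular")
    out["gff3"] <- p
  }
  if ("tsv" %in% formats) {
    p <- file.path(dir, "orfs.tsv")
    o <- report$orfs
    tab <- data.frame(orf = o$orf_id, rbs = o$pattern, spacing = o$spacing,
                      start_codon = chartr("T", "U", o$start_codon),
                      start_nt = o$start,
                      stop_codon = chartr("T", "U", o$stop_codon),
                      stop_nt = o$end, length_aa = o$length_aa,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out["tsv"] <- p
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "annotation.json")
    write_report_json(report, p)
    out["json"] <- p
  }
  invisible(out)
}

.report_features <- function(report) {
  rows <- list()
  o <- report$orfs
  if (nrow(o)) {
    rows[[1L]] <- data.frame(
      seqid = report$genome_id, source = "phannot", type = "CDS",
      start = o$start, end = o$end, score = ".", strand = o$strand,
      phase = "0", attributes = sprintf("ID=%s", o$orf_id),
      stringsAsFactors = FALSE)
  }
  t <- report$terminators
  if (nrow(t)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = report$genome_id, source = "phannot", type = "terminator",
      start = t$start, end = t$end,
      score = sprintf("%.2f", t$dg), strand = "+", phase = ".",
      attributes = sprintf("ID=term_%03d", seq_len(nrow(t))),
      stringsAsFactors = FALSE)
  }
  s <- report$slippery
  if (nrow(s)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = report$genome_id, source = "phannot",
      type = "recoding_stimulatory_region",
      start = s$position, end = s$position + 6L, score = ".", strand = "+",
      phase = ".",
      attributes = sprintf("ID=slip_%03d;Parent=%s;kind=%s",
                           seq_len(nrow(s)), s$orf_id, s$kind),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(),
                      end = integer(), score = character(),
                      strand = character(), phase = character(),
                      attributes = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Serialise / restore an annotation report as JSON
#'
#' The JSON round trip is lossless for every feature table in the report.
#'
#' @param report A `phage_annotation`.
#' @param path JSON path.
#' @return `write_report_json`: invisible path. `read_report_json`: the
#'   restored `phage_annotation`.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$orfs$internal_starts <- NULL
  if (!is.null(x$removed_orfs)) x$removed_orfs$internal_starts <- NULL
  x$codon_usage <- if (!is.null(x$codon_usage)) {
    list(counts = as.list(x$codon_usage$counts), total = x$codon_usage$total)
  }
  if (!is.null(x$summary)) {
    x$summary$start_tally <- as.list(x$summary$start_tally)
    x$summary$stop_tally <- as.list(x$summary$stop_tally)
    x$summary$stop_fractions <- as.list(x$summary$stop_fractions)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$codon_usage <- if (!is.null(x$codon_usage)) {
    codon_usage_from_counts(unlist(x$codon_usage$counts))
  }
  if (!is.null(x$summary)) {
    x$summary$start_tally <- unlist(x$summary$start_tally)
    x$summary$stop_tally <- unlist(x$summary$stop_tally)
    x$summary$stop_fractions <- unlist(x$summary$stop_fractions)
  }
  class(x) <- "phage_annotation"
  x
}
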