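# Packaged SPP1 reference tables (plain TSV under inst/extdata), transcribed
# from the published re-annotation of the 44,016 bp genome: the 80-ORF table
# (RBS pattern, spacing, coordinates, length, mass), the 13 Rho-independent
# terminators with their printed stem-loop free energies, and the codon
# usage table for the phage ORF set and its B. subtilis host.

.fixture <- function(name) {
  f <- system.file("extdata", name, package = "phannot", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE,
                    colClasses = if (name == "spp1_orfs.tsv")
                      c(orf = "character") else NA)
}

#' The packaged 80-row phage ORF reference table
#'
#' Columns: `orf` (name; frameshift products carry a `*`), `rbs` (mRNA-side
#' pattern, mismatches lowercase, `n.d.` when absent), `spacing`,
#' `start_codon`, `start_nt`, `stop_codon`, `stop_nt` (1-based inclusive,
#' stop codon included; gene 1 wraps the origin), `length_aa`, `mass_kda`,
#' `tmm` (predicted transmembrane segments), `rbs_category`.
#'
#' @return Data frame with 80 rows.
#' @export
spp1_orf_table <- function() .fixture("spp1_orfs.tsv")

#' The packaged 13-row phage terminator reference table
#'
#' Columns: `sequence` (coding strand, DNA), `start`, `end`, `dg` (printed
#' stem-loop free energy, kcal/mol).
#'
#' @return Data frame with 13 rows.
#' @export
spp1_terminator_table <- function() .fixture("spp1_terminators.tsv")

#' The packaged phage/host codon usage reference table
#'
#' Within-family usage fractions and raw counts for the 80-ORF phage set
#' (`spp1_*` columns) and the host genome (`bs_*` columns); `divergent`
#' marks codons whose fractions differ by more than 0.1, as highlighted in
#' the published table.
#'
#' @return Data frame with 64 rows.
#' @export
spp1_codon_table <- function() .fixture("spp1_codon_usage.tsv")
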