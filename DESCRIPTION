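Package: phannot
Title: Annotation Toolkit for Small Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-annotation toolkit for small (circular) bacteriophage genomes,
    built around the Bacillus subtilis phage SPP1 genome. Provides ORF calling
    with configurable start codons and a minimum-length cut-off, anti-Shine-
    Dalgarno ribosome binding site scanning with an explicit spacing rule,
    Rho-independent terminator detection with nearest-neighbor hairpin free
    energies, codon usage bias tables, genome composition statistics,
    programmed ribosomal frameshift motif discovery, a seeded synthetic-genome
    generator with planted ground-truth features, and GFF3/TSV/JSON export.
    Ships the SPP1 ORF, terminator and codon-usage reference tables as
    plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
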