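Package: dgrscan
Title: Gene-Neighborhood Screening for Defense Systems Organized Around
    Diversity-Generating Retroelements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to nominate candidate prokaryotic anti-phage defense
    systems organized around diversity-generating retroelements (DGRs).
    Implements a Pfam-cluster co-localization (Icity) score around DGR
    reverse-transcriptase and variable-repeat baits with a multi-run
    convergence protocol, immune-Pfam composition selection, gene-order
    and strand arrangement canonicalization and conservation analysis, a
    codon-usage-bias (effective number of codons, Kolmogorov-Smirnov)
    screen for recent horizontal transfer, and residence/clade/taxon
    profiling. Ships a seeded synthetic-contig generator that plants DGR
    cassettes with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
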