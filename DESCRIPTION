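Package: orthoprimer
Title: Cross-Species PCR Primer Design from Conserved Regions of
    Orthologous Genes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Designs PCR primer pairs for non-sequenced target species by
    comparative genomics of two fully-sequenced reference genomes. Detects
    perfectly identical conserved regions (>= 20 bp) within one-to-one
    orthologous unspliced gene pairs, enumerates conserved-region pairs
    flanking a 300-700 bp putatively polymorphic interval, picks primers
    confined to the conserved regions over a dummy-spacer template, screens
    primers genome-wide with Karlin-Altschul E-values, scores interval
    identity after N-column removal, classifies loci as exonic, intronic or
    both, applies chromosome-balanced candidate selection within a 75-90%
    identity band, and tests GO-slim term enrichment of primer-bearing genes
    with exact hypergeometric p-values and resampled Z scores. Includes a
    seeded synthetic reference-pair simulator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, GeneSetEnrichment,
    ComparativeGenomics
RoxygenNote: 7.3.3
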