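# Shared fixtures built in code.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

# Write a minimal genome FASTA + GFF3 and load the GenomeAnnotation.
makeTinyAnnotation <- function(chromSeqs, gffLines, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "g.fa")
  writeLines(unlist(lapply(names(chromSeqs), function(id) {
    c(paste0(">", id), chromSeqs[[id]])
  })), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3", gffLines), gff)
  readGff3(gff, readGenomeFasta(fa))
}

# The planted-locus study scenario (in-window spacing kept clear of the
# 300/700 edges so small intronic indels cannot push a planted interval
# out of the design window; divergence capped at ~20% substitutions).
acceptanceScenarioConfig <- function(seed = 20260101L) {
  simulationConfig(
    seed = seed, nGenes = 20L, inWindowGenes = 10L,
    spacingRange = c(350L, 650L),
    exonRate = 0.08, intronRate = 0.18, rateScaleRange = c(0.8, 1.1),
    decoyFraction = 0)
}

# One shared scenario run, computed lazily and reused across tests.
.runCache <- new.env(parent = emptyenv())
getScenarioRun <- function() {
  if (!is.null(.runCache$run)) return(.runCache$run)
  sim <- simulateReferencePair(acceptanceScenarioConfig(), tempfile("acc"))
  annA <- readGff3(sim$paths$gffA, readGenomeFasta(sim$paths$genomeA))
  annB <- readGff3(sim$paths$gffB, readGenomeFasta(sim$paths$genomeB))
  orth <- utils::read.delim(sim$paths$orthologs)
  res <- runDesign(annA, annB, orth)
  .runCache$run <- list(sim = sim, annA = annA, annB = annB,
                        orth = orth, res = res)
  .runCache$run
}
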