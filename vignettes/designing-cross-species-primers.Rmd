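---
title: "Designing cross-species PCR primers from conserved regions"
author: "orthoprimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cross-species PCR primers from conserved regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoprimer)
```

## The problem

Population-genetic studies of species without a sequenced genome need
co-dominant, sequence-based nuclear markers, but primers cannot be designed
directly against an unknown genome. A comparative-genomics workaround uses
two fully sequenced *reference* species that bracket (or neighbour) the
target lineage: wherever the two reference genomes are *perfectly identical*
over a stretch long enough to hold a primer, the target species — sitting
phylogenetically between or near them — is very likely to carry a
near-identical sequence too. A pair of such conserved regions (CRs) flanking
a few hundred bases of divergent sequence defines a PCR assay: the primers
anneal in the conserved anchors, and the amplified *interval region* (IR) is
the putatively polymorphic marker.

`orthoprimer` implements this pipeline end to end, together with a seeded
synthetic data generator so that every stage can be validated against known
ground truth without any external downloads.

## The pipeline

1. **Ortholog filtering.** Only one-to-one orthologous gene pairs are used
   (`filterOrthologs()`). One-to-many and many-to-many relationships are
   discarded because lineage-specific duplications would let one primer pair
   amplify several fragments.
2. **Conserved-region detection.** Within each orthologous pair of
   *unspliced* gene sequences (introns included, transcript orientation),
   `findConservedRegions()` reports every maximal exact match of at least
   20 bp. Matching is strict base identity over A/C/G/T; N never matches, so
   a CR can never contain an unknown base. Detection seeds on shared k-mers
   (k = the minimum length) and extracts match runs per diagonal, which is
   provably exhaustive for matches of at least k bases.
3. **Locus enumeration.** `enumerateCandidateLoci()` pairs CRs whose inner
   gap lies in the 300–700 bp window — long enough to contain informative
   polymorphism, short enough for one Sanger read from each end. The window
   is enforced on **both** genomes and is inclusive at both bounds.
4. **Primer picking.** `buildTemplate()` concatenates the two CRs around a
   fixed 108 bp dummy spacer, `NNNN(AATT)₂₅NNNN`. The dummy replaces the
   divergent interval (whose target-species sequence is unknown) so that no
   primer can be placed there: its terminal Ns are unambiguous poison for
   any overlapping oligo, and its AT-only core is unusable as a primer
   site. `pickPrimerPairs()` then enumerates every candidate oligo inside
   the CR spans and keeps pairs meeting the hard constraints (length 18–27
   nt, Tm 57–63 °C, GC 20–80 %, mononucleotide runs ≤ 4, pairwise Tm
   difference ≤ 3 °C, self/cross complementarity limits), ranked by a
   penalty that sums each primer's deviation from the 60 °C / 20 nt optima.
5. **Specificity.** Each primer of each surviving pair is searched against
   both complete reference genomes (`searchGenome()`). A pair is kept only
   when every hit with expectation value E < 0.1 coincides with the site it
   was designed from, in both genomes (`screenPrimerPair()`).
6. **Interval identity.** The two reference IR sequences are globally
   aligned (`globalAlign()`), alignment columns containing N in either row
   are removed, and identity is the fraction of identical columns among
   those remaining (`identityAfterNRemoval()`). Gap columns stay in the
   denominator: an indel is divergence.
7. **Classification and selection.** The amplified span is classified as
   exonic, intronic or both on the anchor genome (`classifyLocus()`), and
   `selectCandidates()` applies the selection rules: identity within the
   75–90 % band (high enough for the primers to transfer, low enough for
   the target interval to be polymorphic), at most two loci per chromosome
   to spread markers across the genome, and a class round-robin so exonic
   and intronic markers are both represented.
8. **GO enrichment.** Finally `runEnrich()` asks whether the genes carrying
   designed primers are a biased functional sample: exact hypergeometric
   one-sided p-values per GO-slim term (the side chosen by whether the
   observed count is above or below its expectation), a resampled null mean
   and standard deviation giving a Z score, and Bonferroni adjustment with
   multiplicity equal to the number of tested terms in the same GO domain.
   The uninformative root term GO:0008150 is always excluded.

`runDesign()` chains stages 1–7 and records, per dropped locus, a
machine-readable rejection reason (`no-CR-pair`, `no-primer`,
`specificity-fail`, `band-fail`, `chromosome-quota`).

## Thermodynamics

Melting temperatures use the unified nearest-neighbor parameters of
SantaLucia (1998) with the entropic salt correction
0.368·(N−1)·ln[Na⁺], at 50 mM monovalent cation and 50 nM oligo
(`tmParameters()`). These concentrations are conventional for PCR primer
design; Tm has no meaning without them, so they are explicit and
configurable. Self-complementary oligos get the symmetry entropy correction
and the undiluted concentration term.

## E-value statistics

The specificity search computes exact best ungapped local alignments of
each (≤ 27 nt) primer against every diagonal of both strands of each
chromosome — at primer scale gapped alignment adds nothing, and an
exhaustive scan is cheap, deterministic, and cannot miss a hit the way a
word-seeded heuristic can. Scores (+1 match / −2 mismatch by default) are
converted to expectation values with the Karlin–Altschul formula
E = K·m·n·e^(−λS), with n the length of both strands of the searched
genome. λ is the positive root of Σ pᵢe^(λsᵢ) = 1 and K is evaluated from
the lattice-case series by convolving the partial-sum distribution; for the
default scheme this reproduces the published blastn constants
(λ ≈ 1.33, K ≈ 0.621). Because E-values are calibrated, roughly one search
in ten finds a *genuine* chance similarity below E = 0.1 somewhere in a
genome; the screen treating such loci as failures is the intended,
conservative behaviour.

## The synthetic data generator

`simulateReferencePair()` fabricates the statistical structure the method
assumes: orthologous unspliced genes with exon/intron architecture, two
planted CRs per gene flanking a divergent interval, genome B derived from
the common ancestor by per-base substitution (uniform choice among the
three alternatives), geometric-length intronic indels, optional N masking,
and optional decoy copies of a CR placed in intergenic space to exercise
the specificity screen. Everything is driven by one seed; identical seeds
give byte-identical files.

Default conditions (chosen once, as the realistic operating point of the
method, and used by the acceptance script):

* 20 genes on 4 chromosomes, one planted CR pair per gene, CR lengths
  25–40 bp; 10 genes get an in-window spacing (300–700 bp), 10 get an
  out-of-window spacing as negative controls.
* Substitution rates 0.10 (exon) and 0.22 (intron) scaled per gene by
  U(0.7, 1.4). These place interval identity in the 70–90 % range — the
  regime the method targets, where reference pairs are deeply diverged and
  20 bp of perfect identity is the exception, not the rule. Introns are
  more divergent than exons, as in real genomes.
* Intronic indels at 0.01 per base with mean length 2; N masking of genome
  A at 0.001 per base.

Three deliberate constructions make the ground truth exact rather than
probabilistic. First, the base adjacent to each planted CR is forced to
differ between the genomes (whenever any mutation occurs at all), so
planted CRs are maximal by construction and their coordinates can be
asserted exactly. Second, indels never touch the bases flanking a CR, so
planted boundaries survive in both genomes. Third, planted CR pairs are
rejection-sampled until they contain at least one (forward, reverse) oligo
combination that satisfies *every* picking constraint — the generator's
planted loci are, by definition, loci where design is supposed to succeed,
which is what makes "every planted locus yields a primer pair" a testable
claim rather than a coin flip.

What the generator does **not** emulate: paralogous gene families, repeat
elements, GC heterogeneity and mutation-rate autocorrelation along
chromosomes, codon structure within exons, and within-population
polymorphism of the target species (a wet-lab quantity outside this
package's scope). Passing tests therefore demonstrate algorithmic
correctness under the stated model, not PCR success rates on real genomes.

## Numerical and design choices

* All plain-integer coordinates in tables are 0-based half-open; GFF3
  (1-based closed) and BED (0-based half-open) are converted at the I/O
  boundary, and `GRanges` objects follow the Bioconductor convention.
  Gene sequences are handled in transcript orientation; genomic outputs
  are always plus-strand.
* Ambiguity codes other than N are rejected on load: perfect-identity
  semantics are undefined for them.
* The 300–700 bp window and the 75–90 % band are closed intervals; the
  interval constraint is applied on both genomes (the identity stage needs
  both IRs to exist at comparable scale).
* Global alignment uses match +5 / mismatch −4, gap open 10 / extend 0.5
  (a gap of length g costs 10 + 0.5·g), via `pairwiseAlignment`. A
  five-letter scoring matrix treats N as matching nothing, so unknown
  bases cannot attract the alignment; their columns are removed before
  identity is computed, while gap columns remain in the denominator (the
  most conservative readable definition of identity).
* Selection ties are broken deterministically: classes rotate in the fixed
  order exon → intron → both and, within a class, the smallest locus id
  wins. The whole pipeline is deterministic given its inputs; the only
  stochastic component is the resampled enrichment null, which is seeded.
* `resampleNull()` reconstructs the null mean and spread of per-term
  counts by drawing study-set-sized subsets without replacement; the
  reported p-values never depend on it (they are exact tail sums), the Z
  scores do. 10,000 replicates keep the Monte-Carlo error of the mean
  below a few percent of the SD.
* Per-gene-pair locus counts can explode combinatorially when divergence
  is low (every exon becomes one long CR chain); `designConfig()` exposes
  `maxLociPerPair` to bound such runs by keeping the loci with the longest
  flanking anchors. It is off (unlimited) by default because a cap can
  discard true loci.
* Problem sizes in the test-suite and acceptance runs (4–20 genes,
  kilobase-scale chromosomes) were chosen so that every stage — including
  the exhaustive specificity scan — runs in seconds to a couple of minutes
  while still exercising every code path; the algorithms themselves have
  no scale-specific assumptions.

## Known limitations

* The specificity model is ungapped and purely score-based; it does not
  model thermodynamic off-target annealing or gapped similarity, which can
  matter for primers at the long end of the allowed range.
* Identity is computed from a single optimal pairwise alignment;
  alternative co-optimal alignments could shift identity by a fraction of
  a percent.
* Classification follows the anchor genome's annotation only (the second
  genome's evidence is recorded but not voted), mirroring the one-class-
  per-locus reporting the workflow requires.
* Enrichment treats GO-slim annotations as flat labels; no graph
  propagation is attempted.

## A worked example

```{r example, eval = FALSE}
library(orthoprimer)

sim <- simulateReferencePair(simulationConfig(seed = 7), "simdir")
annA <- readGff3(sim$paths$gffA, readGenomeFasta(sim$paths$genomeA))
annB <- readGff3(sim$paths$gffB, readGenomeFasta(sim$paths$genomeB))
res <- runDesign(annA, annB, read.delim(sim$paths$orthologs),
                 outDir = "rundir")
show(res)
evaluateRecovery(res, sim$truth)
```

The README shows the numbers this prints and what they mean; the
`scripts/acceptance.R` entry point re-runs the same computation from
scratch and writes the headline quantities as JSON.
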