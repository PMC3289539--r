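#' Globally align the two reference interval regions
#'
#' Optimal global (Needleman-Wunsch) alignment via
#' \code{\link[Biostrings]{pairwiseAlignment}} under a DNA scoring scheme
#' of match +5 / mismatch -4, affine gaps costing
#' \code{gapOpen + gapExt * length}. N is treated as matching nothing so
#' alignment placement is not biased by unknown bases; N columns are dealt
#' with downstream by \code{\link{identityAfterNRemoval}}.
#'
#' @param irA,irB Non-empty interval-region sequences (A/C/G/T/N).
#' @param scoring List with \code{match}, \code{mismatch}, \code{gapOpen},
#'   \code{gapExt} (penalties as positive numbers).
#' @return List with gapped strings \code{alignedA}, \code{alignedB} and
#'   the alignment \code{score}.
#' @examples
#' globalAlign("ACGT", "AGT")
#' @export
globalAlign <- function(irA, irB,
                        scoring = list(match = 5, mismatch = -4,
                                       gapOpen = 10, gapExt = 0.5)) {
  irA <- .normalizeSeq(as.character(irA))
  irB <- .normalizeSeq(as.character(irB))
  if (nchar(irA) == 0L || nchar(irB) == 0L)
    stop("cannot align an empty sequence", call. = FALSE)
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat) <- scoring$match
  mat["N", ] <- scoring$mismatch
  mat[, "N"] <- scoring$mismatch
  aln <- Biostrings::pairwiseAlignment(
    irA, irB, type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExt)
  list(alignedA = as.character(Biostrings::alignedPattern(aln)),
       alignedB = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Percent identity of an alignment after removing N columns
#'
#' Columns containing an unknown base (N) in either row are removed, then
#' identity is the fraction of remaining columns where both rows carry the
#' same base. Gap columns stay in the denominator: an indel is divergence.
#'
#' @param alignedA,alignedB Gapped rows of equal length (from
#'   \code{\link{globalAlign}}).
#' @return A list: \code{columnsTotal}, \code{columnsRemovedN},
#'   \code{matches}, \code{identity} (fraction in [0,1]; \code{NA} with
#'   \code{defined = FALSE} when every column was removed).
#' @examples
#' identityAfterNRemoval("ACGT", "ACGA")$identity  # 0.75
#' @export
identityAfterNRemoval <- function(alignedA, alignedB) {
  a <- strsplit(toupper(alignedA), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(alignedB), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("alignment rows differ in length", call. = FALSE)
  hasN <- a == "N" | b == "N"
  keepA <- a[!hasN]; keepB <- b[!hasN]
  matches <- sum(keepA == keepB & keepA != "-")
  denom <- length(keepA)
  list(columnsTotal = length(a),
       columnsRemovedN = sum(hasN),
       matches = matches,
       identity = if (denom > 0L) matches / denom else NA_real_,
       defined = denom > 0L)
}

#' Classify a locus as exonic, intronic or both
#'
#' The amplified span (outer conserved-region edge to outer edge) is
#' projected onto the anchor genome and intersected with the gene's exon
#' annotation at base resolution: \code{exon} when every base is exonic,
#' \code{intron} when every base is intronic, \code{both} otherwise.
#'
#' @param chrom Chromosome of the amplified span on the anchor genome.
#' @param start,end Amplified span, 0-based half-open, genome coordinates.
#' @param annotation A \linkS4class{GenomeAnnotation} (anchor genome).
#' @return A list: \code{class} (\code{exon}/\code{intron}/\code{both}),
#'   \code{exonBases}, \code{intronBases}, \code{gene_id}.
#' @export
classifyLocus <- function(chrom, start, end, annotation) {
  genes <- geneModels(annotation)
  gs <- BiocGenerics::start(genes) - 1L  # 0-based
  ge <- BiocGenerics::end(genes)
  hit <- which(as.character(GenomeInfoDb::seqnames(genes)) == chrom &
               gs <= start & ge >= end)
  if (length(hit) == 0L)
    stop("amplified span [", start, ",", end, ") on ", chrom,
         " is not contained in any gene model", call. = FALSE)
  gid <- genes$gene_id[hit[1]]
  ex <- exonsByGene(annotation)[[gid]]
  exS <- BiocGenerics::start(ex) - 1L
  exE <- BiocGenerics::end(ex)
  exBases <- sum(pmax(0L, pmin(exE, end) - pmax(exS, start)))
  total <- end - start
  cls <- if (exBases == total) "exon"
  else if (exBases == 0L) "intron"
  else "both"
  list(class = cls, exonBases = exBases, intronBases = total - exBases,
       gene_id = gid)
}

#' Select candidate loci: identity band and chromosome balance
#'
#' Applies the candidate-selection rules: keep only loci whose interval
#' identity lies within the band (inclusive; high enough that primers
#' transfer to the target species, low enough that the target interval is
#' likely polymorphic), then take at most \code{perChromosome} loci per
#' anchor-genome chromosome, balancing exonic/intronic/both classes by
#' round-robin (class order exon, intron, both; within a class, smallest
#' locus id first). Fully deterministic.
#'
#' @param loci A data.frame/DataFrame with columns \code{locus_id},
#'   \code{chromosome}, \code{identity}, \code{class}.
#' @param band Length-2 numeric, inclusive identity band.
#' @param perChromosome Maximum loci kept per chromosome.
#' @return Character vector of selected locus ids.
#' @export
selectCandidates <- function(loci, band = c(0.75, 0.90),
                             perChromosome = 2L) {
  df <- as.data.frame(loci)
  if (nrow(df) == 0L) return(character(0))
  df <- df[!is.na(df$identity) &
           df$identity >= band[1] & df$identity <= band[2], , drop = FALSE]
  if (nrow(df) == 0L) return(character(0))
  sel <- character(0)
  for (chrom in sort(unique(df$chromosome))) {
    sub <- df[df$chromosome == chrom, , drop = FALSE]
    pools <- lapply(c("exon", "intron", "both"), function(cl) {
      sort(sub$locus_id[sub$class == cl])
    })
    taken <- character(0)
    while (length(taken) < perChromosome && any(lengths(pools) > 0L)) {
      for (i in seq_along(pools)) {
        if (length(taken) >= perChromosome) break
        if (length(pools[[i]]) == 0L) next
        taken <- c(taken, pools[[i]][1])
        pools[[i]] <- pools[[i]][-1]
      }
    }
    sel <- c(sel, taken)
  }
  sel
}

#' Histogram of interval identities
#'
#' Bins identity values over [0, 1] into half-open bins of width
#' \code{binWidth}; the last bin is closed so identity 1.0 is counted.
#'
#' @param identities Numeric vector of identity fractions.
#' @param binWidth Bin width (default 0.05).
#' @return A data.frame with \code{binStart}, \code{binEnd}, \code{count}.
#' @export
identityHistogram <- function(identities, binWidth = 0.05) {
  identities <- identities[!is.na(identities)]
  if (length(identities) == 0L)
    stop("no identity values to bin", call. = FALSE)
  if (any(identities < 0 | identities > 1))
    stop("identities must lie in [0, 1]", call. = FALSE)
  nb <- ceiling(1 / binWidth)
  idx <- pmin(floor(identities / binWidth) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  data.frame(binStart = (seq_len(nb) - 1L) * binWidth,
             binEnd = pmin(seq_len(nb) * binWidth, 1),
             count = counts)
}
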