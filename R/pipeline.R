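#' Configuration for a full design run
#'
#' Houses the pipeline constants: the 20 bp minimum conserved-region
#' length, the 300-700 bp interval window, the E < 0.1 specificity
#' threshold, and the 75-90\% identity selection band, together with the
#' primer-picking constraints and scoring schemes.
#'
#' @param minCrLen Minimum conserved-region length (bp).
#' @param interval Allowed interval-region length range (bp), inclusive.
#' @param constraints Primer constraints, \code{\link{primerConstraints}}.
#' @param searchScoring Match/mismatch scores for the specificity search.
#' @param evalueThreshold Specificity E-value threshold.
#' @param alignScoring Global-alignment scoring for interval identity.
#' @param band Inclusive identity selection band (fractions).
#' @param perChromosome Maximum selected loci per chromosome.
#' @param maxLociPerPair Optional cap on candidate loci carried forward
#'   per gene pair (default unlimited). When set and exceeded, loci are
#'   ranked by total flanking-CR length (longer anchors give better
#'   primer sites) and the excess is logged as \code{locus-cap}; useful
#'   for bounding very large runs, at the cost of possibly discarding
#'   true loci with short anchors.
#' @param goReps,seed Resampling replicates and seed for enrichment.
#' @return A configuration list.
#' @export
designConfig <- function(minCrLen = 20L, interval = c(300, 700),
                         constraints = primerConstraints(),
                         searchScoring = list(match = 1, mismatch = -2),
                         evalueThreshold = 0.1,
                         alignScoring = list(match = 5, mismatch = -4,
                                             gapOpen = 10, gapExt = 0.5),
                         band = c(0.75, 0.90), perChromosome = 2L,
                         maxLociPerPair = Inf,
                         goReps = 10000L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$minCrLen > 0, cfg$interval[1] <= cfg$interval[2],
            cfg$evalueThreshold > 0,
            cfg$band[1] >= 0, cfg$band[2] <= 1, cfg$band[1] <= cfg$band[2])
  cfg
}

# Project a strand-oriented gene-space interval (0-based half-open) onto
# plus-strand genome coordinates.
.geneToGenome <- function(annotation, geneId, start0, end0) {
  genes <- geneModels(annotation)
  i <- match(geneId, genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", geneId, call. = FALSE)
  gs <- BiocGenerics::start(genes)[i] - 1L  # 0-based gene start
  ge <- BiocGenerics::end(genes)[i]         # 0-based half-open gene end
  strand <- as.character(BiocGenerics::strand(genes))[i]
  if (strand == "-") {
    list(chrom = as.character(GenomeInfoDb::seqnames(genes))[i],
         start = ge - end0, end = ge - start0, strand = "-")
  } else {
    list(chrom = as.character(GenomeInfoDb::seqnames(genes))[i],
         start = gs + start0, end = gs + end0, strand = "+")
  }
}

#' Run the full primer-design pipeline
#'
#' Stages, in order: one-to-one ortholog filtering; conserved-region
#' detection within each orthologous unspliced gene pair; enumeration of
#' CR pairs flanking a 300-700 bp interval on both genes; dummy-template
#' construction and CR-confined primer picking; genome-wide specificity
#' screening of both primers in both genomes (E < 0.1, self-sites
#' excepted); global alignment of the two reference interval regions and
#' identity after N-column removal; exonic/intronic/both classification of
#' the amplified span on the anchor (A) genome; and chromosome-balanced
#' candidate selection within the identity band. Deterministic throughout.
#'
#' @param annA,annB \linkS4class{GenomeAnnotation} objects for the two
#'   reference species; species A is the anchor used for classification
#'   and chromosome assignment.
#' @param orthologTable Data.frame of (gene id A, gene id B, homology
#'   type) rows.
#' @param config From \code{\link{designConfig}}.
#' @param outDir Optional output directory; when given, the primer table
#'   (TSV), interval-region BED, conserved-region TSV, per-locus log TSV
#'   and a run manifest (JSON) are written there.
#' @return A \linkS4class{PrimerDesignResult}.
#' @export
runDesign <- function(annA, annB, orthologTable, config = designConfig(),
                      outDir = NULL) {
  pairs <- filterOrthologs(orthologTable)
  seqsA <- unsplicedSeqs(annA); seqsB <- unsplicedSeqs(annB)
  known <- pairs$gene_id_A %in% names(seqsA) &
    pairs$gene_id_B %in% names(seqsB)
  log <- data.frame(locus_id = character(0), gene_id_A = character(0),
                    reason = character(0))
  if (any(!known)) {
    log <- rbind(log, data.frame(
      locus_id = NA_character_, gene_id_A = pairs$gene_id_A[!known],
      reason = "gene-not-annotated"))
    pairs <- pairs[known, , drop = FALSE]
  }
  stats <- alignmentStats(config$searchScoring$match,
                          config$searchScoring$mismatch)

  crsAll <- list(); lociAll <- list()
  for (i in seq_len(nrow(pairs))) {
    gA <- pairs$gene_id_A[i]; gB <- pairs$gene_id_B[i]
    crs <- as.data.frame(findConservedRegions(
      as.character(seqsA[[gA]]), as.character(seqsB[[gB]]),
      config$minCrLen))
    if (nrow(crs)) {
      crs$gene_id_A <- gA; crs$gene_id_B <- gB
      crsAll[[length(crsAll) + 1L]] <- crs
    }
    loci <- as.data.frame(enumerateCandidateLoci(
      S4Vectors::DataFrame(crs), config$interval))
    if (nrow(loci) == 0L) {
      log <- rbind(log, data.frame(locus_id = NA_character_,
                                   gene_id_A = gA, reason = "no-CR-pair"))
      next
    }
    loci$gene_id_A <- gA; loci$gene_id_B <- gB
    loci$locus_id <- sprintf("%s|L%02d", gA, seq_len(nrow(loci)))
    if (nrow(loci) > config$maxLociPerPair) {
      anchor <- crs$length[loci$left] + crs$length[loci$right]
      keep <- order(-anchor, loci$irStartA)[seq_len(config$maxLociPerPair)]
      dropped <- setdiff(seq_len(nrow(loci)), keep)
      log <- rbind(log, data.frame(locus_id = loci$locus_id[dropped],
                                   gene_id_A = gA, reason = "locus-cap"))
      loci <- loci[sort(keep), , drop = FALSE]
    }
    loci$crLeftStartA <- crs$startA[loci$left]
    loci$crLeftEndA <- crs$endA[loci$left]
    loci$crRightStartA <- crs$startA[loci$right]
    loci$crRightEndA <- crs$endA[loci$right]
    loci$crLeftStartB <- crs$startB[loci$left]
    loci$crLeftEndB <- crs$endB[loci$left]
    loci$crRightStartB <- crs$startB[loci$right]
    loci$crRightEndB <- crs$endB[loci$right]
    loci$crLeftSeq <- crs$seq[loci$left]
    loci$crRightSeq <- crs$seq[loci$right]
    lociAll[[length(lociAll) + 1L]] <- loci
  }
  crsDf <- if (length(crsAll)) do.call(rbind, crsAll) else
    data.frame(startA = integer(0), endA = integer(0), startB = integer(0),
               endB = integer(0), length = integer(0), seq = character(0),
               gene_id_A = character(0), gene_id_B = character(0))
  lociDf <- if (length(lociAll)) do.call(rbind, lociAll) else NULL

  primers <- list()
  genomes <- list(A = genomeSeq(annA), B = genomeSeq(annB))
  genomeCodes <- list(A = .encodeGenome(genomes$A),
                      B = .encodeGenome(genomes$B))
  if (!is.null(lociDf)) {
    for (i in seq_len(nrow(lociDf))) {
      lc <- lociDf[i, ]
      tpl <- buildTemplate(lc$crLeftSeq, lc$crRightSeq)
      cand <- pickPrimerPairs(tpl, config$constraints)
      if (nrow(cand) == 0L) {
        log <- rbind(log, data.frame(locus_id = lc$locus_id,
                                     gene_id_A = lc$gene_id_A,
                                     reason = "no-primer"))
        next
      }
      best <- as.data.frame(cand[1, ])
      # gene-space binding sites (0-based): forward in the left CR,
      # reverse in the right CR (template right-CR span starts at
      # crLeftLen + 108)
      fOffL <- best$fStart - tpl$crLeftSpan[1]
      fLen <- best$fEnd - best$fStart
      rOffR <- best$rStart - tpl$crRightSpan[1]
      rLen <- best$rEnd - best$rStart
      fA <- c(lc$crLeftStartA + fOffL, lc$crLeftStartA + fOffL + fLen)
      rA <- c(lc$crRightStartA + rOffR, lc$crRightStartA + rOffR + rLen)
      fB <- c(lc$crLeftStartB + fOffL, lc$crLeftStartB + fOffL + fLen)
      rB <- c(lc$crRightStartB + rOffR, lc$crRightStartB + rOffR + rLen)
      selfA <- do.call(rbind, list(
        as.data.frame(.geneToGenome(annA, lc$gene_id_A, fA[1], fA[2])),
        as.data.frame(.geneToGenome(annA, lc$gene_id_A, rA[1], rA[2]))))
      selfB <- do.call(rbind, list(
        as.data.frame(.geneToGenome(annB, lc$gene_id_B, fB[1], fB[2])),
        as.data.frame(.geneToGenome(annB, lc$gene_id_B, rB[1], rB[2]))))
      verdict <- screenPrimerPair(
        best$forward, best$reverse, genomes,
        selfSites = list(A = selfA, B = selfB),
        evalueThreshold = config$evalueThreshold, stats = stats,
        genomeCodes = genomeCodes)
      if (!verdict$pass) {
        log <- rbind(log, data.frame(locus_id = lc$locus_id,
                                     gene_id_A = lc$gene_id_A,
                                     reason = "specificity-fail"))
      }
      # interval identity
      irA <- .sliceSeq(as.character(seqsA[[lc$gene_id_A]]),
                       lc$irStartA, lc$irEndA)
      irB <- .sliceSeq(as.character(seqsB[[lc$gene_id_B]]),
                       lc$irStartB, lc$irEndB)
      aln <- globalAlign(irA, irB, config$alignScoring)
      rec <- identityAfterNRemoval(aln$alignedA, aln$alignedB)
      # amplified span (outer primer edges) on the anchor genome
      ampA <- .geneToGenome(annA, lc$gene_id_A, fA[1], rA[2])
      cls <- classifyLocus(ampA$chrom, ampA$start, ampA$end, annA)
      irGen <- .geneToGenome(annA, lc$gene_id_A, lc$irStartA, lc$irEndA)
      prodA <- rA[2] - fA[1]
      prodB <- rB[2] - fB[1]
      primers[[length(primers) + 1L]] <- cbind(
        data.frame(locus_id = lc$locus_id, gene_id_A = lc$gene_id_A,
                   gene_id_B = lc$gene_id_B),
        best[, c("forward", "reverse", "tm_f", "tm_r", "gc_f", "gc_r",
                 "penalty")],
        data.frame(
          product_min = min(prodA, prodB),
          product_max = max(prodA, prodB),
          identity = rec$identity,
          identity_defined = rec$defined,
          class = cls$class,
          chromosome = ampA$chrom,
          ir_genome_start = irGen$start, ir_genome_end = irGen$end,
          amp_genome_start = ampA$start, amp_genome_end = ampA$end,
          fStartA = fA[1], fEndA = fA[2],
          rStartA = rA[1], rEndA = rA[2],
          irStartA = lc$irStartA, irEndA = lc$irEndA,
          irStartB = lc$irStartB, irEndB = lc$irEndB,
          specific = verdict$pass))
    }
  }
  primersDf <- if (length(primers)) do.call(rbind, primers) else
    data.frame(locus_id = character(0), gene_id_A = character(0),
               gene_id_B = character(0), forward = character(0),
               reverse = character(0), tm_f = numeric(0), tm_r = numeric(0),
               gc_f = numeric(0), gc_r = numeric(0), penalty = numeric(0),
               product_min = integer(0), product_max = integer(0),
               identity = numeric(0), identity_defined = logical(0),
               class = character(0), chromosome = character(0),
               ir_genome_start = integer(0), ir_genome_end = integer(0),
               amp_genome_start = integer(0), amp_genome_end = integer(0),
               specific = logical(0))

  eligible <- primersDf[primersDf$specific & primersDf$identity_defined, ,
                        drop = FALSE]
  selected <- selectCandidates(eligible, config$band, config$perChromosome)
  primersDf$selected <- primersDf$locus_id %in% selected
  inBand <- eligible$identity >= config$band[1] &
    eligible$identity <= config$band[2]
  if (any(!inBand)) {
    log <- rbind(log, data.frame(
      locus_id = eligible$locus_id[!inBand],
      gene_id_A = eligible$gene_id_A[!inBand], reason = "band-fail"))
  }
  quota <- inBand & !eligible$locus_id %in% selected
  if (any(quota)) {
    log <- rbind(log, data.frame(
      locus_id = eligible$locus_id[quota],
      gene_id_A = eligible$gene_id_A[quota], reason = "chromosome-quota"))
  }

  lociOut <- if (is.null(lociDf)) {
    data.frame(locus_id = character(0), gene_id_A = character(0),
               gene_id_B = character(0), irStartA = integer(0),
               irEndA = integer(0), irStartB = integer(0),
               irEndB = integer(0), irLenA = integer(0),
               irLenB = integer(0), overlapping = logical(0))
  } else {
    lociDf[, c("locus_id", "gene_id_A", "gene_id_B", "irStartA", "irEndA",
               "irStartB", "irEndB", "irLenA", "irLenB", "overlapping")]
  }
  result <- methods::new(
    "PrimerDesignResult",
    crs = S4Vectors::DataFrame(crsDf),
    loci = S4Vectors::DataFrame(lociOut),
    primers = S4Vectors::DataFrame(primersDf),
    log = S4Vectors::DataFrame(log),
    stageCounts = c(
      ortholog_pairs = nrow(pairs),
      pairs_with_cr = length(unique(crsDf$gene_id_A)),
      candidate_loci = if (is.null(lociDf)) 0L else nrow(lociDf),
      loci_with_primers = nrow(primersDf),
      specific_loci = sum(primersDf$specific),
      in_band_loci = if (nrow(eligible)) sum(inBand) else 0L,
      selected_loci = length(selected)),
    config = config)
  if (!is.null(outDir)) writeRunOutputs(result, outDir)
  result
}

#' Write the standard output files of a design run
#'
#' @param result A \linkS4class{PrimerDesignResult}.
#' @param outDir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
writeRunOutputs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(primers = file.path(outDir, "primer_table.tsv"),
             irs = file.path(outDir, "interval_regions.bed"),
             crs = file.path(outDir, "conserved_regions.tsv"),
             log = file.path(outDir, "design_log.tsv"),
             manifest = file.path(outDir, "manifest.json"))
  primers <- as.data.frame(primerTable(result))
  writePrimerTable(primers, paths[["primers"]])
  writeIrBed(primers, paths[["irs"]])
  utils::write.table(as.data.frame(conservedRegionTable(result)),
                     paths[["crs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(designLog(result)), paths[["log"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- result@config
  manifest <- list(
    package = "orthoprimer",
    version = as.character(utils::packageVersion("orthoprimer")),
    config = cfg,
    stageCounts = as.list(result@stageCounts))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' GO-slim enrichment of the genes carrying designed primers
#'
#' The study set is the anchor-species genes contributing at least one
#' selected primer pair (falling back to all specific primer-bearing genes
#' when \code{useSelected = FALSE}); the population is every gene with at
#' least one slim GO id.
#'
#' @param result A \linkS4class{PrimerDesignResult}.
#' @param gaf Parsed GAF annotation from \code{\link{readGaf}} (anchor
#'   species).
#' @param config From \code{\link{designConfig}} (supplies \code{goReps}
#'   and \code{seed}).
#' @param useSelected Use selected loci only (default) or all
#'   specificity-passing loci.
#' @return The enrichment table of \code{\link{enrichGoTerms}}.
#' @export
runEnrich <- function(result, gaf, config = designConfig(),
                      useSelected = TRUE) {
  primers <- as.data.frame(primerTable(result))
  rows <- if (useSelected) primers$selected else primers$specific
  studyAll <- unique(primers$gene_id_A[rows])
  population <- names(gaf$annotation)[lengths(gaf$annotation) > 0L]
  study <- intersect(studyAll, population)
  if (length(study) == 0L)
    stop("empty study set: no primer-bearing genes carry GO annotation; ",
         "run the design first or check the GAF inputs", call. = FALSE)
  enrichGoTerms(gaf$annotation, gaf$domains, study, population,
                reps = config$goReps, seed = config$seed)
}
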