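#' Configuration for the synthetic reference-pair simulator
#'
#' Defines the statistical structure the design method assumes: orthologous
#' unspliced genes that share perfectly identical conserved blocks
#' separated by divergent intervals, with introns more polymorphic than
#' exons. Genome B is derived from genome A's ancestor by seeded per-base
#' substitution (uniform choice among the three alternatives) and
#' geometric-length intronic indels applied outside the planted conserved
#' regions, which are copied verbatim. A per-gene divergence scale spreads
#' interval identities across the selection band. Every source of
#' randomness is fixed by \code{seed}.
#'
#' @param seed Integer seed fixing all randomness.
#' @param nGenes Number of orthologous gene pairs.
#' @param nChrom Number of chromosomes per genome.
#' @param crLenRange Planted conserved-region lengths (bp, >= 20).
#' @param spacingRange Range the planted CR-pair spacing is drawn from
#'   (bp) for in-window genes; matches the design window so those planted
#'   loci are recoverable candidates.
#' @param inWindowGenes How many genes get an in-window spacing; the
#'   remaining genes draw their spacing from \code{offSpacingRanges} and
#'   act as negative controls for the interval filter.
#' @param offSpacingRanges List of two ranges (below and above the design
#'   window) for the out-of-window genes.
#' @param exonRate,intronRate Baseline per-base substitution probabilities
#'   outside CRs (exonic < intronic, as in real genomes; defaults place
#'   interval identity in the 70-90 percent range typical of the deeply
#'   diverged reference pairs this design strategy is used with).
#' @param rateScaleRange Per-gene multiplier on both rates, drawn
#'   uniformly; spreads interval identity across loci.
#' @param indelRate Per-base intronic indel probability outside CRs.
#' @param indelMeanLen Mean indel length (geometric).
#' @param nRate Per-base probability of masking a genome-A base to N
#'   outside CRs (exercises N-column removal).
#' @param flankRange Gene padding before the first and after the second
#'   planted CR (bp).
#' @param decoyFraction Fraction of genes whose left CR is also copied
#'   into intergenic space elsewhere in genome A, creating an off-target
#'   site the specificity screen must catch.
#' @param nGoTermsPerDomain GO-slim catalogue size per domain.
#' @param goDensity Mean number of slim terms per gene (Poisson).
#' @param minusStrandEvery Every k-th gene is placed on the minus strand.
#' @param orthologNoise Number of one2many decoy rows added to the
#'   ortholog table.
#' @return A configuration list for
#'   \code{\link{simulateReferencePair}}.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 20L, nChrom = 4L,
                             crLenRange = c(25L, 40L),
                             spacingRange = c(300L, 700L),
                             inWindowGenes = 10L,
                             offSpacingRanges = list(c(150L, 280L),
                                                     c(720L, 900L)),
                             exonRate = 0.10, intronRate = 0.22,
                             rateScaleRange = c(0.7, 1.4),
                             indelRate = 0.01, indelMeanLen = 2,
                             nRate = 0.001,
                             flankRange = c(150L, 400L),
                             decoyFraction = 0,
                             nGoTermsPerDomain = 5L, goDensity = 2,
                             minusStrandEvery = 5L,
                             orthologNoise = 2L) {
  cfg <- as.list(environment())
  if (any(cfg$crLenRange < 20L))
    stop("planted CR lengths must be >= 20 bp", call. = FALSE)
  rates <- c(exonRate, intronRate, indelRate, nRate, decoyFraction)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  cfg
}

# Segment a gene of length L into alternating exon/intron blocks
# (exon first and last). Returns 0-based half-open exon intervals.
.segmentGene <- function(L, nExons) {
  nSeg <- 2L * nExons - 1L
  cuts <- sort(sample(seq_len(L - 1L), nSeg - 1L))
  bounds <- c(0L, cuts, L)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  exon <- seq_len(nSeg) %% 2L == 1L
  cbind(start = starts[exon], end = ends[exon])
}

.randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform draw from lo..hi, safe for degenerate ranges (unlike sample())
.sampleRange <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Oligos (up to `limit`) from 18-27 nt windows of `seq` that satisfy the
# default primer hard constraints, with Tm inside a band placed centrally
# in the 57-63 degC picking window (so any two such sites also satisfy
# the 3 degC pairwise Tm-difference constraint). For the right conserved
# region the primer is the reverse complement of the window it binds.
.primerSites <- function(seq, reverse = FALSE, tmWindow = c(58.5, 61.5),
                         limit = 5L) {
  n <- nchar(seq)
  found <- character(0)
  for (L in 18:min(27L, n)) {
    starts <- seq_len(n - L + 1L)
    subs <- substring(seq, starts, starts + L - 1L)
    gc <- .gcPercent(subs)
    subs <- subs[gc >= 30 & gc <= 70]
    if (!length(subs)) next
    subs <- subs[.maxHomopolymerRun(subs) <= 4L]
    if (!length(subs)) next
    tm <- vapply(subs, meltingTemperature, numeric(1))
    subs <- subs[tm >= tmWindow[1] & tm <= tmWindow[2]]
    for (w in subs) {
      oligo <- if (reverse) .revComp(w) else w
      if (.complScore(oligo, oligo) <= 8 &&
          .complScore(oligo, oligo, anchor3p = TRUE) <= 3) {
        found <- c(found, oligo)
        if (length(found) >= limit) return(found)
      }
    }
  }
  found
}

# Planted conserved-region pairs are rejection-sampled until at least one
# (forward, reverse) combination passes every hard picking constraint:
# the simulator's ground-truth loci are loci where primer design succeeds
# by construction.
.plantableCRPair <- function(lenL, lenR, maxTry = 500L) {
  for (t in seq_len(maxTry)) {
    crL <- .randomSeq(lenL)
    fw <- .primerSites(crL, reverse = FALSE)
    if (!length(fw)) next
    crR <- .randomSeq(lenR)
    rv <- .primerSites(crR, reverse = TRUE)
    if (!length(rv)) next
    for (f in fw) {
      for (r in rv) {
        if (.complScore(f, r) <= 8 &&
            max(.complScore(f, r, TRUE), .complScore(r, f, TRUE)) <= 3) {
          return(c(crL, crR))
        }
      }
    }
  }
  stop("could not construct a primer-compatible conserved-region pair (",
       lenL, "/", lenR, " bp)", call. = FALSE)
}

.mutateBase <- function(base) {
  alt <- setdiff(c("A", "C", "G", "T"), base)
  alt[sample.int(3L, 1L)]
}

# Evolve gene B from the ancestor: substitutions at rate[i] per base,
# intronic indels, planted CRs copied verbatim. Indels are kept away from
# the bases immediately flanking a CR so that planted CR boundaries stay
# exact in both genomes. Returns the B sequence and a monotone map from A
# boundaries (0-based, length L+1) to B positions.
.evolveGene <- function(anc, rate, isIntron, inCR, indelRate, indelMeanLen) {
  L <- length(anc)
  protected <- inCR | c(FALSE, inCR[-L]) | c(inCR[-1], FALSE)
  out <- character(L + 16L)
  nOut <- 0L
  map <- integer(L + 1L)
  i <- 1L
  while (i <= L) {
    map[i] <- nOut
    if (inCR[i]) {
      nOut <- nOut + 1L
      if (nOut > length(out)) out <- c(out, character(L))
      out[nOut] <- anc[i]
      i <- i + 1L
      next
    }
    if (isIntron[i] && !protected[i] && indelRate > 0 &&
        stats::runif(1) < indelRate) {
      len <- 1L + stats::rgeom(1, 1 / indelMeanLen)
      if (stats::runif(1) < 0.5) {
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        while (nOut + len > length(out)) out <- c(out, character(L))
        out[nOut + seq_len(len)] <- ins
        nOut <- nOut + len
      } else {
        # deletion: skip up to len bases, never into or next to a CR
        j <- i
        while (j <= L && !protected[j] && j - i < len) {
          map[j] <- nOut
          j <- j + 1L
        }
        i <- j
        next
      }
    }
    b <- anc[i]
    if (stats::runif(1) < rate[i]) b <- .mutateBase(b)
    nOut <- nOut + 1L
    if (nOut > length(out)) out <- c(out, character(L))
    out[nOut] <- b
    i <- i + 1L
  }
  map[L + 1L] <- nOut
  list(seq = out[seq_len(nOut)], map = map)
}

#' Simulate an orthologous reference-genome pair with ground truth
#'
#' Writes a complete, file-based study instance: two genome FASTAs, two
#' GFF3 annotations, a one-to-one ortholog table (with one2many decoy
#' rows), two GAF annotation files, a GO-slim term list, and a JSON ground
#' truth. Each gene carries two planted conserved regions flanking a
#' divergent interval; outside the CRs genome B accumulates seeded
#' substitutions and intronic indels. The base immediately adjacent to
#' each planted CR end is forced to differ between the genomes (when any
#' substitution occurs at all) so that planted CRs are maximal by
#' construction and ground-truth coordinates are exact.
#'
#' @param config From \code{\link{simulationConfig}}.
#' @param outDir Output directory (created if missing).
#' @return Invisibly, a list with \code{paths} (named file paths) and
#'   \code{truth} (planted CR and locus coordinates, decoy sites, per-gene
#'   expected divergence, GO annotations).
#' @export
simulateReferencePair <- function(config = simulationConfig(),
                                  outDir = tempfile("simpair")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(config$seed, .simulateImpl(config, outDir))
}

.simulateImpl <- function(config, outDir) {
  nG <- config$nGenes
  genes <- vector("list", nG)
  mutating <- config$exonRate > 0 || config$intronRate > 0 ||
    config$indelRate > 0

  for (i in seq_len(nG)) {
    crLen <- .sampleRange(config$crLenRange[1], config$crLenRange[2], 2L)
    spacing <- if (i <= config$inWindowGenes) {
      .sampleRange(config$spacingRange[1], config$spacingRange[2])
    } else {
      rg <- config$offSpacingRanges[[sample.int(2L, 1L)]]
      .sampleRange(rg[1], rg[2])
    }
    pad <- .sampleRange(config$flankRange[1], config$flankRange[2], 2L)
    L <- pad[1] + crLen[1] + spacing + crLen[2] + pad[2]
    cr1 <- c(pad[1], pad[1] + crLen[1])
    cr2 <- c(cr1[2] + spacing, cr1[2] + spacing + crLen[2])
    exons <- .segmentGene(L, sample(2:4, 1L))
    isExon <- logical(L)
    for (r in seq_len(nrow(exons)))
      isExon[(exons[r, 1] + 1L):exons[r, 2]] <- TRUE
    inCR <- logical(L)
    inCR[(cr1[1] + 1L):cr1[2]] <- TRUE
    inCR[(cr2[1] + 1L):cr2[2]] <- TRUE
    anc <- strsplit(.randomSeq(L), "", fixed = TRUE)[[1]]
    crPair <- .plantableCRPair(crLen[1], crLen[2])
    anc[(cr1[1] + 1L):cr1[2]] <- strsplit(crPair[1], "", fixed = TRUE)[[1]]
    anc[(cr2[1] + 1L):cr2[2]] <- strsplit(crPair[2], "", fixed = TRUE)[[1]]
    scale <- stats::runif(1, config$rateScaleRange[1],
                          config$rateScaleRange[2])
    rate <- ifelse(isExon, config$exonRate, config$intronRate) * scale
    rate[inCR] <- 0
    ev <- .evolveGene(anc, rate, !isExon, inCR,
                      config$indelRate, config$indelMeanLen)
    bseq <- ev$seq
    # force maximality of planted CRs at their boundaries
    if (mutating) {
      for (pos0 in c(cr1[1] - 1L, cr2[1] - 1L)) {  # base before each CR
        if (pos0 >= 0L) {
          bp <- ev$map[pos0 + 1L] + 1L
          if (bp >= 1L && bp <= length(bseq) && bseq[bp] == anc[pos0 + 1L])
            bseq[bp] <- .mutateBase(anc[pos0 + 1L])
        }
      }
      for (pos0 in c(cr1[2], cr2[2])) {  # base just after each CR
        if (pos0 < L) {
          bp <- ev$map[pos0 + 1L] + 1L
          if (bp >= 1L && bp <= length(bseq) && bseq[bp] == anc[pos0 + 1L])
            bseq[bp] <- .mutateBase(anc[pos0 + 1L])
        }
      }
    }
    aseq <- anc
    if (config$nRate > 0) {
      mask <- stats::runif(L) < config$nRate & !inCR
      aseq[mask] <- "N"
    }
    crB1 <- c(ev$map[cr1[1] + 1L], ev$map[cr1[2] + 1L])
    crB2 <- c(ev$map[cr2[1] + 1L], ev$map[cr2[2] + 1L])
    exonsB <- cbind(start = ev$map[exons[, 1] + 1L],
                    end = ev$map[exons[, 2] + 1L])
    genes[[i]] <- list(
      idA = sprintf("geneA_%02d", i), idB = sprintf("geneB_%02d", i),
      seqA = paste(aseq, collapse = ""), seqB = paste(bseq, collapse = ""),
      exonsA = exons, exonsB = exonsB,
      crA = rbind(cr1, cr2), crB = rbind(crB1, crB2),
      spacingA = spacing, spacingB = crB2[1] - crB1[2],
      divergence = mean(rate[!inCR]),
      crSeq1 = paste(anc[(cr1[1] + 1L):cr1[2]], collapse = ""),
      strand = if (i %% config$minusStrandEvery == 0L) "-" else "+")
  }

  # assemble genomes; record intergenic spacers for decoy placement
  buildGenome <- function(which) {
    chromSeqs <- stats::setNames(rep("", config$nChrom),
                                 sprintf("chr%d", seq_len(config$nChrom)))
    placement <- list()
    spacers <- list()
    for (i in seq_len(nG)) {
      g <- genes[[i]]
      chrom <- sprintf("chr%d", ((i - 1L) %% config$nChrom) + 1L)
      sp <- .randomSeq(sample(300:500, 1L))
      spStart <- nchar(chromSeqs[[chrom]])
      chromSeqs[[chrom]] <- paste0(chromSeqs[[chrom]], sp)
      spacers[[length(spacers) + 1L]] <- data.frame(
        chrom = chrom, start = spStart,
        end = spStart + nchar(sp))
      seq <- if (which == "A") g$seqA else g$seqB
      oriented <- if (g$strand == "-") .revComp(seq) else seq
      gStart <- nchar(chromSeqs[[chrom]])
      chromSeqs[[chrom]] <- paste0(chromSeqs[[chrom]], oriented)
      placement[[i]] <- data.frame(
        gene = if (which == "A") g$idA else g$idB, chrom = chrom,
        start = gStart, end = gStart + nchar(seq), strand = g$strand)
    }
    for (chrom in names(chromSeqs)) {
      tail <- .randomSeq(sample(300:500, 1L))
      chromSeqs[[chrom]] <- paste0(chromSeqs[[chrom]], tail)
    }
    list(seqs = chromSeqs, placement = do.call(rbind, placement),
         spacers = do.call(rbind, spacers))
  }
  gA <- buildGenome("A")
  gB <- buildGenome("B")

  # decoys: duplicate the left CR of chosen genes into a spacer of genome A
  decoys <- data.frame(gene_id_A = character(0), chrom = character(0),
                       start = integer(0), end = integer(0))
  nDecoy <- floor(config$decoyFraction * nG)
  if (nDecoy > 0L) {
    pick <- sample.int(nG, nDecoy)
    # one spacer per decoy so copies never overwrite each other
    spacerOrder <- sample.int(nrow(gA$spacers))
    for (di in seq_along(pick)) {
      i <- pick[di]
      g <- genes[[i]]
      crSeq <- g$crSeq1
      row <- gA$spacers[spacerOrder[di], ]
      if (nchar(crSeq) > row$end - row$start) next
      pos <- row$start  # 0-based in chromosome
      s <- gA$seqs[[row$chrom]]
      gA$seqs[[row$chrom]] <- paste0(
        substr(s, 1L, pos), crSeq,
        substr(s, pos + nchar(crSeq) + 1L, nchar(s)))
      decoys <- rbind(decoys, data.frame(
        gene_id_A = g$idA, chrom = row$chrom, start = pos,
        end = pos + nchar(crSeq)))
    }
  }

  # GO catalogue and annotations (shared across the orthologous pair)
  domains <- c("biological_process", "molecular_function",
               "cellular_component")
  aspects <- c(biological_process = "P", molecular_function = "F",
               cellular_component = "C")
  terms <- sprintf("GO:%07d", seq_len(3L * config$nGoTermsPerDomain))
  termDomain <- stats::setNames(rep(domains, each = config$nGoTermsPerDomain),
                                terms)
  goAnn <- lapply(seq_len(nG), function(i) {
    k <- min(stats::rpois(1, config$goDensity), length(terms))
    sort(sample(terms, k))
  })
  hasRoot <- stats::runif(nG) < 0.3

  # ---- write files ----
  paths <- list(
    genomeA = file.path(outDir, "genomeA.fa"),
    genomeB = file.path(outDir, "genomeB.fa"),
    gffA = file.path(outDir, "genesA.gff3"),
    gffB = file.path(outDir, "genesB.gff3"),
    orthologs = file.path(outDir, "orthologs.tsv"),
    gafA = file.path(outDir, "speciesA.gaf"),
    gafB = file.path(outDir, "speciesB.gaf"),
    slim = file.path(outDir, "goslim.txt"),
    truth = file.path(outDir, "truth.json"))

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gA$seqs),
                              paths$genomeA)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gB$seqs),
                              paths$genomeB)

  writeGff <- function(build, which, path) {
    lines <- "##gff-version 3"
    for (i in seq_len(nG)) {
      g <- genes[[i]]
      pl <- build$placement[i, ]
      gid <- pl$gene
      lines <- c(lines, sprintf(
        "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
        pl$chrom, pl$start + 1L, pl$end, pl$strand, gid))
      ex <- if (which == "A") g$exonsA else g$exonsB
      for (r in seq_len(nrow(ex))) {
        if (pl$strand == "+") {
          s <- pl$start + ex[r, 1] + 1L; e <- pl$start + ex[r, 2]
        } else {
          s <- pl$end - ex[r, 2] + 1L; e <- pl$end - ex[r, 1]
        }
        lines <- c(lines, sprintf(
          "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          pl$chrom, s, e, pl$strand, gid, r, gid))
      }
    }
    writeLines(lines, path)
  }
  writeGff(gA, "A", paths$gffA)
  writeGff(gB, "B", paths$gffB)

  orth <- data.frame(
    gene_id_A = vapply(genes, `[[`, character(1), "idA"),
    gene_id_B = vapply(genes, `[[`, character(1), "idB"),
    homology_type = "one2one")
  if (config$orthologNoise > 0L) {
    noisy <- sample.int(nG, min(config$orthologNoise, nG))
    orth <- rbind(orth, data.frame(
      gene_id_A = orth$gene_id_A[noisy],
      gene_id_B = sprintf("paralogB_%02d", seq_along(noisy)),
      homology_type = "one2many"))
  }
  utils::write.table(orth, paths$orthologs, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  writeGaf <- function(ids, path) {
    rows <- character(0)
    for (i in seq_len(nG)) {
      tset <- goAnn[[i]]
      if (hasRoot[i]) tset <- c(tset, "GO:0008150")
      for (tm in tset) {
        asp <- if (tm == "GO:0008150") "P" else aspects[[termDomain[[tm]]]]
        rows <- c(rows, paste(
          "SIM", ids[i], ids[i], "", tm, "SIM:1", "IEA", "", asp,
          "", "", "protein", "taxon:0", "20100101", "SIM", sep = "\t"))
      }
    }
    writeLines(c("!gaf-version: 2.1", rows), path)
  }
  writeGaf(orth$gene_id_A[seq_len(nG)], paths$gafA)
  writeGaf(orth$gene_id_B[seq_len(nG)], paths$gafB)
  writeLines(c(terms, "GO:0008150"), paths$slim)

  planted <- do.call(rbind, lapply(seq_len(nG), function(i) {
    g <- genes[[i]]
    data.frame(
      gene_id_A = g$idA, gene_id_B = g$idB,
      cr1StartA = g$crA[1, 1], cr1EndA = g$crA[1, 2],
      cr2StartA = g$crA[2, 1], cr2EndA = g$crA[2, 2],
      cr1StartB = g$crB[1, 1], cr1EndB = g$crB[1, 2],
      cr2StartB = g$crB[2, 1], cr2EndB = g$crB[2, 2],
      irLenA = g$spacingA, irLenB = g$spacingB,
      divergence = g$divergence, strand = g$strand,
      inWindow = g$spacingA >= 300 & g$spacingA <= 700 &
        g$spacingB >= 300 & g$spacingB <= 700)
  }))
  truth <- list(
    planted = planted,
    decoys = decoys,
    goAnnotation = stats::setNames(goAnn, planted$gene_id_A),
    config = config)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(paths = paths, truth = truth))
}

#' Score pipeline output against the simulator's ground truth
#'
#' Per-stage recall/precision of a \code{\link{runDesign}} run on files
#' from \code{\link{simulateReferencePair}}.
#'
#' @param result A \linkS4class{PrimerDesignResult}.
#' @param truth The \code{truth} element returned by
#'   \code{\link{simulateReferencePair}}.
#' @return A list: \code{crRecall} (planted CRs recovered, by containment
#'   of the planted A- and B-intervals within a detected CR of the same
#'   gene pair), \code{locusRecall} (planted in-window loci whose interval
#'   region is enumerated exactly), \code{primerFeasibility} (fraction of
#'   recovered loci with a designed pair), \code{specificityPassDecoy} and
#'   \code{specificityPassClean} (pass rates for decoy-bearing and clean
#'   genes), and \code{identityDivergenceCor} (Spearman correlation of
#'   measured identity with planted divergence; expected negative).
#' @export
evaluateRecovery <- function(result, truth) {
  crs <- as.data.frame(conservedRegionTable(result))
  loci <- as.data.frame(candidateLoci(result))
  primers <- as.data.frame(primerTable(result))
  pl <- truth$planted

  crHit <- function(gA, s, e, sB, eB) {
    any(crs$gene_id_A == gA & crs$startA <= s & crs$endA >= e &
        crs$startB <= sB & crs$endB >= eB)
  }
  rec1 <- mapply(crHit, pl$gene_id_A, pl$cr1StartA, pl$cr1EndA,
                 pl$cr1StartB, pl$cr1EndB)
  rec2 <- mapply(crHit, pl$gene_id_A, pl$cr2StartA, pl$cr2EndA,
                 pl$cr2StartB, pl$cr2EndB)
  crRecall <- mean(c(rec1, rec2))

  inw <- pl[pl$inWindow, , drop = FALSE]
  locHit <- vapply(seq_len(nrow(inw)), function(i) {
    any(loci$gene_id_A == inw$gene_id_A[i] &
        loci$irStartA == inw$cr1EndA[i] &
        loci$irEndA == inw$cr2StartA[i])
  }, logical(1))
  locusRecall <- if (nrow(inw)) mean(locHit) else NA_real_

  recLoci <- loci[paste(loci$gene_id_A, loci$irStartA, loci$irEndA) %in%
                  paste(inw$gene_id_A, inw$cr1EndA, inw$cr2StartA), ,
                  drop = FALSE]
  feas <- if (nrow(recLoci)) {
    mean(recLoci$locus_id %in% primers$locus_id)
  } else NA_real_

  decoyGenes <- unique(truth$decoys$gene_id_A)
  passDecoy <- if (length(decoyGenes) && nrow(primers)) {
    mean(primers$specific[primers$gene_id_A %in% decoyGenes])
  } else NA_real_
  passClean <- if (nrow(primers)) {
    p <- primers[!primers$gene_id_A %in% decoyGenes, , drop = FALSE]
    if (nrow(p)) mean(p$specific) else NA_real_
  } else NA_real_

  idcor <- NA_real_
  if (nrow(primers) && sum(!is.na(primers$identity)) >= 3L) {
    dv <- pl$divergence[match(primers$gene_id_A, pl$gene_id_A)]
    idcor <- suppressWarnings(
      stats::cor(primers$identity, dv, method = "spearman",
                 use = "complete.obs"))
  }

  list(crRecall = crRecall, locusRecall = locusRecall,
       primerFeasibility = feas,
       specificityPassDecoy = passDecoy,
       specificityPassClean = passClean,
       identityDivergenceCor = idcor)
}
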