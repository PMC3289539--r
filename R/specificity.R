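#' Karlin-Altschul statistics for an ungapped match/mismatch scheme
#'
#' Computes lambda, K and H numerically for local ungapped alignment of
#' nucleotide sequences under a uniform base composition. lambda is the
#' positive root of \code{sum(p_s * exp(lambda * s)) = 1}; K is evaluated
#' with the Karlin-Altschul lattice-case series, convolving the score
#' distribution of partial sums until the correction term converges.
#'
#' @param match,mismatch Match reward (> 0) and mismatch penalty (< 0).
#' @param maxIter Number of convolution terms in the K series.
#' @return List with \code{lambda}, \code{K}, \code{H}, \code{match},
#'   \code{mismatch}.
#' @examples
#' s <- alignmentStats()  # +1/-2: lambda ~ 1.33, K ~ 0.62
#' @export
alignmentStats <- function(match = 1, mismatch = -2, maxIter = 80L) {
  if (match <= 0 || mismatch >= 0)
    stop("need match > 0 and mismatch < 0", call. = FALSE)
  pMatch <- 0.25
  scores <- c(match, mismatch)
  probs <- c(pMatch, 1 - pMatch)
  if (sum(scores * probs) >= 0)
    stop("expected score must be negative for local statistics",
         call. = FALSE)
  f <- function(l) sum(probs * exp(l * scores)) - 1
  lambda <- stats::uniroot(f, c(1e-6, 20), tol = 1e-12)$root
  q <- probs * exp(lambda * scores)
  H <- lambda * sum(q * scores)

  # lattice span of the score set
  d <- Reduce(function(a, b) {
    while (b) { t <- b; b <- a %% b; a <- t }; a
  }, abs(scores))

  # distribution of S_k (sum of k i.i.d. scores) by convolution; sigma
  # accumulates sum_k (1/k) [ P(S_k >= 0) + E(exp(lambda S_k); S_k < 0) ]
  lo <- min(scores); hi <- max(scores)
  dist <- c(1)  # P(S_0 = 0)
  offset <- 0L
  sigma <- 0
  step <- numeric(hi - lo + 1)
  step[scores - lo + 1] <- probs
  for (k in seq_len(maxIter)) {
    dist <- stats::convolve(dist, rev(step), type = "open")
    dist[dist < 0] <- 0
    offset <- offset + lo
    vals <- offset + seq_along(dist) - 1L
    neg <- vals < 0
    term <- sum(dist[!neg]) + sum(dist[neg] * exp(lambda * vals[neg]))
    sigma <- sigma + term / k
    if (term / k < 1e-12) break
  }
  K <- (d * lambda * exp(-2 * sigma)) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H, match = match, mismatch = mismatch)
}

#' Expectation value of a local alignment score
#'
#' \code{E = K * m * n * exp(-lambda * S)} with \code{m} the query length
#' and \code{n} the database size (both strands of the searched genome).
#'
#' @param score Alignment score.
#' @param m Query length (bp).
#' @param n Database size (bp).
#' @param stats From \code{\link{alignmentStats}}.
#' @return The E-value.
#' @export
evalueOf <- function(score, m, n, stats) {
  stats$K * m * n * exp(-stats$lambda * score)
}

# Integer encoding of sequences for the diagonal scan: A/C/G/T -> 1..4,
# N and anything else -> 0, which never matches.
.encodeSeq <- function(x) {
  v <- utf8ToInt(x)
  code <- integer(128L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[v]
}

.encodeGenome <- function(genome) {
  seqs <- as.character(genome)
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  lapply(seqs, .encodeSeq)
}

# Exact best ungapped local alignment of a short query against one strand
# of one chromosome: per-diagonal Kadane over query positions (compiled
# kernel). Returns the best segment per diagonal with score >= minScore,
# coordinates 0-based half-open on the subject's plus strand.
.diagonalHits <- function(qcode, subjCode, match, mismatch, minScore) {
  h <- .diagonalHitsCpp(qcode, subjCode, match, mismatch, minScore)
  if (nrow(h) == 0L) NULL else h
}

#' Search a genome for local matches to a primer sequence
#'
#' Exact ungapped local alignment of the query against both strands of
#' every chromosome (best-scoring segment per diagonal), scored with the
#' configured match/mismatch scheme. For primer-length queries gaps are
#' irrelevant, so this is a deterministic, exhaustive stand-in for a
#' word-seeded search: no hit above threshold can be missed. Hits are
#' reported when their E-value is below \code{eValueCeiling}.
#'
#' @param query Primer sequence (character, >= \code{minQueryLen} nt).
#' @param genome A \link[Biostrings]{DNAStringSet} of chromosomes.
#' @param stats From \code{\link{alignmentStats}}.
#' @param eValueCeiling Report ceiling for hits.
#' @param minQueryLen Shortest query accepted.
#' @param dbSize Database size n; defaults to both strands of
#'   \code{genome}. Supply to keep E-values comparable across partial
#'   searches.
#' @param genomeCode Optional precomputed integer encoding of
#'   \code{genome} (internal cache used by \code{\link{runDesign}} to
#'   avoid re-encoding across many queries).
#' @return A \link[S4Vectors]{DataFrame}: \code{chrom}, \code{strand},
#'   \code{score}, \code{evalue}, query and subject spans (0-based
#'   half-open; subject coordinates always on the plus strand).
#' @export
searchGenome <- function(query, genome, stats = alignmentStats(),
                         eValueCeiling = 10, minQueryLen = 11L,
                         dbSize = NULL, genomeCode = NULL) {
  if (is.null(genomeCode)) genomeCode <- .encodeGenome(genome)
  h <- .searchGenomeRaw(query, genomeCode, stats, eValueCeiling,
                        minQueryLen, dbSize)
  S4Vectors::DataFrame(h)
}

# Plain data.frame search path shared by searchGenome and the per-locus
# screening loop (avoids repeated S4 container construction).
.searchGenomeRaw <- function(query, genomeCode, stats, eValueCeiling,
                             minQueryLen = 11L, dbSize = NULL) {
  query <- .normalizeSeq(as.character(query))
  m <- nchar(query)
  if (m < minQueryLen)
    stop("query shorter than minimum query length (", minQueryLen, ")",
         call. = FALSE)
  n <- if (is.null(dbSize)) 2 * sum(lengths(genomeCode)) else dbSize
  minScore <- if (eValueCeiling <= 0) Inf else
    max(1, ceiling(log(stats$K * m * n / eValueCeiling) / stats$lambda))
  qf <- .encodeSeq(query)
  qr <- .encodeSeq(.revComp(query))
  out <- list()
  for (chrom in names(genomeCode)) {
    subj <- genomeCode[[chrom]]
    for (strand in c("+", "-")) {
      qch <- if (strand == "+") qf else qr
      h <- .diagonalHits(qch, subj, stats$match, stats$mismatch, minScore)
      if (is.null(h)) next
      if (strand == "-") {
        # report query span in original 5'->3' coordinates
        tmp <- h$qStart
        h$qStart <- m - h$qEnd
        h$qEnd <- m - tmp
      }
      h$chrom <- chrom
      h$strand <- strand
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      chrom = character(0), strand = character(0), score = numeric(0),
      evalue = numeric(0), qStart = integer(0), qEnd = integer(0),
      sStart = integer(0), sEnd = integer(0)))
  }
  h <- do.call(rbind, out)
  h$evalue <- evalueOf(h$score, m, n, stats)
  h <- h[h$evalue < eValueCeiling, , drop = FALSE]
  h <- h[order(h$evalue, h$chrom, h$sStart), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("chrom", "strand", "score", "evalue", "qStart", "qEnd",
        "sStart", "sEnd")]
}

#' Screen a primer pair for genome-wide specificity
#'
#' A pair passes when, in \emph{both} reference genomes, every hit with
#' E-value below the threshold coincides with a self-site: the genomic
#' projection of the conserved region the primer was designed from. A hit
#' counts as self when it overlaps the projected interval by at least one
#' base (coordinate jitter from extension must not cause false failures).
#'
#' @param forward,reverse Primer sequences (5' to 3').
#' @param genomes Named list of two \code{DNAStringSet}s (\code{A},
#'   \code{B}).
#' @param selfSites Named list (\code{A}, \code{B}) of data.frames with
#'   columns \code{chrom}, \code{start}, \code{end} (0-based half-open):
#'   the projected design-site intervals of both primers in each genome.
#' @param evalueThreshold Specificity threshold (default 0.1).
#' @param stats From \code{\link{alignmentStats}}.
#' @param genomeCodes Optional named list (\code{A}, \code{B}) of
#'   precomputed genome encodings (see \code{\link{searchGenome}}).
#' @return List with \code{pass} (logical) and \code{offendingHits}
#'   (DataFrame of sub-threshold non-self hits, with a \code{genome}
#'   column).
#' @export
screenPrimerPair <- function(forward, reverse, genomes, selfSites,
                             evalueThreshold = 0.1,
                             stats = alignmentStats(),
                             genomeCodes = NULL) {
  if (!all(c("A", "B") %in% names(genomes)))
    stop("genomes must be a named list with elements A and B", call. = FALSE)
  if (is.null(genomeCodes))
    genomeCodes <- lapply(genomes, .encodeGenome)
  offending <- list()
  for (g in c("A", "B")) {
    self <- selfSites[[g]]
    if (is.null(self) || nrow(self) == 0L)
      stop("locus lacking genomic projection in genome ", g, call. = FALSE)
    for (oligo in c(forward, reverse)) {
      hits <- .searchGenomeRaw(oligo, genomeCodes[[g]], stats,
                               evalueThreshold)
      if (nrow(hits) == 0L) next
      isSelf <- vapply(seq_len(nrow(hits)), function(i) {
        any(self$chrom == hits$chrom[i] &
            self$start < hits$sEnd[i] & self$end > hits$sStart[i])
      }, logical(1))
      if (any(!isSelf)) {
        bad <- as.data.frame(hits[!isSelf, , drop = FALSE])
        bad$genome <- g
        bad$query <- oligo
        offending[[length(offending) + 1L]] <- bad
      }
    }
  }
  if (length(offending)) {
    list(pass = FALSE, offendingHits = S4Vectors::DataFrame(
      do.call(rbind, offending)))
  } else {
    list(pass = TRUE, offendingHits = S4Vectors::DataFrame(
      chrom = character(0), strand = character(0), score = numeric(0),
      evalue = numeric(0), qStart = integer(0), qEnd = integer(0),
      sStart = integer(0), sEnd = integer(0), genome = character(0),
      query = character(0)))
  }
}

#' Predict PCR amplicons of a primer pair in a genome
#'
#' Finds all loci where the forward and reverse primers bind in convergent
#' orientation within \code{maxProduct} bp, using exact matching of the
#' binding sites (\code{maxMismatch = 0} by default).
#'
#' @param forward,reverse Primer sequences (5' to 3').
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param maxProduct Largest reported amplicon (bp).
#' @param maxMismatch Mismatches tolerated at each binding site.
#' @return A \link[S4Vectors]{DataFrame}: \code{chrom}, \code{start},
#'   \code{end} (outer amplicon span, 0-based half-open), \code{length},
#'   and \code{orientation} (\code{fwd>rev} or \code{rev>fwd}).
#' @export
insilicoPcr <- function(forward, reverse, genome, maxProduct = 2000,
                        maxMismatch = 0) {
  sites <- function(oligo) {
    lapply(as.character(genome), function(s) {
      mi <- Biostrings::matchPattern(oligo, Biostrings::DNAString(s),
                                     max.mismatch = maxMismatch)
      cbind(start = BiocGenerics::start(mi) - 1L, end = BiocGenerics::end(mi))
    })
  }
  f <- sites(forward); fr <- sites(.revComp(forward))
  r <- sites(reverse); rr <- sites(.revComp(reverse))
  out <- list()
  addProducts <- function(plus, minus, chrom, orientation) {
    if (nrow(plus) == 0L || nrow(minus) == 0L) return()
    for (i in seq_len(nrow(plus))) {
      dn <- minus[minus[, "start"] >= plus[i, "start"] &
                  minus[, "end"] - plus[i, "start"] <= maxProduct, ,
                  drop = FALSE]
      if (nrow(dn) == 0L) next
      out[[length(out) + 1L]] <<- data.frame(
        chrom = chrom, start = plus[i, "start"], end = dn[, "end"],
        orientation = orientation)
    }
  }
  for (chrom in names(f)) {
    addProducts(f[[chrom]], rr[[chrom]], chrom, "fwd>rev")
    addProducts(r[[chrom]], fr[[chrom]], chrom, "rev>fwd")
  }
  if (length(out) == 0L) {
    return(S4Vectors::DataFrame(chrom = character(0), start = integer(0),
                                end = integer(0), length = integer(0),
                                orientation = character(0)))
  }
  res <- do.call(rbind, out)
  res$length <- res$end - res$start
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  S4Vectors::DataFrame(res[, c("chrom", "start", "end", "length",
                               "orientation")])
}
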