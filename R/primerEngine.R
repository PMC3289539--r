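#' The fixed dummy spacer inserted between two conserved regions
#'
#' \code{NNNN} + 25 repeats of \code{AATT} + \code{NNNN}, 108 bp in total.
#' Substituting this spacer for the real (divergent, unknown in the target
#' species) interval region forces primer picking to stay inside the
#' conserved regions: the terminal Ns make any boundary violation
#' detectable, and the AT-only core is unusable as a primer site.
#'
#' @return A 108-character string.
#' @export
dummySequence <- function() {
  paste0("NNNN", strrep("AATT", 25L), "NNNN")
}

#' Build the primer-design template for a candidate locus
#'
#' Concatenates the left conserved region, the \code{\link{dummySequence}},
#' and the right conserved region.
#'
#' @param crLeft,crRight Conserved-region sequences (character scalars,
#'   A/C/G/T only).
#' @return A list with \code{sequence}, and 0-based half-open spans
#'   \code{crLeftSpan} and \code{crRightSpan} within the template.
#' @examples
#' tpl <- buildTemplate(strrep("ACGTT", 6), strrep("TGCAA", 8))
#' nchar(tpl$sequence)  # 30 + 108 + 40
#' @export
buildTemplate <- function(crLeft, crRight) {
  crLeft <- as.character(crLeft); crRight <- as.character(crRight)
  if (grepl("N", crLeft) || grepl("N", crRight))
    stop("conserved regions must be N-free", call. = FALSE)
  dummy <- dummySequence()
  nL <- nchar(crLeft); nR <- nchar(crRight)
  list(
    sequence = paste0(crLeft, dummy, crRight),
    crLeftSpan = c(0L, nL),
    crRightSpan = c(nL + nchar(dummy), nL + nchar(dummy) + nR))
}

#' Thermodynamic parameters for melting-temperature calculation
#'
#' Nearest-neighbor enthalpy/entropy values are the unified DNA duplex
#' parameters of SantaLucia (1998), with the matching terminal-initiation
#' terms and the 0.368 * (N-1) * ln[Na+] entropic salt correction. The
#' defaults (50 mM monovalent cation, 50 nM oligo) are the usual
#' primer-design operating point; Tm is meaningless without them, so they
#' are explicit and configurable here.
#'
#' @param monovalentMilliMolar Monovalent cation concentration in mM.
#' @param oligoNanoMolar Total oligo concentration in nM.
#' @return A parameter list consumed by \code{\link{meltingTemperature}}.
#' @export
tmParameters <- function(monovalentMilliMolar = 50, oligoNanoMolar = 50) {
  stacks <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG",
              "TT", "TG", "AC", "AG", "TC", "CC")
  dH <- c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0,
          -7.9, -8.5, -8.4, -7.8, -8.2, -8.0)
  dS <- c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4,
          -19.9, -22.2, -22.7, -22.4, -21.0, -22.2, -19.9)
  list(
    dH = stats::setNames(dH, stacks),
    dS = stats::setNames(dS, stacks),
    initGC = c(dH = 0.1, dS = -2.8),
    initAT = c(dH = 2.3, dS = 4.1),
    monovalentMolar = monovalentMilliMolar / 1000,
    oligoMolar = oligoNanoMolar / 1e9)
}

.isSelfComplementary <- function(x) identical(x, .revComp(x))

#' Nearest-neighbor melting temperature of a primer
#'
#' Deterministic SantaLucia (1998) nearest-neighbor Tm with entropic salt
#' correction, assuming the oligo anneals to its perfect complement.
#'
#' @param oligo Character scalar over A/C/G/T, length >= 8.
#' @param params See \code{\link{tmParameters}}.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemperature("ACGTGCTAGCTAGGCTAGCA")
#' @export
meltingTemperature <- function(oligo, params = tmParameters()) {
  oligo <- toupper(as.character(oligo))
  if (grepl("[^ACGT]", oligo))
    stop("oligo must contain only A/C/G/T", call. = FALSE)
  n <- nchar(oligo)
  if (n < 8L) stop("oligo too short for nearest-neighbor Tm", call. = FALSE)
  di <- substring(oligo, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  dH <- sum(params$dH[di])
  dS <- sum(params$dS[di])
  for (term in c(substr(oligo, 1L, 1L), substr(oligo, n, n))) {
    init <- if (term %in% c("G", "C")) params$initGC else params$initAT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  sym <- .isSelfComplementary(oligo)
  if (sym) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1L) * log(params$monovalentMolar)
  ct <- params$oligoMolar / (if (sym) 1 else 4)
  R <- 1.9872
  dH * 1000 / (dS + R * log(ct)) - 273.15
}

#' Default primer-picking constraints
#'
#' Hard constraints and penalty weights for \code{\link{pickPrimerPairs}}.
#' The defaults mirror common primer3 practice: length 18-27 nt (optimum
#' 20), Tm 57-63 degC (optimum 60), GC 20-80 percent, mononucleotide runs
#' of at most 4, pairwise Tm difference of at most 3 degC, and ungapped
#' self/cross-complementarity score limits of 8 overall and 3 anchored at
#' the 3' end (match +1 / mismatch -1). The penalty of a primer is
#' \code{wTm * |Tm - tmOpt| + wLen * |len - lenOpt|}; a pair's penalty is
#' the sum over its two primers.
#'
#' @param lenRange,lenOpt Primer length bounds and optimum (nt).
#' @param tmRange,tmOpt Melting-temperature bounds and optimum (degC).
#' @param gcRange GC-content bounds (percent).
#' @param maxTmDiff Maximum |Tm_forward - Tm_reverse| (degC).
#' @param maxPolyX Maximum mononucleotide run length.
#' @param maxSelfAny,maxSelfEnd Self-complementarity limits.
#' @param maxPairAny,maxPairEnd Cross-complementarity limits.
#' @param wTm,wLen Penalty weights.
#' @param maxCandidatesPerSide Cap on per-side candidates carried into
#'   pairing (lowest-penalty first); bounds worst-case cost on long CRs.
#' @param maxPairsReturned Number of ranked pairs returned per template.
#' @param tm Thermodynamic parameters, see \code{\link{tmParameters}}.
#' @return A constraints list.
#' @export
primerConstraints <- function(lenRange = c(18L, 27L), lenOpt = 20L,
                              tmRange = c(57, 63), tmOpt = 60,
                              gcRange = c(20, 80), maxTmDiff = 3,
                              maxPolyX = 4L,
                              maxSelfAny = 8, maxSelfEnd = 3,
                              maxPairAny = 8, maxPairEnd = 3,
                              wTm = 1, wLen = 1,
                              maxCandidatesPerSide = 100L,
                              maxPairsReturned = 10L,
                              tm = tmParameters()) {
  as.list(environment())
}

# Best ungapped complementarity score between s1 (5'->3') and s2, both
# given 5'->3': s1 is slid along the reverse of s2 and aligned positions
# score +1 when Watson-Crick complementary, -1 otherwise; the score of an
# offset is its best contiguous segment (prefix-sum form of Kadane).
# anchor3p = TRUE restricts segments to those ending at the 3' terminus
# of s1.
.complScore <- function(s1, s2, anchor3p = FALSE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a <- unname(comp[strsplit(s1, "", fixed = TRUE)[[1]]])
  b <- rev(strsplit(s2, "", fixed = TRUE)[[1]])
  n1 <- length(a); n2 <- length(b)
  best <- 0
  for (off in (-(n1 - 1L)):(n2 - 1L)) {
    i <- max(1L, 1L - off):min(n1, n2 - off)
    if (anchor3p && i[length(i)] != n1) next
    s <- ifelse(a[i] == b[i + off], 1, -1)
    if (anchor3p) {
      best <- max(best, max(rev(cumsum(rev(s)))))
    } else {
      P <- cumsum(s)
      best <- max(best, max(P - cummin(c(0, P[-length(P)]))))
    }
  }
  best
}

# Nearest-neighbor Tm for every candidate window of one region at once:
# stack enthalpies/entropies as prefix sums over the region, O(1) per
# window. Numerically equivalent to meltingTemperature() (summation order
# aside). starts0 are 0-based window starts within `region`.
.tmWindows <- function(region, starts0, lens, params) {
  code <- .encodeSeq(region)
  n <- length(code)
  bases <- c("A", "C", "G", "T")
  key <- as.vector(outer(bases, bases, function(a, b) paste0(a, b)))
  # key order: AA,CA,GA,TA,AC,... index = b1 + 4*(b2-1)
  dHtab <- unname(params$dH[key])
  dStab <- unname(params$dS[key])
  idx <- code[-n] + 4L * (code[-1] - 1L)
  cH <- c(0, cumsum(dHtab[idx]))
  cS <- c(0, cumsum(dStab[idx]))
  dH <- cH[starts0 + lens] - cH[starts0 + 1L]
  dS <- cS[starts0 + lens] - cS[starts0 + 1L]
  for (endCode in list(code[starts0 + 1L], code[starts0 + lens])) {
    gcEnd <- endCode == 2L | endCode == 3L
    dH <- dH + ifelse(gcEnd, params$initGC[["dH"]], params$initAT[["dH"]])
    dS <- dS + ifelse(gcEnd, params$initGC[["dS"]], params$initAT[["dS"]])
  }
  seqs <- substring(region, starts0 + 1L, starts0 + lens)
  sym <- seqs == .revComp(seqs)
  dS <- dS - 1.4 * sym
  dS <- dS + 0.368 * (lens - 1L) * log(params$monovalentMolar)
  ct <- params$oligoMolar / ifelse(sym, 1, 4)
  dH * 1000 / (dS + 1.9872 * log(ct)) - 273.15
}

.primerCandidates <- function(region, regionStart0, constraints) {
  n <- nchar(region)
  lens <- constraints$lenRange[1]:constraints$lenRange[2]
  lens <- lens[lens <= n]
  if (length(lens) == 0L) return(NULL)
  cand <- do.call(rbind, lapply(lens, function(L) {
    data.frame(start0 = 0:(n - L), len = L)
  }))
  code <- .encodeSeq(region)
  gcCum <- c(0, cumsum(code == 2L | code == 3L))
  cand$gc <- 100 * (gcCum[cand$start0 + cand$len + 1L] -
                    gcCum[cand$start0 + 1L]) / cand$len
  # a window fails the poly-X rule iff it contains maxPolyX+1 equal bases
  # in a row; runStart marks where such a run begins
  eq <- code[-1] == code[-n]
  k <- constraints$maxPolyX
  runStart <- if (n > k) {
    as.numeric(stats::filter(eq, rep(1, k), sides = 1)[-seq_len(k - 1)] == k)
  } else numeric(0)
  badCum <- c(0, cumsum(runStart))  # badCum[p]: runs starting at chars 1..p
  hasRun <- function(s0, L) {
    hi <- pmin(s0 + L - k, length(badCum) - 1L)
    lo <- s0
    ifelse(hi > lo, badCum[pmax(hi, 1L) + 1L] - badCum[lo + 1L] > 0, FALSE)
  }
  ok <- cand$gc >= constraints$gcRange[1] &
    cand$gc <= constraints$gcRange[2] &
    !hasRun(cand$start0, cand$len)
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand$tm <- .tmWindows(region, cand$start0, cand$len, constraints$tm)
  cand <- cand[cand$tm >= constraints$tmRange[1] &
               cand$tm <= constraints$tmRange[2], , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand$seq <- substring(region, cand$start0 + 1L, cand$start0 + cand$len)
  cand$start0 <- regionStart0 + cand$start0
  cand$penalty <- constraints$wTm * abs(cand$tm - constraints$tmOpt) +
    constraints$wLen * abs(cand$len - constraints$lenOpt)
  cand <- cand[order(cand$penalty, cand$start0, cand$len), , drop = FALSE]
  utils::head(cand, constraints$maxCandidatesPerSide)
}

#' Pick primer pairs confined to the conserved regions of a template
#'
#' Enumerates all forward candidates within the left conserved region and
#' all reverse candidates within the right conserved region (the reverse
#' primer is the reverse complement of the template slice it binds),
#' filters on the hard constraints, scores each surviving pair by summed
#' penalty, and returns the ranked list. No primer can touch the dummy
#' spacer: candidates are drawn from the CR spans only, and any overlap
#' would introduce an N, which the hard constraints reject.
#'
#' @param template From \code{\link{buildTemplate}}.
#' @param constraints From \code{\link{primerConstraints}}.
#' @return A \link[S4Vectors]{DataFrame}, best pair first, with oligo
#'   sequences, 0-based template coordinates of the binding sites, Tm, GC
#'   and penalty; zero rows when no pair satisfies the constraints.
#' @export
pickPrimerPairs <- function(template, constraints = primerConstraints()) {
  empty <- S4Vectors::DataFrame(
    forward = character(0), reverse = character(0),
    fStart = integer(0), fEnd = integer(0),
    rStart = integer(0), rEnd = integer(0),
    tm_f = numeric(0), tm_r = numeric(0),
    gc_f = numeric(0), gc_r = numeric(0), penalty = numeric(0))
  crL <- .sliceSeq(template$sequence, template$crLeftSpan[1],
                   template$crLeftSpan[2])
  crR <- .sliceSeq(template$sequence, template$crRightSpan[1],
                   template$crRightSpan[2])
  fwd <- .primerCandidates(crL, template$crLeftSpan[1], constraints)
  if (is.null(fwd)) return(empty)
  revBind <- .primerCandidates(crR, template$crRightSpan[1], constraints)
  if (is.null(revBind)) return(empty)
  fwd$selfAny <- vapply(fwd$seq, function(s) .complScore(s, s), numeric(1))
  fwd$selfEnd <- vapply(fwd$seq, function(s) .complScore(s, s, TRUE),
                        numeric(1))
  fwd <- fwd[fwd$selfAny <= constraints$maxSelfAny &
             fwd$selfEnd <= constraints$maxSelfEnd, , drop = FALSE]
  if (nrow(fwd) == 0L) return(empty)
  revBind$oligo <- .revComp(revBind$seq)
  revBind$selfAny <- vapply(revBind$oligo, function(s) .complScore(s, s),
                            numeric(1))
  revBind$selfEnd <- vapply(revBind$oligo, function(s) .complScore(s, s, TRUE),
                            numeric(1))
  revBind <- revBind[revBind$selfAny <= constraints$maxSelfAny &
                     revBind$selfEnd <= constraints$maxSelfEnd, , drop = FALSE]
  if (nrow(revBind) == 0L) return(empty)

  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(revBind)))
  tmd <- abs(fwd$tm[grid$f] - revBind$tm[grid$r])
  grid <- grid[tmd <= constraints$maxTmDiff, , drop = FALSE]
  if (nrow(grid) == 0L) return(empty)
  # rank all pairs by penalty (deterministic tie-break on coordinates),
  # then evaluate the costly cross-complementarity lazily in that order
  grid$penalty <- fwd$penalty[grid$f] + revBind$penalty[grid$r]
  o <- order(grid$penalty,
             fwd$start0[grid$f], fwd$len[grid$f],
             revBind$start0[grid$r], revBind$len[grid$r])
  grid <- grid[o, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(grid))) {
    f <- fwd$seq[grid$f[i]]; r <- revBind$oligo[grid$r[i]]
    if (.complScore(f, r) > constraints$maxPairAny) next
    if (max(.complScore(f, r, TRUE), .complScore(r, f, TRUE)) >
        constraints$maxPairEnd) next
    keep <- c(keep, i)
    if (length(keep) >= constraints$maxPairsReturned) break
  }
  if (length(keep) == 0L) return(empty)
  grid <- grid[keep, , drop = FALSE]
  out <- S4Vectors::DataFrame(
    forward = fwd$seq[grid$f],
    reverse = revBind$oligo[grid$r],
    fStart = as.integer(fwd$start0[grid$f]),
    fEnd = as.integer(fwd$start0[grid$f] + fwd$len[grid$f]),
    rStart = as.integer(revBind$start0[grid$r]),
    rEnd = as.integer(revBind$start0[grid$r] + revBind$len[grid$r]),
    tm_f = fwd$tm[grid$f], tm_r = revBind$tm[grid$r],
    gc_f = fwd$gc[grid$f], gc_r = revBind$gc[grid$r],
    penalty = grid$penalty)
  rownames(out) <- NULL
  out
}
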