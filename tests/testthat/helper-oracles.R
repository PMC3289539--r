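# Independent reference implementations used as oracles. These share no
# code with the package internals they check.

# All maximal exact matches >= k between two sequences, by examining every
# diagonal of the full character-match matrix.
oracleMEMs <- function(a, b, k) {
  ac <- strsplit(toupper(a), "")[[1]]
  bc <- strsplit(toupper(b), "")[[1]]
  nA <- length(ac); nB <- length(bc)
  out <- list()
  if (nA >= 1 && nB >= 1) {
    M <- outer(ac, bc, "==") & outer(ac != "N", bc != "N", "&")
    for (d in (-(nB - 1)):(nA - 1)) {
      i <- max(1, 1 + d):min(nA, nB + d)
      if (length(i) < k) next
      v <- M[cbind(i, i - d)]
      r <- rle(v)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (h in which(r$values & r$lengths >= k)) {
        sA <- i[starts[h]]; eA <- i[ends[h]]
        out[[length(out) + 1]] <- data.frame(
          startA = sA - 1L, endA = eA, startB = sA - d - 1L, endB = eA - d,
          length = eA - sA + 1L)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(startA = integer(0), endA = integer(0),
                      startB = integer(0), endB = integer(0),
                      length = integer(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$startA, df$startB), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Nearest-neighbor Tm, written independently: per-dinucleotide loop with a
# list-based parameter lookup (SantaLucia 1998 unified table, entropic
# salt correction, 50 mM monovalent, 50 nM oligo).
oracleTm <- function(oligo) {
  nn <- list(
    AA = c(-7.9, -22.2), TT = c(-7.9, -22.2),
    AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
    GT = c(-8.4, -22.4), AC = c(-8.4, -22.4),
    CT = c(-7.8, -21.0), AG = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
    CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9), CC = c(-8.0, -19.9))
  ch <- strsplit(oligo, "")[[1]]
  n <- length(ch)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    v <- nn[[paste0(ch[i], ch[i + 1])]]
    dH <- dH + v[1]; dS <- dS + v[2]
  }
  for (term in ch[c(1, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  selfc <- identical(paste(rev(unname(comp[ch])), collapse = ""), oligo)
  if (selfc) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1) * log(0.05)
  ct <- 50e-9 / (if (selfc) 1 else 4)
  dH * 1000 / (dS + 1.9872 * log(ct)) - 273.15
}

# Optimal global alignment score by exhaustive recursion over all
# alignments. Affine gaps: a gap of length g costs open + ext * g.
# Feasible for sequences of length <= 8.
oracleAlignScore <- function(a, b, match = 5, mismatch = -4,
                             gapOpen = 10, gapExt = 0.5) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(ac) && j > length(bc)) return(0)
    best <- -Inf
    if (i <= length(ac) && j <= length(bc)) {
      s <- if (ac[i] == bc[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ac)) {  # gap in b
      cost <- gapExt + if (prev == "gb") 0 else gapOpen
      best <- max(best, rec(i + 1, j, "gb") - cost)
    }
    if (j <= length(bc)) {  # gap in a
      cost <- gapExt + if (prev == "ga") 0 else gapOpen
      best <- max(best, rec(i, j + 1, "ga") - cost)
    }
    best
  }
  rec(1, 1, "m")
}

# Best ungapped local-alignment segment per diagonal, explicit scan.
oracleLocalHits <- function(query, subject, match = 1, mismatch = -2,
                            minScore = 1) {
  qc <- strsplit(query, "")[[1]]; sc <- strsplit(subject, "")[[1]]
  m <- length(qc); L <- length(sc)
  out <- list()
  for (d in (1 - m):(L - 1)) {  # d = sStart - qStart (0-based)
    H <- 0; best <- 0; cur <- 1; bq <- c(0, 0)
    for (j in seq_len(m)) {
      p <- d + j  # 1-based subject pos of query base j
      s <- if (p >= 1 && p <= L && sc[p] == qc[j] && qc[j] != "N")
        match else mismatch
      if (H == 0) cur <- j
      H <- max(0, H + s)
      if (H > best) { best <- H; bq <- c(cur, j) }
    }
    if (best >= minScore) {
      out[[length(out) + 1]] <- data.frame(
        score = best, qStart = bq[1] - 1L, qEnd = bq[2],
        sStart = d + bq[1] - 1L, sEnd = d + bq[2])
    }
  }
  if (!length(out)) {
    return(data.frame(score = numeric(0), qStart = integer(0),
                      qEnd = integer(0), sStart = integer(0),
                      sEnd = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$sStart, df$qStart), , drop = FALSE]
}

# Exact hypergeometric tail by direct summation of choose() masses.
oracleHyperTail <- function(obs, K, N, n, upper) {
  xs <- if (upper) obs:min(K, n) else 0:obs
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a genome with the two primer sites planted once each (at 1001 and
# 1501, 1-based), and verify with the brute-force aligner (both strands)
# that no off-site segment reaches the E < 0.1 score threshold: the
# planted sites are then provably unique at that stringency.
plantUniqueGenome <- function(fwd, revSite, bgLen = 6000) {
  stats <- alignmentStats(1, -2)
  repeat {
    s <- randomDna(bgLen)
    substr(s, 1001, 1020) <- fwd
    substr(s, 1501, 1520) <- revSite
    minScore <- ceiling(log(stats$K * 20 * 2 * bgLen / 0.1) / stats$lambda)
    offsite <- function(q) {
      h <- rbind(oracleLocalHits(q, s, 1, -2, minScore),
                 oracleLocalHits(as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(q))), s, 1, -2, minScore))
      h[!(h$sStart < 1020 & h$sEnd > 1000) &
        !(h$sStart < 1520 & h$sEnd > 1500), , drop = FALSE]
    }
    if (nrow(offsite(fwd)) == 0 && nrow(offsite(revSite)) == 0) return(s)
  }
}
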