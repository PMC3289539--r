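test_that("Karlin-Altschul parameters match published blastn values", {
  s <- alignmentStats(1, -2)
  expect_equal(s$lambda, 1.33, tolerance = 0.005)
  expect_equal(s$K, 0.621, tolerance = 0.01)
  expect_equal(s$H, 1.12, tolerance = 0.01)
  s2 <- alignmentStats(5, -4)
  expect_equal(s2$lambda, 0.192, tolerance = 0.01)
  expect_equal(s2$K, 0.176, tolerance = 0.01)
})

test_that("planted query sites are found exactly", {
  set.seed(1)
  g <- randomDna(20000)
  q <- substr(g, 8001, 8020)
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  hits <- searchGenome(q, genome)
  top <- as.data.frame(hits[1, ])
  expect_equal(top$score, 20)
  expect_equal(top$sStart, 8000L)
  expect_equal(top$sEnd, 8020L)
  expect_equal(top$qStart, 0L)
  expect_equal(top$qEnd, 20L)
  expect_equal(top$strand, "+")
  expect_equal(sum(hits$score == 20), 1L)
  # planted twice: two perfect hits
  g2 <- paste0(g, randomDna(500), q, randomDna(500))
  hits2 <- searchGenome(q, Biostrings::DNAStringSet(c(chr1 = g2)))
  expect_equal(sum(hits2$score == 20), 2L)
})

test_that("doubling the database size doubles the E-value", {
  set.seed(2)
  g <- randomDna(5000)
  q <- substr(g, 1001, 1020)
  one <- searchGenome(q, Biostrings::DNAStringSet(c(chr1 = g)))
  two <- searchGenome(q, Biostrings::DNAStringSet(
    c(chr1 = g, chr2 = randomDna(5000))))
  e1 <- one$evalue[one$score == 20][1]
  e2 <- two$evalue[two$score == 20][1]
  expect_equal(e2 / e1, 2, tolerance = 1e-9)
})

test_that("search agrees with a brute-force local aligner", {
  set.seed(3)
  stats <- alignmentStats(1, -2)
  for (rep in 1:5) {
    g <- randomDna(3000)
    q <- randomDna(22)
    # plant a degraded copy so mid-range scores exist
    copy <- q
    for (p in sample(1:22, 3)) {
      substr(copy, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(copy, p, p))[1]
    }
    pos <- sample(0:(3000 - 22), 1)
    substr(g, pos + 1, pos + 22) <- copy
    minScore <- 10
    want <- oracleLocalHits(q, g, 1, -2, minScore)
    genome <- Biostrings::DNAStringSet(c(c1 = g))
    got <- as.data.frame(searchGenome(q, genome, stats,
                                      eValueCeiling = Inf))
    got <- got[got$strand == "+" & got$score >= minScore, , drop = FALSE]
    got <- got[order(got$sStart, got$qStart),
               c("score", "qStart", "qEnd", "sStart", "sEnd")]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("short queries are rejected", {
  expect_error(searchGenome("ACGTACGTAC",
                            Biostrings::DNAStringSet(c(a = "ACGTACGT"))),
               "query shorter")
})

test_that("specificity screen separates unique and duplicated primers", {
  set.seed(4)
  fwd <- randomDna(20)
  revSite <- randomDna(20)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(revSite)))
  genomes <- list(
    A = Biostrings::DNAStringSet(c(chr1 = plantUniqueGenome(fwd, revSite))),
    B = Biostrings::DNAStringSet(c(chr1 = plantUniqueGenome(fwd, revSite))))
  self <- data.frame(chrom = "chr1", start = c(1000L, 1500L),
                     end = c(1020L, 1520L))
  v <- screenPrimerPair(fwd, rev, genomes, list(A = self, B = self))
  expect_true(v$pass)
  expect_equal(nrow(v$offendingHits), 0L)
  # duplicate the forward site on another chromosome: must fail
  genomes2 <- genomes
  dup <- randomDna(4000)
  substr(dup, 3001, 3020) <- fwd
  genomes2$A <- Biostrings::DNAStringSet(
    c(chr1 = as.character(genomes$A[[1]]), chr2 = dup))
  v2 <- screenPrimerPair(fwd, rev, genomes2, list(A = self, B = self))
  expect_false(v2$pass)
  expect_gte(nrow(v2$offendingHits), 1L)
  expect_true(any(v2$offendingHits$chrom == "chr2"))
})

test_that("a heavily degraded duplicate scores below the threshold", {
  set.seed(5)
  stats <- alignmentStats(1, -2)
  fwd <- randomDna(20)
  # duplicate with 8 mismatches spread evenly: best segment stays short
  degraded <- strsplit(fwd, "")[[1]]
  for (p in round(seq(1, 20, length.out = 8))) {
    degraded[p] <- setdiff(c("A", "C", "G", "T"), degraded[p])[1]
  }
  degraded <- paste(degraded, collapse = "")
  s <- plantUniqueGenome(fwd, randomDna(20), bgLen = 6000)
  substr(s, 4001, 4020) <- degraded
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  # the degraded copy's best local score must give E >= 0.1
  revcq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  hits <- rbind(oracleLocalHits(fwd, s, 1, -2, minScore = 1),
                oracleLocalHits(revcq, s, 1, -2, minScore = 1))
  inDup <- hits[hits$sStart >= 4000 & hits$sEnd <= 4020, , drop = FALSE]
  expect_gt(nrow(inDup), 0L)
  eDup <- evalueOf(max(inDup$score), 20, 2 * 6000, stats)
  expect_gte(eDup, 0.1)
  self <- data.frame(chrom = "chr1", start = 1000L, end = 1020L)
  revc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  v <- screenPrimerPair(fwd, revc, list(A = genome, B = genome),
                        list(A = self, B = self))
  expect_true(v$pass)
})

test_that("in-silico PCR reproduces the designed amplicon arithmetic", {
  set.seed(6)
  for (rep in 1:20) {
    crL <- randomDna(30); crR <- randomDna(30)
    irLen <- sample(300:700, 1)
    ir <- randomDna(irLen)
    gene <- paste0(randomDna(100), crL, ir, crR, randomDna(100))
    fOff <- sample(0:10, 1)          # forward start within left CR
    rEndOff <- sample(0:10, 1)       # reverse end offset from right CR end
    fwd <- substr(crL, fOff + 1, fOff + 20)
    rSite <- substr(crR, 30 - rEndOff - 19, 30 - rEndOff)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rSite)))
    genome <- Biostrings::DNAStringSet(c(chr1 = gene))
    amp <- insilicoPcr(fwd, rev, genome)
    expect_equal(nrow(amp), 1L)
    expectLen <- (30 - fOff) + irLen + (30 - rEndOff)
    expect_equal(amp$length[1], expectLen)
    # amplicon contains the full interval region
    expect_lte(amp$start[1], 100 + 30)
    expect_gte(amp$end[1], 100 + 30 + irLen)
  }
  # absent reverse site: no amplicon
  expect_equal(nrow(insilicoPcr("ACGTACGTACGTACGTACGT",
                                "TTTTGGGGCCCCAAAATTTT",
                                Biostrings::DNAStringSet(
                                  c(chr1 = randomDna(2000))))), 0L)
})
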