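test_that("identical sequences align gap-free with score 5 per base", {
  set.seed(1)
  s <- randomDna(120)
  aln <- globalAlign(s, s)
  expect_equal(aln$alignedA, s)
  expect_equal(aln$alignedB, s)
  expect_equal(aln$score, 5 * 120)
})

test_that("alignment scores match exhaustive enumeration on short pairs", {
  aln <- globalAlign("ACGT", "AGT")
  expect_equal(sum(strsplit(aln$alignedB, "")[[1]] == "-"), 1L)
  expect_equal(aln$score, oracleAlignScore("ACGT", "AGT"))
  set.seed(2)
  for (rep in 1:25) {
    a <- randomDna(sample(3:8, 1))
    b <- randomDna(sample(3:8, 1))
    expect_equal(globalAlign(a, b)$score, oracleAlignScore(a, b),
                 info = paste(a, b))
  }
})

test_that("the optimal score is at least any ungapped diagonal score", {
  set.seed(3)
  for (rep in 1:10) {
    a <- randomDna(40); b <- randomDna(40)
    diag <- sum(ifelse(strsplit(a, "")[[1]] == strsplit(b, "")[[1]],
                       5, -4))
    expect_gte(globalAlign(a, b)$score, diag)
  }
  expect_error(globalAlign("", "ACGT"), "empty")
})

test_that("identity removes N columns and keeps gap columns", {
  set.seed(4)
  s <- randomDna(100)
  expect_equal(identityAfterNRemoval(s, s)$identity, 1.0)
  s2 <- s
  substr(s2, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                substr(s, 50, 50))[1]
  expect_equal(identityAfterNRemoval(s, s2)$identity, 0.99)
  # 100 columns, 10 with N, 85 of the remaining 90 identical
  a <- strsplit(s, "")[[1]]
  b <- a
  b[1:10] <- "N"
  for (p in 11:15) b[p] <- setdiff(c("A", "C", "G", "T"), a[p])[1]
  rec <- identityAfterNRemoval(paste(a, collapse = ""),
                               paste(b, collapse = ""))
  expect_equal(rec$columnsRemovedN, 10L)
  expect_equal(rec$matches, 85L)
  expect_equal(rec$identity, 85 / 90)
  # gap columns count in the denominator
  gap <- identityAfterNRemoval("ACGTACGTAC", "ACGT-CGTAC")
  expect_equal(gap$identity, 0.9)
})

test_that("identity is undefined, not 0 or 1, when all columns drop", {
  rec <- identityAfterNRemoval("NNNN", "ACGT")
  expect_false(rec$defined)
  expect_true(is.na(rec$identity))
})

test_that("identity is symmetric", {
  set.seed(5)
  for (rep in 1:10) {
    a <- randomDna(60); b <- randomDna(60)
    expect_equal(identityAfterNRemoval(a, b)$identity,
                 identityAfterNRemoval(b, a)$identity)
  }
})

test_that("loci are classified exonic, intronic or both", {
  chrom <- paste(rep("ACGTT", 200), collapse = "")  # 1000 bp
  ann <- makeTinyAnnotation(
    list(chr1 = chrom),
    c("chr1\tt\tgene\t1\t1000\t.\t+\t.\tID=g1",
      "chr1\tt\texon\t1\t300\t.\t+\t.\tID=g1.e1;Parent=g1",
      "chr1\tt\texon\t601\t1000\t.\t+\t.\tID=g1.e2;Parent=g1"))
  expect_equal(classifyLocus("chr1", 50, 250, ann)$class, "exon")
  expect_equal(classifyLocus("chr1", 350, 550, ann)$class, "intron")
  expect_equal(classifyLocus("chr1", 200, 400, ann)$class, "both")
  expect_error(classifyLocus("chr1", 900, 1100, ann), "not contained")
})

test_that("selection honors the identity band inclusively", {
  loci <- data.frame(
    locus_id = sprintf("l%d", 1:4),
    chromosome = c("c1", "c2", "c3", "c4"),
    identity = c(0.74, 0.75, 0.90, 0.91),
    class = "exon")
  expect_setequal(selectCandidates(loci), c("l2", "l3"))
})

test_that("selection caps loci per chromosome and balances classes", {
  loci <- data.frame(
    locus_id = sprintf("l%d", 1:5), chromosome = "c1",
    identity = 0.8, class = c("exon", "exon", "exon", "exon", "exon"))
  expect_length(selectCandidates(loci, perChromosome = 2), 2L)
  mix <- data.frame(
    locus_id = c("a", "b", "c"), chromosome = "c1",
    identity = 0.8, class = c("exon", "exon", "intron"))
  sel <- selectCandidates(mix, perChromosome = 2)
  expect_setequal(sel, c("a", "c"))  # one exon (smallest id) + one intron
})

test_that("identity histogram bins conserve counts, last bin closed", {
  h <- identityHistogram(rep(1.0, 7))
  expect_equal(sum(h$count), 7L)
  expect_equal(h$count[nrow(h)], 7L)  # terminal bin [0.95, 1] is closed
  expect_equal(h$binStart[nrow(h)], 0.95)
  set.seed(6)
  ids <- runif(200)
  expect_equal(sum(identityHistogram(ids)$count), 200L)
})

test_that("higher substitution rates shift identity mass downward", {
  set.seed(7)
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  idAt <- function(rate) {
    vapply(1:40, function(i) {
      s <- randomDna(300)
      identityAfterNRemoval(s, mutate(s, rate))$identity
    }, numeric(1))
  }
  id05 <- idAt(0.05); id15 <- idAt(0.15)
  # mass below 0.9 is larger at the higher substitution rate
  expect_gt(mean(id15 < 0.9), mean(id05 < 0.9))
  expect_gt(mean(id05), mean(id15))
})
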