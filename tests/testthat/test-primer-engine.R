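test_that("the design template is CR + 108 bp dummy + CR", {
  expect_equal(nchar(dummySequence()), 108L)
  expect_equal(dummySequence(),
               paste0("NNNN", paste(rep("AATT", 25), collapse = ""), "NNNN"))
  set.seed(1)
  crL <- randomDna(30); crR <- randomDna(40)
  tpl <- buildTemplate(crL, crR)
  expect_equal(nchar(tpl$sequence), 178L)
  expect_equal(substr(tpl$sequence, 31, 138), dummySequence())
  expect_equal(tpl$crLeftSpan, c(0L, 30L))
  expect_equal(tpl$crRightSpan, c(138L, 178L))
})

test_that("nearest-neighbor Tm matches an independent implementation", {
  set.seed(2)
  for (i in 1:20) {
    oligo <- randomDna(sample(18:27, 1))
    expect_equal(meltingTemperature(oligo), oracleTm(oligo),
                 tolerance = 1 / 60)  # within 1 degC, absolute
  }
})

test_that("Tm is symmetric under reverse complement (duplex symmetry)", {
  set.seed(3)
  for (i in 1:20) {
    oligo <- randomDna(20)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(oligo)))
    expect_equal(meltingTemperature(oligo), meltingTemperature(rc),
                 tolerance = 1e-9)
  }
})

test_that("appending a G or C base never decreases Tm of an A/T core", {
  # exhaustive over all 4096 A/T-only 12-mers
  cores <- do.call(paste0, expand.grid(rep(list(c("A", "T")), 12)))
  for (ext in c("G", "C")) {
    tmCore <- vapply(cores, meltingTemperature, numeric(1))
    tmExt <- vapply(paste0(cores, ext), meltingTemperature, numeric(1))
    expect_true(all(tmExt >= tmCore))
  }
})

test_that("Tm rejects N and short oligos", {
  expect_error(meltingTemperature("ACGTNACGTACGTACGT"), "A/C/G/T")
  expect_error(meltingTemperature("ACGTACG"), "short")
})

test_that("primer picking is confined to the conserved regions", {
  set.seed(4)
  # left CR shorter than the minimum primer length: no design possible
  tpl <- buildTemplate(randomDna(17), randomDna(40))
  expect_equal(nrow(pickPrimerPairs(tpl)), 0L)
  # both CRs 27 bp: any forward primer is a substring of the left CR
  found <- FALSE
  for (i in 1:20) {
    crL <- randomDna(27); crR <- randomDna(27)
    pp <- pickPrimerPairs(buildTemplate(crL, crR))
    if (nrow(pp) == 0L) next
    found <- TRUE
    expect_true(all(vapply(pp$forward, grepl, logical(1), x = crL,
                           fixed = TRUE)))
    rcRev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(pp$reverse)))
    expect_true(all(vapply(rcRev, grepl, logical(1), x = crR,
                           fixed = TRUE)))
    expect_false(any(grepl("N", pp$forward)))
    expect_false(any(grepl("N", pp$reverse)))
  }
  expect_true(found)
})

test_that("the best pair agrees with exhaustive enumeration", {
  cons <- primerConstraints()
  set.seed(6)
  done <- 0L
  for (rep in 1:40) {
    crL <- randomDna(30); crR <- randomDna(30)
    tpl <- buildTemplate(crL, crR)
    pp <- pickPrimerPairs(tpl, cons)
    # independent enumeration of every legal (forward, reverse) pair
    windows <- function(s) {
      out <- character(0)
      for (L in cons$lenRange[1]:cons$lenRange[2]) {
        if (L > nchar(s)) next
        out <- c(out, substring(s, 1:(nchar(s) - L + 1),
                                1:(nchar(s) - L + 1) + L - 1))
      }
      out
    }
    hardOk <- function(o) {
      gc <- 100 * lengths(regmatches(o, gregexpr("[GC]", o))) / nchar(o)
      run <- vapply(strsplit(o, ""), function(x) max(rle(x)$lengths), 1)
      tm <- vapply(o, oracleTm, numeric(1))
      gc >= cons$gcRange[1] & gc <= cons$gcRange[2] &
        run <= cons$maxPolyX &
        tm >= cons$tmRange[1] & tm <= cons$tmRange[2]
    }
    fw <- windows(crL); fw <- fw[hardOk(fw)]
    rv <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(windows(crR))))
    rv <- rv[hardOk(rv)]
    sa <- orthoprimer:::.complScore
    fw <- fw[vapply(fw, function(s) sa(s, s) <= cons$maxSelfAny &&
                      sa(s, s, TRUE) <= cons$maxSelfEnd, logical(1))]
    rv <- rv[vapply(rv, function(s) sa(s, s) <= cons$maxSelfAny &&
                      sa(s, s, TRUE) <= cons$maxSelfEnd, logical(1))]
    bestPen <- Inf
    for (f in fw) for (r in rv) {
      if (abs(oracleTm(f) - oracleTm(r)) > cons$maxTmDiff) next
      if (sa(f, r) > cons$maxPairAny) next
      if (max(sa(f, r, TRUE), sa(r, f, TRUE)) > cons$maxPairEnd) next
      pen <- abs(oracleTm(f) - cons$tmOpt) + abs(nchar(f) - cons$lenOpt) +
        abs(oracleTm(r) - cons$tmOpt) + abs(nchar(r) - cons$lenOpt)
      bestPen <- min(bestPen, pen)
    }
    if (is.infinite(bestPen)) {
      expect_equal(nrow(pp), 0L)
    } else {
      expect_gt(nrow(pp), 0L)
      expect_equal(pp$penalty[1], bestPen, tolerance = 1e-6)
      done <- done + 1L
    }
    if (done >= 3L) break
  }
  expect_gte(done, 1L)
})

test_that("picking is deterministic", {
  set.seed(7)
  tpl <- buildTemplate(randomDna(35), randomDna(35))
  a <- pickPrimerPairs(tpl)
  b <- pickPrimerPairs(tpl)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
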