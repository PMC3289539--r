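test_that("FASTA reading normalizes case, U and identifiers", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgtuACGTN",
               ">chr2", "GGGGGCCCCC"), fa)
  x <- readGenomeFasta(fa)
  expect_equal(names(x), c("chr1", "chr2"))
  expect_equal(unname(width(x)), c(10L, 10L))
  expect_equal(as.character(x[["chr1"]]), "ACGTTACGTN")
})

test_that("empty FASTA gives an empty set; bad characters are rejected", {
  fa <- tempfile(fileext = ".fa")
  file.create(fa)
  expect_length(readGenomeFasta(fa), 0L)
  writeLines(c(">r1", "ACGRTACGTA"), fa)  # R = ambiguity code
  expect_error(readGenomeFasta(fa), "r1")
  writeLines(c("ACGT", ">r1", "ACGT"), fa)
  expect_error(readGenomeFasta(fa), "header")
})

test_that("FASTA round-trips through write and read", {
  set.seed(5)
  seqs <- Biostrings::DNAStringSet(
    c(a = randomDna(83), b = randomDna(200)))
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(seqs, fa)
  back <- readGenomeFasta(fa)
  expect_equal(as.character(back), as.character(seqs))
})

test_that("GFF3 coordinates convert to 0-based half-open internally", {
  chrom <- paste(rep("ACGTT", 60), collapse = "")  # 300 bp
  ann <- makeTinyAnnotation(
    list(chr1 = chrom),
    c("chr1\tt\tgene\t101\t200\t.\t+\t.\tID=g1",
      "chr1\tt\texon\t101\t130\t.\t+\t.\tID=g1.e1;Parent=g1",
      "chr1\tt\texon\t171\t200\t.\t+\t.\tID=g1.e2;Parent=g1"))
  g <- geneModels(ann)
  expect_equal(start(g) - 1L, 100L)  # 0-based start
  expect_equal(end(g), 200L)        # half-open end
  ex <- exonsByGene(ann)[["g1"]]
  # one intron between the exons: internal [130, 170)
  expect_equal(end(ex)[1], 130L)
  expect_equal(start(ex)[2] - 1L, 170L)
  expect_equal(as.character(unsplicedSeqs(ann)[["g1"]]),
               substr(chrom, 101, 200))
})

test_that("minus-strand genes get reverse-complemented unspliced sequence", {
  set.seed(9)
  chrom <- randomDna(400)
  ann <- makeTinyAnnotation(
    list(chr1 = chrom),
    c("chr1\tt\tgene\t51\t250\t.\t-\t.\tID=gm",
      "chr1\tt\texon\t51\t250\t.\t-\t.\tID=gm.e1;Parent=gm"))
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 51, 250))))
  expect_equal(as.character(unsplicedSeqs(ann)[["gm"]]), expected)
})

test_that("exons outside their parent gene are a validation error", {
  chrom <- paste(rep("ACGTT", 40), collapse = "")
  expect_error(makeTinyAnnotation(
    list(chr1 = chrom),
    c("chr1\tt\tgene\t11\t100\t.\t+\t.\tID=gBad",
      "chr1\tt\texon\t5\t50\t.\t+\t.\tID=gBad.e1;Parent=gBad")),
    "gBad")
})

test_that("GAF parsing restricts to slim terms and drops GO:0008150", {
  gaf <- tempfile(fileext = ".gaf")
  row <- function(gene, go, asp) paste(
    "DB", gene, gene, "", go, "REF", "IEA", "", asp, "", "", "protein",
    "taxon:1", "20200101", "DB", sep = "\t")
  writeLines(c("!gaf-version: 2.1",
               row("gRoot", "GO:0008150", "P"),
               row("gMulti", "GO:0000001", "P"),
               row("gMulti", "GO:0000002", "F"),
               row("gMulti", "GO:0000003", "F"),
               row("gMulti", "GO:0999999", "F"),  # not in slim
               row("gBadId", "GO:12", "P")), gaf)
  slim <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0008150")
  expect_warning(out <- readGaf(gaf, slim), "malformed GO id")
  expect_equal(out$annotation[["gRoot"]], character(0))
  expect_length(out$annotation[["gMulti"]], 3L)
  expect_equal(unname(out$domains["GO:0000002"]), "molecular_function")
})

test_that("empty GAF yields an empty annotation map", {
  gaf <- tempfile(fileext = ".gaf")
  writeLines("!gaf-version: 2.1", gaf)
  out <- readGaf(gaf, c("GO:0000001"))
  expect_length(out$annotation, 0L)
})

test_that("primer table and BED outputs follow their conventions", {
  primers <- data.frame(
    locus_id = c("l1", "l2", "l3"),
    gene_id_A = "ga", gene_id_B = "gb",
    forward = "ACGTACGTACGTACGTAC", reverse = "TGCATGCATGCATGCATG",
    tm_f = 60, tm_r = 60.5, gc_f = 50, gc_r = 50,
    product_min = 400L, product_max = 410L,
    identity = c(0.8, 0.85, 0.9), class = "exon",
    chromosome = c("chr2", "chr1", "chr1"),
    ir_genome_start = c(1000L, 50L, 900L),
    ir_genome_end = c(1450L, 500L, 1300L),
    specific = TRUE, selected = c(TRUE, FALSE, TRUE))
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  writePrimerTable(primers, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 3L)
  writeIrBed(primers, bed)
  lines <- readLines(bed)
  expect_length(lines, 3L)
  l1 <- strsplit(lines[1], "\t")[[1]]
  expect_equal(l1[1:4], c("chr2", "1000", "1450", "l1"))
  # empty tables: header-only TSV, empty BED
  writePrimerTable(primers[0, ], tsv)
  expect_equal(nrow(read.delim(tsv)), 0L)
  writeIrBed(primers[0, ], bed)
  expect_length(readLines(bed), 0L)
})
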