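#' Read a FASTA file of genome or gene sequences
#'
#' Sequences are upper-cased, U is normalized to T, and identifiers are
#' taken as the first whitespace-delimited token of the header. Characters
#' outside A/C/G/T/N are rejected: the conserved-region stage needs exact
#' identity semantics, which are undefined for ambiguity codes other than N.
#'
#' @param path Path to a FASTA file. An empty file yields an empty set.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 description", "acgtACGT"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    return(Biostrings::DNAStringSet(stats::setNames(character(0), character(0))))
  }
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L || hdr[1] != which(nzchar(trimws(lines)))[1]) {
    stop("malformed FASTA (line ", if (length(hdr)) hdr[1] else 1L,
         "): expected '>' header first", call. = FALSE)
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  seqs <- .normalizeSeq(gsub("\\s", "", seqs))
  for (i in seq_along(seqs)) {
    m <- regexpr("[^ACGTN]", seqs[i])
    if (m > 0) {
      # recover an approximate source line for the offending character
      off <- 0L
      ln <- starts[i]
      while (ln <= ends[i] && off + nchar(lines[ln]) < m) {
        off <- off + nchar(gsub("\\s", "", lines[ln]))
        ln <- ln + 1L
      }
      stop("non-IUPAC/ambiguous character in record '", ids[i],
           "' (around line ", ln, ")", call. = FALSE)
    }
  }
  names(seqs) <- ids
  Biostrings::DNAStringSet(seqs)
}

#' Read gene models from GFF3 and build a GenomeAnnotation
#'
#' GFF3 coordinates (1-based inclusive) are converted to the package's
#' internal conventions at this boundary. Exons are grouped under their
#' parent gene; minus-strand genes get a reverse-complemented unspliced
#' sequence so that all gene sequences are in transcript orientation.
#'
#' @param path Path to a GFF3 file with \code{gene} features (attribute
#'   \code{ID}) and \code{exon} features (attribute \code{Parent}).
#' @param genome A \link[Biostrings]{DNAStringSet} of chromosome sequences,
#'   e.g. from \code{\link{readGenomeFasta}}.
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
readGff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  if (length(genes) == 0L) stop("no gene features in ", path, call. = FALSE)
  gid <- as.character(genes$ID)
  if (anyNA(gid)) stop("gene feature without ID attribute", call. = FALSE)
  parent <- as.character(S4Vectors::unstrsplit(exons$Parent, ","))
  if (length(exons) && anyNA(parent))
    stop("exon feature without Parent attribute", call. = FALSE)
  miss <- setdiff(parent, gid)
  if (length(miss))
    stop("exon Parent not a known gene: ", paste(miss, collapse = ", "),
         call. = FALSE)
  # validate exon containment before constructing the object so the error
  # message names the offending gene(s)
  gspan <- stats::setNames(
    data.frame(start = BiocGenerics::start(genes),
               end = BiocGenerics::end(genes),
               chrom = as.character(GenomeInfoDb::seqnames(genes))),
    c("start", "end", "chrom"))
  rownames(gspan) <- gid
  if (length(exons)) {
    es <- BiocGenerics::start(exons)
    ee <- BiocGenerics::end(exons)
    out <- es < gspan[parent, "start"] | ee > gspan[parent, "end"] |
      as.character(GenomeInfoDb::seqnames(exons)) != gspan[parent, "chrom"]
    if (any(out))
      stop("exon outside parent gene span: ",
           paste(unique(parent[out]), collapse = ", "), call. = FALSE)
  }
  genesOut <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes),
    IRanges::IRanges(BiocGenerics::start(genes), BiocGenerics::end(genes)),
    strand = BiocGenerics::strand(genes),
    gene_id = gid)
  exl <- GenomicRanges::GRangesList(lapply(gid, function(g) {
    ex <- exons[parent == g]
    ex <- ex[BiocGenerics::order(BiocGenerics::start(ex))]
    GenomicRanges::granges(ex)
  }))
  names(exl) <- gid
  seqs <- .normalizeSeq(as.character(genome))
  .checkAlphabet(seqs, "genome")
  gseq <- vapply(seq_along(gid), function(i) {
    chrom <- gspan[gid[i], "chrom"]
    if (!chrom %in% names(seqs))
      stop("gene ", gid[i], " on unknown chromosome ", chrom, call. = FALSE)
    s <- substr(seqs[[chrom]], gspan[gid[i], "start"], gspan[gid[i], "end"])
    if (as.character(BiocGenerics::strand(genesOut))[i] == "-") .revComp(s) else s
  }, character(1))
  names(gseq) <- gid
  methods::new("GenomeAnnotation",
    genome = Biostrings::DNAStringSet(seqs),
    genes = genesOut,
    exons = exl,
    geneSeqs = Biostrings::DNAStringSet(gseq))
}

#' Read GO-slim annotations from a GAF 2.x file
#'
#' Annotations are restricted to the supplied slim terms, and the root
#' biological-process term GO:0008150 is always removed. Genes whose
#' annotations are entirely filtered out still appear, with an empty set.
#' Rows with malformed GO identifiers are skipped with a warning.
#'
#' @param path Path to a GAF 2.x file (column 2 = gene id, 5 = GO id,
#'   9 = aspect).
#' @param slimTerms Character vector of slim GO ids, e.g. from
#'   \code{\link{readSlimTerms}}.
#' @return A list with elements \code{annotation} (named list gene id ->
#'   character vector of GO ids) and \code{domains} (named character vector
#'   GO id -> \code{biological_process}/\code{molecular_function}/
#'   \code{cellular_component}).
#' @export
readGaf <- function(path, slimTerms) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(list(annotation = stats::setNames(list(), character(0)),
                domains = stats::setNames(character(0), character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 9L
  if (any(short)) {
    warning(sum(short), " GAF row(s) with fewer than 9 columns skipped")
    parts <- parts[!short]
  }
  gene <- vapply(parts, `[[`, character(1), 2L)
  goid <- vapply(parts, `[[`, character(1), 5L)
  aspect <- vapply(parts, `[[`, character(1), 9L)
  badGo <- !grepl("^GO:\\d{7}$", goid)
  if (any(badGo)) {
    warning(sum(badGo), " GAF row(s) with malformed GO id skipped: ",
            paste(utils::head(unique(goid[badGo]), 3L), collapse = ", "))
    gene <- gene[!badGo]; goid <- goid[!badGo]; aspect <- aspect[!badGo]
  }
  domMap <- c(P = "biological_process", F = "molecular_function",
              C = "cellular_component")
  keep <- goid %in% slimTerms & goid != "GO:0008150"
  ann <- lapply(split(goid[keep], factor(gene[keep], levels = unique(gene))),
                function(g) sort(unique(g)))
  domains <- stats::setNames(unname(domMap[aspect[keep]]), goid[keep])
  domains <- domains[!duplicated(names(domains))]
  list(annotation = ann, domains = domains)
}

#' Read a flat list of GO-slim term ids
#'
#' @param path Text file with one GO id per line; blank lines and lines
#'   starting with \code{!} or \code{#} are ignored.
#' @return Character vector of GO ids.
#' @export
readSlimTerms <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "!") & !startsWith(x, "#")]
  bad <- !grepl("^GO:\\d{7}$", x)
  if (any(bad))
    stop("malformed GO id in slim list: ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  unique(x)
}

#' Write the primer report table
#'
#' One TSV row per primer pair: locus and gene ids, both oligo sequences,
#' melting temperatures, GC content, predicted product-size range on each
#' reference genome, interval identity, exon/intron class and chromosome.
#'
#' @param primers A data.frame or DataFrame as found in
#'   \code{primerTable(result)}.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writePrimerTable <- function(primers, path) {
  cols <- c("locus_id", "gene_id_A", "gene_id_B", "forward", "reverse",
            "tm_f", "tm_r", "gc_f", "gc_r", "product_min", "product_max",
            "identity", "class", "chromosome", "specific", "selected")
  df <- as.data.frame(primers)
  cols <- cols[cols %in% colnames(df) | nrow(df) == 0L]
  if (nrow(df) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
  } else {
    df <- df[, cols, drop = FALSE]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 4))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write interval regions as BED6 on genome A
#'
#' @param loci A data.frame/DataFrame with columns \code{chromosome},
#'   \code{ir_genome_start}, \code{ir_genome_end} (0-based half-open),
#'   \code{locus_id} and optionally \code{identity}.
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
writeIrBed <- function(loci, path) {
  df <- as.data.frame(loci)
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- if ("identity" %in% colnames(df) && !all(is.na(df$identity))) {
    as.integer(round(1000 * ifelse(is.na(df$identity), 0, df$identity)))
  } else rep(0L, nrow(df))
  gr <- GenomicRanges::GRanges(
    df$chromosome,
    IRanges::IRanges(start = df$ir_genome_start + 1L, end = df$ir_genome_end),
    strand = "+", name = df$locus_id, score = score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
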