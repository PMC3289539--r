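#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' GenomeAnnotation: a reference genome with gene models
#'
#' Container tying chromosome sequences to gene models (span, strand,
#' exon structure) and the strand-oriented unspliced gene sequences the
#' conserved-region stage operates on.
#'
#' All plain-integer coordinate tables emitted by this package are 0-based
#' half-open; the \linkS4class{GRanges} slots follow the usual Bioconductor
#' 1-based closed convention and are converted at the boundary.
#'
#' @slot genome A \link[Biostrings]{DNAStringSet} of chromosome sequences
#'   (upper case, alphabet restricted to A/C/G/T/N).
#' @slot genes A \link[GenomicRanges]{GRanges} of gene spans with a
#'   \code{gene_id} metadata column.
#' @slot exons A \link[GenomicRanges]{GRangesList} of exon ranges, one
#'   element per gene, named by \code{gene_id} (plus-strand coordinates).
#' @slot geneSeqs A \link[Biostrings]{DNAStringSet} of unspliced gene
#'   sequences in transcript (strand) orientation, named by \code{gene_id}.
#'
#' @seealso \code{\link{readGff3}} which constructs objects of this class.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  slots = c(
    genome   = "DNAStringSet",
    genes    = "GRanges",
    exons    = "GRangesList",
    geneSeqs = "DNAStringSet"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msgs <- character(0)
  gn <- object@genes
  ids <- gn$gene_id
  if (is.null(ids)) return("genes must carry a gene_id metadata column")
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicated gene_id in genes")
  sl <- stats::setNames(BiocGenerics::width(object@genome),
                        names(object@genome))
  bad <- as.character(GenomeInfoDb::seqnames(gn)) %in% names(sl) &
    BiocGenerics::end(gn) <= sl[as.character(GenomeInfoDb::seqnames(gn))]
  if (length(gn) && !all(bad))
    msgs <- c(msgs, paste0("gene span outside chromosome sequence: ",
                           paste(ids[!bad], collapse = ", ")))
  if (!setequal(names(object@exons), ids))
    msgs <- c(msgs, "exons must be named by gene_id, one element per gene")
  if (!setequal(names(object@geneSeqs), ids))
    msgs <- c(msgs, "geneSeqs must be named by gene_id")
  if (length(gn)) {
    w <- BiocGenerics::width(gn)
    ws <- BiocGenerics::width(object@geneSeqs)[match(ids, names(object@geneSeqs))]
    if (!all(w == ws))
      msgs <- c(msgs, "unspliced sequence length must equal gene span length")
    for (i in seq_along(gn)) {
      ex <- object@exons[[ids[i]]]
      if (length(ex) == 0L) next
      if (min(BiocGenerics::start(ex)) < BiocGenerics::start(gn)[i] ||
          max(BiocGenerics::end(ex)) > BiocGenerics::end(gn)[i])
        msgs <- c(msgs, paste0("exon outside gene span for gene ", ids[i]))
      if (length(ex) > 1L) {
        o <- order(BiocGenerics::start(ex))
        if (any(BiocGenerics::start(ex)[o][-1] <=
                BiocGenerics::end(ex)[o][-length(ex)]))
          msgs <- c(msgs, paste0("overlapping exons in gene ", ids[i]))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GenomeAnnotation Compact summary of the annotation.
#' @param object A \code{GenomeAnnotation}.
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@genome), "chromosome(s) (",
      sum(BiocGenerics::width(object@genome)), "bp ) and",
      length(object@genes), "gene model(s)\n")
})

#' PrimerDesignResult: the output of a full design run
#'
#' Holds the per-stage tables produced by \code{\link{runDesign}}: conserved
#' regions, candidate loci, primer pairs, specificity verdicts, interval
#' identities, exon/intron classes, the final selection, and a per-locus
#' rejection log. All coordinates in these tables are 0-based half-open.
#'
#' @slot crs DataFrame of conserved regions per orthologous gene pair.
#' @slot loci DataFrame of candidate loci (CR pairs flanking a 300-700 bp
#'   interval region).
#' @slot primers DataFrame of designed primer pairs, one row per locus that
#'   yielded a design, including specificity verdict, identity, class and
#'   selection flag.
#' @slot log DataFrame of per-locus rejection reasons
#'   (no-CR-pair, no-primer, specificity-fail, band-fail, chromosome-quota).
#' @slot stageCounts Named integer vector of objects surviving each stage.
#' @slot config The run configuration list (see \code{\link{designConfig}}).
#' @exportClass PrimerDesignResult
setClass("PrimerDesignResult",
  slots = c(
    crs         = "DataFrame",
    loci        = "DataFrame",
    primers     = "DataFrame",
    log         = "DataFrame",
    stageCounts = "integer",
    config      = "list"
  )
)

setValidity("PrimerDesignResult", function(object) {
  need <- c("locus_id", "gene_id_A", "gene_id_B")
  if (nrow(object@primers) && !all(need %in% colnames(object@primers)))
    return(paste("primers table must contain:", paste(need, collapse = ", ")))
  TRUE
})

#' @describeIn PrimerDesignResult Per-stage summary of a design run.
#' @param object A \code{PrimerDesignResult}.
#' @export
setMethod("show", "PrimerDesignResult", function(object) {
  cat("PrimerDesignResult\n")
  sc <- object@stageCounts
  for (nm in names(sc)) cat(sprintf("  %-22s %d\n", nm, sc[[nm]]))
})
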