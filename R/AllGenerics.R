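#' Accessors for GenomeAnnotation and PrimerDesignResult
#'
#' @param x A \linkS4class{GenomeAnnotation} or
#'   \linkS4class{PrimerDesignResult}.
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{genomeSeq}: the chromosome \code{DNAStringSet}.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname accessors
#' @return \code{geneModels}: a \code{GRanges} of gene spans.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname accessors
#' @return \code{exonsByGene}: a \code{GRangesList} of exons named by gene.
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' @rdname accessors
#' @return \code{unsplicedSeqs}: strand-oriented gene sequences.
#' @export
setGeneric("unsplicedSeqs", function(x) standardGeneric("unsplicedSeqs"))

#' @rdname accessors
#' @return \code{conservedRegionTable}: DataFrame of detected CRs.
#' @export
setGeneric("conservedRegionTable",
           function(x) standardGeneric("conservedRegionTable"))

#' @rdname accessors
#' @return \code{candidateLoci}: DataFrame of CR-pair candidate loci.
#' @export
setGeneric("candidateLoci", function(x) standardGeneric("candidateLoci"))

#' @rdname accessors
#' @return \code{primerTable}: DataFrame of designed primer pairs with
#'   verdicts, identities, classes and selection flags.
#' @export
setGeneric("primerTable", function(x) standardGeneric("primerTable"))

#' @rdname accessors
#' @return \code{designLog}: DataFrame of per-locus rejection reasons.
#' @export
setGeneric("designLog", function(x) standardGeneric("designLog"))

#' @rdname accessors
#' @export
setMethod("genomeSeq", "GenomeAnnotation", function(x) x@genome)

#' @rdname accessors
#' @export
setMethod("geneModels", "GenomeAnnotation", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("exonsByGene", "GenomeAnnotation", function(x) x@exons)

#' @rdname accessors
#' @export
setMethod("unsplicedSeqs", "GenomeAnnotation", function(x) x@geneSeqs)

#' @rdname accessors
#' @export
setMethod("conservedRegionTable", "PrimerDesignResult", function(x) x@crs)

#' @rdname accessors
#' @export
setMethod("candidateLoci", "PrimerDesignResult", function(x) x@loci)

#' @rdname accessors
#' @export
setMethod("primerTable", "PrimerDesignResult", function(x) x@primers)

#' @rdname accessors
#' @export
setMethod("designLog", "PrimerDesignResult", function(x) x@log)
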