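#' Filter an ortholog table to one-to-one pairs
#'
#' Only rows with homology type \code{one2one} are retained; one-to-many
#' and many-to-many relationships are discarded to avoid designing primers
#' that could co-amplify lineage-specific paralogs. Retained ids must be
#' unique on both sides, otherwise the table is not truly one-to-one.
#'
#' @param table A data.frame whose first three columns are gene id in
#'   species A, gene id in species B, and homology type
#'   (\code{one2one}/\code{one2many}/\code{many2many}).
#' @return A data.frame with columns \code{gene_id_A}, \code{gene_id_B}.
#' @examples
#' tab <- data.frame(a = c("g1", "g2"), b = c("h1", "h2"),
#'                   type = c("one2one", "one2many"))
#' filterOrthologs(tab)
#' @export
filterOrthologs <- function(table) {
  df <- as.data.frame(table)
  if (ncol(df) < 3L)
    stop("ortholog table needs 3 columns (id A, id B, homology type)",
         call. = FALSE)
  colnames(df)[1:3] <- c("gene_id_A", "gene_id_B", "homology_type")
  keep <- df[df$homology_type == "one2one", c("gene_id_A", "gene_id_B"),
             drop = FALSE]
  dupA <- unique(keep$gene_id_A[duplicated(keep$gene_id_A)])
  dupB <- unique(keep$gene_id_B[duplicated(keep$gene_id_B)])
  if (length(dupA) || length(dupB))
    stop("gene id repeated among one2one rows: ",
         paste(c(dupA, dupB), collapse = ", "), call. = FALSE)
  rownames(keep) <- NULL
  keep
}

#' Detect perfectly identical conserved regions between two gene sequences
#'
#' Finds every maximal exact match of length >= \code{minCrLen} between the
#' two unspliced gene sequences. Matching is by strict base identity over
#' A/C/G/T; N never matches anything, so conserved regions are N-free.
#' Detection is by k-mer seeding (k = \code{minCrLen}) followed by run
#' extraction along each seeded diagonal, which is exact: any maximal match
#' of length >= k must contain a shared k-mer on its own diagonal.
#'
#' @param seqA,seqB Character scalars or \code{DNAString}s over A/C/G/T/N.
#' @param minCrLen Minimum conserved-region length in bp (default 20, the
#'   shortest block a primer can be anchored in).
#' @return A \link[S4Vectors]{DataFrame} with 0-based half-open coordinates
#'   \code{startA}, \code{endA}, \code{startB}, \code{endB}, plus
#'   \code{length} and \code{seq}, sorted by \code{startA} then
#'   \code{startB}.
#' @examples
#' findConservedRegions(
#'   paste(rep("ACGTT", 10), collapse = ""),
#'   paste(rep("ACGTT", 10), collapse = ""))
#' @export
findConservedRegions <- function(seqA, seqB, minCrLen = 20L) {
  a <- .normalizeSeq(as.character(seqA))
  b <- .normalizeSeq(as.character(seqB))
  nA <- nchar(a); nB <- nchar(b)
  empty <- S4Vectors::DataFrame(
    startA = integer(0), endA = integer(0), startB = integer(0),
    endB = integer(0), length = integer(0), seq = character(0))
  k <- as.integer(minCrLen)
  if (k < 1L) stop("minCrLen must be >= 1", call. = FALSE)
  if (nA < k || nB < k) return(empty)

  ach <- strsplit(a, "", fixed = TRUE)[[1]]
  bch <- strsplit(b, "", fixed = TRUE)[[1]]

  # seeded diagonals: diag = startA - startB (0-based)
  kmA <- substring(a, seq_len(nA - k + 1L), seq_len(nA - k + 1L) + k - 1L)
  kmB <- substring(b, seq_len(nB - k + 1L), seq_len(nB - k + 1L) + k - 1L)
  okA <- !grepl("N", kmA, fixed = TRUE)
  okB <- !grepl("N", kmB, fixed = TRUE)
  posA <- split(which(okA), kmA[okA])
  posB <- split(which(okB), kmB[okB])
  shared <- intersect(names(posA), names(posB))
  if (length(shared) == 0L) return(empty)
  diags <- unique(unlist(lapply(shared, function(km) {
    as.vector(outer(posA[[km]], posB[[km]], `-`))
  }), use.names = FALSE))

  res <- vector("list", length(diags))
  for (di in seq_along(diags)) {
    d <- diags[di]  # startA(1-based) - startB(1-based)
    lo <- max(1L, 1L + d); hi <- min(nA, nB + d)
    if (hi - lo + 1L < k) next
    iA <- lo:hi
    iB <- iA - d
    m <- ach[iA] == bch[iB] & ach[iA] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= k)
    if (length(hit) == 0L) next
    sA <- iA[starts[hit]]; eA <- iA[ends[hit]]
    res[[di]] <- data.frame(
      startA = sA - 1L, endA = eA,
      startB = sA - d - 1L, endB = eA - d,
      length = eA - sA + 1L,
      seq = substring(a, sA, eA),
      stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$startA, out$startB), , drop = FALSE]
  rownames(out) <- NULL
  S4Vectors::DataFrame(out)
}

#' Enumerate candidate loci: CR pairs flanking a 300-700 bp interval
#'
#' Every ordered pair of conserved regions whose inner gap (end of the left
#' CR to start of the right CR) lies within \code{interval}, inclusive at
#' both bounds, on \emph{both} gene sequences becomes a candidate locus.
#' The gap is the interval region (IR), the putatively polymorphic target.
#' Loci whose IRs overlap on gene A are all reported and flagged.
#'
#' @param crs Conserved regions from \code{\link{findConservedRegions}}
#'   (one orthologous gene pair).
#' @param interval Length-2 numeric: allowed IR length range in bp.
#' @return A \link[S4Vectors]{DataFrame} with the flanking CR indices
#'   (\code{left}, \code{right}, rows of \code{crs}), IR coordinates on
#'   both genes (0-based half-open), IR lengths, and an \code{overlapping}
#'   flag; sorted by \code{irStartA}.
#' @export
enumerateCandidateLoci <- function(crs, interval = c(300, 700)) {
  crs <- as.data.frame(crs)
  empty <- S4Vectors::DataFrame(
    left = integer(0), right = integer(0),
    irStartA = integer(0), irEndA = integer(0),
    irStartB = integer(0), irEndB = integer(0),
    irLenA = integer(0), irLenB = integer(0), overlapping = logical(0))
  n <- nrow(crs)
  if (n < 2L) return(empty)
  idx <- expand.grid(left = seq_len(n), right = seq_len(n))
  idx <- idx[idx$left != idx$right, , drop = FALSE]
  gA <- crs$startA[idx$right] - crs$endA[idx$left]
  gB <- crs$startB[idx$right] - crs$endB[idx$left]
  ok <- gA >= interval[1] & gA <= interval[2] &
    gB >= interval[1] & gB <= interval[2]
  idx <- idx[ok, , drop = FALSE]
  if (nrow(idx) == 0L) return(empty)
  out <- data.frame(
    left = idx$left, right = idx$right,
    irStartA = crs$endA[idx$left], irEndA = crs$startA[idx$right],
    irStartB = crs$endB[idx$left], irEndB = crs$startB[idx$right])
  out$irLenA <- out$irEndA - out$irStartA
  out$irLenB <- out$irEndB - out$irStartB
  out <- out[order(out$irStartA, out$irEndA), , drop = FALSE]
  ov <- rep(FALSE, nrow(out))
  if (nrow(out) > 1L) {
    for (i in seq_len(nrow(out))) {
      ov[i] <- any(out$irStartA[-i] < out$irEndA[i] &
                   out$irEndA[-i] > out$irStartA[i])
    }
  }
  out$overlapping <- ov
  rownames(out) <- NULL
  S4Vectors::DataFrame(out)
}
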