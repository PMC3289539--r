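# Internal sequence helpers. Coordinates in all plain-integer arguments are
# 0-based half-open; R's 1-based substr() is confined to these two helpers.

.sliceSeq <- function(x, start0, end0) substr(x, start0 + 1L, end0)

.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.normalizeSeq <- function(x) chartr("U", "T", toupper(x))

# A/C/G/T/N only; other IUPAC ambiguity codes are rejected on load because
# perfect-identity semantics are undefined for them.
.checkAlphabet <- function(x, what) {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-A/C/G/T/N character in ", what, ": ",
         paste(utils::head(names(x)[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

.gcPercent <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  100 * gc / n
}

.maxHomopolymerRun <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    if (length(ch) == 0L) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}

# Restore the caller's RNG state after seeded work.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
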