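#' Exact hypergeometric enrichment p-value for one GO term
#'
#' Draws without replacement: a study set of \code{nStudy} genes from a
#' population of \code{nPopulation}, of which \code{kAnnotated} carry the
#' term. When the observed count is at or above its expectation
#' \code{nStudy * kAnnotated / nPopulation} the upper tail
#' \code{P(X >= obs)} is returned (over-representation), otherwise the
#' lower tail \code{P(X <= obs)} (under-representation). Tails are exact
#' sums of hypergeometric mass, no normal approximation.
#'
#' @param obs Observed number of study genes carrying the term.
#' @param kAnnotated Number of population genes carrying the term.
#' @param nPopulation Population size.
#' @param nStudy Study-set size.
#' @return List with \code{p} and \code{direction}
#'   (\code{over}/\code{under}).
#' @examples
#' hypergeomPvalue(4, 5, 10, 4)  # 5/210
#' @export
hypergeomPvalue <- function(obs, kAnnotated, nPopulation, nStudy) {
  if (kAnnotated > nPopulation || nStudy > nPopulation ||
      obs > min(kAnnotated, nStudy) || obs < 0)
    stop("inconsistent hypergeometric counts", call. = FALSE)
  expected <- nStudy * kAnnotated / nPopulation
  if (obs >= expected) {
    list(p = stats::phyper(obs - 1, kAnnotated, nPopulation - kAnnotated,
                           nStudy, lower.tail = FALSE),
         direction = "over")
  } else {
    list(p = stats::phyper(obs, kAnnotated, nPopulation - kAnnotated,
                           nStudy),
         direction = "under")
  }
}

#' Resampled null mean and spread of per-term study counts
#'
#' Draws \code{reps} random study sets of size \code{nStudy} from the
#' population without replacement and records, for every GO term, the mean
#' and standard deviation of the number of annotated genes per draw. These
#' are the resampled expectations behind the reported Z scores.
#'
#' @param annotation Named list gene id -> character vector of GO ids.
#' @param population Character vector of population gene ids.
#' @param nStudy Study-set size.
#' @param reps Number of resampling draws (>= 100).
#' @param seed Integer seed; fixes the draws bit-identically.
#' @return A data.frame with \code{go_id}, \code{mean}, \code{sd}.
#' @export
resampleNull <- function(annotation, population, nStudy, reps = 10000L,
                         seed = 1L) {
  if (reps < 100L) stop("reps must be >= 100", call. = FALSE)
  if (nStudy > length(population))
    stop("study size exceeds population size", call. = FALSE)
  terms <- sort(unique(unlist(annotation[population], use.names = FALSE)))
  if (length(terms) == 0L) {
    return(data.frame(go_id = character(0), mean = numeric(0),
                      sd = numeric(0)))
  }
  M <- vapply(terms, function(tm) {
    vapply(population, function(g) tm %in% annotation[[g]], logical(1))
  }, logical(length(population)))
  M <- matrix(M, nrow = length(population), dimnames = list(population, terms))
  sums <- numeric(length(terms))
  sq <- numeric(length(terms))
  .withSeed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(length(population), nStudy)
      cnt <- colSums(M[idx, , drop = FALSE])
      sums <- sums + cnt
      sq <- sq + cnt * cnt
    }
  })
  mu <- sums / reps
  va <- (sq - reps * mu * mu) / (reps - 1)
  va[va < 0] <- 0
  data.frame(go_id = terms, mean = mu, sd = sqrt(va), row.names = NULL)
}

#' GO-slim term enrichment of primer-bearing genes
#'
#' For every slim term annotating at least one population gene: the
#' observed study count, the resampled null mean and standard deviation,
#' the Z score \code{(obs - mean)/sd}, the exact hypergeometric one-sided
#' p-value (over- or under-representation, whichever side the observation
#' falls on), and a Bonferroni-adjusted p-value with multiplicity equal to
#' the number of tested terms in the same GO domain.
#'
#' @param annotation Named list gene id -> GO ids (slim-restricted,
#'   GO:0008150 excluded; see \code{\link{readGaf}}).
#' @param domains Named character vector GO id -> GO domain.
#' @param study Character vector of study gene ids (genes with at least
#'   one primer site). Must be a subset of the population.
#' @param population Character vector of population gene ids (genes with
#'   at least one GO id); defaults to all annotated genes.
#' @param reps,seed Resampling control, see \code{\link{resampleNull}}.
#' @return A data.frame sorted by adjusted p: \code{domain}, \code{go_id},
#'   \code{obs}, \code{mean}, \code{sd}, \code{z}, \code{p}, \code{p_adj},
#'   \code{direction}, \code{significant} (\code{p_adj < 0.05}).
#' @export
enrichGoTerms <- function(annotation, domains, study, population = NULL,
                          reps = 10000L, seed = 1L) {
  if (is.null(population))
    population <- names(annotation)[lengths(annotation) > 0L]
  if (length(study) == 0L)
    stop("empty study set: no primer-bearing genes with GO annotation",
         call. = FALSE)
  if (!all(study %in% population))
    stop("study genes outside population: ",
         paste(utils::head(setdiff(study, population), 3L), collapse = ", "),
         call. = FALSE)
  terms <- sort(unique(unlist(annotation[population], use.names = FALSE)))
  terms <- terms[terms %in% names(domains)]
  if (length(terms) == 0L) stop("no annotated terms to test", call. = FALSE)
  null <- resampleNull(annotation, population, length(study),
                       reps = reps, seed = seed)
  res <- do.call(rbind, lapply(terms, function(tm) {
    kAnn <- sum(vapply(population, function(g) tm %in% annotation[[g]],
                       logical(1)))
    obs <- sum(vapply(study, function(g) tm %in% annotation[[g]],
                      logical(1)))
    hp <- hypergeomPvalue(obs, kAnn, length(population), length(study))
    i <- match(tm, null$go_id)
    z <- if (null$sd[i] > 0) (obs - null$mean[i]) / null$sd[i] else NA_real_
    data.frame(domain = unname(domains[tm]), go_id = tm, k = kAnn,
               obs = obs, mean = null$mean[i], sd = null$sd[i], z = z,
               p = hp$p, direction = hp$direction)
  }))
  m <- table(res$domain)
  res$p_adj <- pmin(1, res$p * as.numeric(m[res$domain]))
  res$significant <- res$p_adj < 0.05
  res <- res[order(res$p_adj, res$p, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
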