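test_that("hypergeometric p-values are exact", {
  hp <- hypergeomPvalue(4, 5, 10, 4)
  expect_equal(hp$p, 5 / 210, tolerance = 1e-12)
  expect_equal(hp$direction, "over")
  # observation at the expectation: upper tail, p >= 0.5
  hp2 <- hypergeomPvalue(5, 10, 20, 10)
  expect_equal(hp2$direction, "over")
  expect_gte(hp2$p, 0.5)
  # degenerate term
  expect_equal(hypergeomPvalue(0, 0, 30, 5)$p, 1)
  expect_error(hypergeomPvalue(6, 5, 10, 4), "inconsistent")
})

test_that("tails agree with direct mass summation for all N <= 60", {
  worst <- 0
  checked <- 0L
  for (N in 1:60) {
    for (K in 0:N) {
      for (n in unique(c(0L, 1L, N %/% 3, N %/% 2, N))) {
        expected <- n * K / N
        for (o in 0:min(K, n)) {
          p <- hypergeomPvalue(o, K, N, n)$p
          want <- oracleHyperTail(o, K, N, n, upper = o >= expected)
          worst <- max(worst, abs(p - want))
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 50000L)
  expect_lt(worst, 1e-12)
})

test_that("resampled null means converge to the hypergeometric mean", {
  genes <- sprintf("g%02d", 1:40)
  ann <- setNames(lapply(seq_along(genes), function(i) {
    c(if (i <= 12) "GO:0000001", if (i %% 2 == 0) "GO:0000002")
  }), genes)
  null <- resampleNull(ann, genes, nStudy = 10, reps = 10000, seed = 3)
  # K = 12, N = 40, n = 10 -> mean 3; K = 20 -> mean 5
  k1 <- null[null$go_id == "GO:0000001", ]
  se1 <- k1$sd / sqrt(10000)
  expect_lt(abs(k1$mean - 3), 3 * se1 + 1e-9)
  k2 <- null[null$go_id == "GO:0000002", ]
  expect_lt(abs(k2$mean - 5), 3 * k2$sd / sqrt(10000) + 1e-9)
  # a term annotating everything: mean nStudy, sd 0
  annAll <- setNames(rep(list("GO:0000009"), 40), genes)
  nullAll <- resampleNull(annAll, genes, nStudy = 7, reps = 200, seed = 1)
  expect_equal(nullAll$mean, 7)
  expect_equal(nullAll$sd, 0)
})

test_that("resampling is bit-identical under a fixed seed", {
  genes <- sprintf("g%d", 1:30)
  ann <- setNames(lapply(1:30, function(i) {
    if (i %% 3 == 0) "GO:0000005" else character(0)
  }), genes)
  a <- resampleNull(ann, genes, 8, reps = 500, seed = 11)
  b <- resampleNull(ann, genes, 8, reps = 500, seed = 11)
  expect_identical(a, b)
})

test_that("Bonferroni adjustment is per GO domain", {
  genes <- sprintf("g%d", 1:20)
  ann <- setNames(lapply(1:20, function(i) {
    c(if (i <= 10) "GO:0000001", if (i > 6) "GO:0000011")
  }), genes)
  domains <- c("GO:0000001" = "biological_process",
               "GO:0000011" = "molecular_function")
  res <- enrichGoTerms(ann, domains, study = genes[1:6],
                       population = genes, reps = 200, seed = 2)
  # one tested term per domain: p_adj == p
  expect_equal(res$p_adj, pmin(1, res$p))
  expect_error(enrichGoTerms(ann, domains, character(0), genes),
               "empty study")
})

test_that("a planted enriched term attains the smallest adjusted p", {
  set.seed(4)
  genes <- sprintf("g%03d", 1:60)
  terms <- sprintf("GO:%07d", 1:6)
  domains <- setNames(rep(c("biological_process", "molecular_function",
                            "cellular_component"), 2), terms)
  ann <- setNames(lapply(seq_along(genes), function(i) {
    unique(c(terms[1 + (i %% 6)], if (i %% 4 == 0) terms[1]))
  }), genes)
  pool <- names(ann)[vapply(ann, function(x) "GO:0000001" %in% x,
                            logical(1))]
  study <- c(sample(pool, 8), sample(setdiff(genes, pool), 2))
  res <- enrichGoTerms(ann, domains, study, genes, reps = 2000, seed = 5)
  top <- res[1, ]
  expect_equal(top$go_id, "GO:0000001")
  expect_equal(top$direction, "over")
  expect_equal(res$p_adj, sort(res$p_adj))
})

test_that("type-I error is near or below nominal under random study sets", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:80)
  terms <- sprintf("GO:%07d", 1:8)
  domains <- setNames(rep("biological_process", 8), terms)
  ann <- setNames(lapply(seq_along(genes), function(i) {
    sample(terms, 3)
  }), genes)
  hits <- 0L; total <- 0L
  for (draw in 1:60) {
    study <- sample(genes, 15)
    res <- enrichGoTerms(ann, domains, study, genes, reps = 100,
                         seed = draw)
    hits <- hits + sum(res$p < 0.05)
    total <- total + nrow(res)
  }
  frac <- hits / total
  # exact one-sided discrete tests are conservative; allow Monte-Carlo slack
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("Z scores and p-values rank concordantly", {
  set.seed(7)
  genes <- sprintf("g%03d", 1:70)
  terms <- sprintf("GO:%07d", 1:10)
  domains <- setNames(rep("biological_process", 10), terms)
  ann <- setNames(lapply(seq_along(genes), function(i) {
    sample(terms, sample(1:4, 1))
  }), genes)
  res <- enrichGoTerms(ann, domains, sample(genes, 20), genes,
                       reps = 3000, seed = 8)
  ok <- !is.na(res$z)
  expect_lt(cor(res$p[ok], abs(res$z[ok]), method = "spearman"), 0)
  # sign of z matches the reported direction
  expect_true(all((res$z[ok] >= 0) == (res$direction[ok] == "over") |
                  abs(res$z[ok]) < 0.5))
})
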