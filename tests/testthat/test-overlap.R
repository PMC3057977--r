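test_that("support counting reproduces the consistent-gene table counts", {
  cg <- consistent_gene_calls()
  s <- count_support(cg$calls, roster = cg$roster, up_only = cg$up_only)
  expect_equal(sum(s$support_count == 5), 2L)
  expect_setequal(s$gene[s$support_count == 5], c("CD24", "MAL2"))
  s4 <- s[s$support_count == 4, ]
  expect_equal(nrow(s4), 14L)
  expect_true(all(s4$consensus_direction == "up"))
})

test_that("support counting basics: single calls, conflicts, up-only guard", {
  one <- data.frame(gene = "G1", dataset = "d1", direction = "down")
  s <- count_support(one)
  expect_equal(s$support_count, 1L)
  expect_equal(s$consensus_direction, "down")

  conf <- data.frame(gene = c("G1", "G1"), dataset = c("d1", "d1"),
                     direction = c("up", "down"))
  expect_error(count_support(conf), "conflict")

  # a gene called only in up-only datasets can never be down-consistent
  up <- data.frame(gene = c("G1", "G2"), dataset = c("d9", "d9"),
                   direction = c("down", "up"))
  expect_warning(s2 <- count_support(up, roster = "d9", up_only = "d9"),
                 "up-only")
  expect_false("G1" %in% s2$gene)
  expect_equal(s2$consensus_direction[s2$gene == "G2"], "up")
})

test_that("support counting is invariant to input row order", {
  cg <- consistent_gene_calls()
  set.seed(1)
  shuf <- cg$calls[sample(nrow(cg$calls)), ]
  s1 <- count_support(cg$calls, roster = cg$roster, up_only = cg$up_only)
  s2 <- count_support(shuf, roster = cg$roster, up_only = cg$up_only)
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("estrous intersection carries stage and rejects raw symbols", {
  s <- data.frame(gene = c("EPCAM", "NUAK2", "OTHER1"),
                  support_count = c(4L, 3L, 1L),
                  consensus_direction = "up", stringsAsFactors = FALSE)
  est <- data.frame(hugo_symbol = c("EPCAM", "NUAK2", "XYZ9"),
                    stage = c("PE", "PE", "EM"), stringsAsFactors = FALSE)
  ov <- intersect_with_estrous(s, est)
  expect_setequal(ov$gene, c("EPCAM", "NUAK2"))
  expect_true(all(ov$estrous_stage == "PE"))

  expect_equal(nrow(intersect_with_estrous(
    s, data.frame(hugo_symbol = "ZZZ9", stage = "PE"))), 0L)

  est_bad <- data.frame(hugo_symbol = c("Epcam"), stage = "PE")
  expect_error(intersect_with_estrous(s, est_bad), "unharmonized")
})

test_that("enrichment chi-square agrees with the hypergeometric oracle", {
  # null identity: overlap at its expectation
  r0 <- test_overlap_enrichment(6, 20, 30, 100)
  expect_lt(r0$chisq, 1e-10)
  expect_equal(r0$p_chisq, 1, tolerance = 1e-6)
  expect_equal(r0$expected_overlap, 6)

  # toy table: universe 100, lists 20 and 30, overlap 12
  r <- test_overlap_enrichment(12, 20, 30, 100)
  tail_oracle <- sum(sapply(12:20, function(k)
    choose(20, k) * choose(80, 30 - k) / choose(100, 30)))
  expect_equal(r$p_exact, tail_oracle, tolerance = 1e-12)
  expect_lt(r$p_chisq, 0.05)
  expect_lt(abs(log10(r$p_chisq) - log10(r$p_exact)), 1)

  # study-scale counts: overlap of 338 between 905 and 7285. Enrichment
  # depends critically on the (unstated) universe: the expectation is
  # 905*7285/N, so only universes above ~24000 genes make 338 an excess.
  # Supplying the union of unique genes across five platforms (~25000)
  # reproduces a far-below-1e-4 significance.
  rp <- test_overlap_enrichment(338, 905, 7285, 25000)
  expect_lt(rp$p_chisq, 1e-4)
  expect_lt(rp$p_exact, 1e-4)
})

test_that("enrichment p decreases monotonically in the overlap count", {
  ps <- sapply(6:18, function(k)
    test_overlap_enrichment(k, 20, 30, 100)$p_exact)
  expect_true(all(diff(ps) < 0))
})

test_that("tiny expected cells suppress the chi-square but keep the exact test", {
  r <- test_overlap_enrichment(1, 2, 3, 10000)
  expect_true(is.na(r$chisq))
  expect_false(is.na(r$p_exact))
})

test_that("null synthetic overlaps reject at or below the nominal rate", {
  set.seed(99)
  n_univ <- 400; n_a <- 60; n_b <- 80
  rej <- replicate(100, {
    a <- sample(n_univ, n_a); b <- sample(n_univ, n_b)
    test_overlap_enrichment(length(intersect(a, b)), n_a, n_b,
                            n_univ)$p_exact < 0.05
  })
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("candidate ranking follows support, fold change, then symbol", {
  cg <- consistent_gene_calls()
  s <- count_support(cg$calls, roster = cg$roster, up_only = cg$up_only)
  rk <- rank_candidates(s, reference_dataset = "tothill")
  expect_equal(rk$gene[1:2], c("CD24", "MAL2"))  # both support 5; 68.6 > 3.4

  # all-equal evidence falls back to alphabetical order
  eq <- data.frame(gene = c("BBB", "AAA", "CCC"), support_count = 2L,
                   consensus_direction = "up", fc_d1 = "2.0",
                   stringsAsFactors = FALSE)
  expect_equal(rank_candidates(eq)$gene, c("AAA", "BBB", "CCC"))

  # permuting input rows leaves the ranking unchanged
  set.seed(5)
  rk2 <- rank_candidates(s[sample(nrow(s)), ], reference_dataset = "tothill")
  expect_equal(rk2$gene, rk$gene)

  # qualitative fold changes order after numeric ones
  q <- data.frame(gene = c("QUAL", "NUM"), support_count = 3L,
                  consensus_direction = "up", fc_d1 = c(">3", "2.1"),
                  stringsAsFactors = FALSE)
  expect_equal(rank_candidates(q)$gene, c("NUM", "QUAL"))
})
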