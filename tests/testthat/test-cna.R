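test_that("gain/loss calls use strict thresholds on ratios and frequencies", {
  # 10-sample toy: exactly 3/10 samples above 0.3 -> neutral (strict >30%)
  vals <- rbind(at_thr = c(rep(0.5, 3), rep(0, 7)),
                above = c(rep(0.5, 4), rep(0, 6)),
                loss4 = c(rep(-0.5, 4), rep(0, 6)),
                flat = rep(0, 10),
                boundary = c(rep(0.3, 10)))   # ratio exactly 0.3 never counts
  cc <- call_cna(list(gene_ids = rownames(vals), values = vals))
  expect_equal(cc$call, c("neutral", "gain", "loss", "neutral", "neutral"))
  expect_equal(cc$gain_freq[2], 0.4)

  # precomputed frequencies follow the same strict rule
  freq <- data.frame(gene = c("a", "b", "c"),
                     gain_freq = c(0.30, 0.31, 0),
                     loss_freq = c(0, 0, 0.57))
  cf <- call_cna(freq)
  expect_equal(cf$call, c("neutral", "gain", "loss"))

  expect_error(call_cna(data.frame(gene = "x", gain_freq = 0.7,
                                   loss_freq = 0.6)), "exceeds 1|> 1")
  expect_error(call_cna(data.frame(gene = "x")), "frequencies|ratios")
})

test_that("peak-region membership qualifies genes below the frequency cut", {
  freq <- data.frame(gene = c("inpeak", "nopeak"),
                     gain_freq = c(0.29, 0.29), loss_freq = 0,
                     in_peak_region = c(TRUE, FALSE),
                     peak_direction = c("gain", "gain"))
  cc <- call_cna(freq)
  expect_equal(cc$call, c("gain", "neutral"))
})

test_that("raising the frequency threshold never creates new aberration calls", {
  set.seed(21)
  vals <- matrix(rnorm(50 * 40, sd = 0.3), 50,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  prof <- list(gene_ids = rownames(vals), values = vals)
  thr <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  calls <- lapply(thr, function(f) call_cna(prof, freq_thr = f)$call)
  for (i in seq_along(thr)[-1])
    expect_true(all(calls[[i]] == "neutral" | calls[[i]] == calls[[i - 1]]))
})

test_that("dual-source consensus requires agreement and reports exclusions", {
  calls <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3", "g3", "g4"),
    source = c("A", "B", "A", "B", "A", "B", "A"),
    call = c("gain", "gain", "gain", "loss", "gain", "neutral", "loss"))
  res <- dual_source_consensus(calls, sources = c("A", "B"))
  expect_equal(res$consensus$gene, "g1")
  expect_equal(res$consensus$call, "gain")
  expect_equal(res$excluded$reason[res$excluded$gene == "g2"], "DISCORDANT")
  expect_equal(res$excluded$reason[res$excluded$gene == "g3"], "NO_ABERRATION")
  expect_equal(res$excluded$reason[res$excluded$gene == "g4"], "SINGLE_SOURCE")
  expect_error(dual_source_consensus(calls, sources = c("A", "B", "C")),
               "two sources")
})

test_that("consensus and concordance are invariant to source order", {
  ct <- cna_table_calls()
  r1 <- dual_source_consensus(ct$calls, sources = c("gorringe", "tcga"))
  r2 <- dual_source_consensus(ct$calls, sources = c("tcga", "gorringe"))
  expect_setequal(r1$consensus$gene, r2$consensus$gene)
  c1 <- test_expression_concordance(r1$consensus, ct$directions)
  c2 <- test_expression_concordance(r2$consensus, ct$directions)
  expect_setequal(c1$concordant, c2$concordant)
})

test_that("expression concordance classifies directions and excludes inconsistents", {
  cons <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     call = c("gain", "gain", "loss", "gain"))
  dirs <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     direction = c("up", "down", "down", "inconsistent"))
  r <- test_expression_concordance(cons, dirs)
  expect_setequal(r$concordant, c("g1", "g3"))
  expect_equal(r$n_tested, 3L)
  expect_equal(r$excluded$gene, "g4")
  expect_equal(r$excluded$reason, "INCONSISTENT_DIRECTION")
})

test_that("random direction assignment shows chance-level concordance", {
  set.seed(31)
  cons <- data.frame(gene = sprintf("g%02d", 1:64),
                     call = rep(c("gain", "loss"), c(40, 24)))
  fracs <- replicate(200, {
    dirs <- data.frame(gene = cons$gene,
                       direction = sample(c("up", "down"), 64, TRUE))
    test_expression_concordance(cons, dirs)$n_concordant / 64
  })
  expect_equal(mean(fracs), 0.5, tolerance = 0.02)
})

test_that("frequency estimates tighten as 1/sqrt(n)", {
  cfg <- sim_config(seed = 5)
  err_at <- function(n) {
    m <- generate_cna_matrix(cfg, sprintf("g%02d", 1:40),
                             gain_genes = sprintf("g%02d", 1:40),
                             n_samples = n, seed = 11)
    mean(abs(rowMeans(m > 0.3) - cfg$cna_gain_freq))
  }
  e1 <- err_at(50); e2 <- err_at(5000)
  expect_lt(e2, e1 / 5)  # 100x samples: ~10x tighter
})

test_that("chromosome arm parsing and region grouping match enumeration", {
  expect_equal(cytoband_arm(c("8q24.3", "12pter-q12", "1q21.1", "19", "Xp11")),
               c("8q", "12p", "1q", NA, "Xp"))

  # toy 3-gene group over 4 patients: calls {all 3, 2 of 3, 1 of 3, none}
  calls <- cbind(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
                 c(TRUE, FALSE, FALSE), c(FALSE, FALSE, FALSE))
  rownames(calls) <- c("a", "b", "c")
  genes <- data.frame(gene = c("a", "b", "c"),
                      cytoband = c("1q23", "1q21.1", "1q21"))
  rg <- summarize_region_groups(genes, calls)
  expect_equal(rg$group, "1q")
  expect_equal(rg$n_patients_any, 3L)
  expect_equal(rg$n_patients_all, 1L)
  expect_equal(rg$fraction_all, 1 / 3)

  # single-gene groups fall into the remainder; unparseable too
  g2 <- data.frame(gene = c("a", "b", "c", "d"),
                   cytoband = c("1q23", "1q21", "5p15", "19"))
  rg2 <- summarize_region_groups(g2, min_group = 2)
  expect_equal(rg2$group, c("1q", "remainder"))
  expect_equal(rg2$n_genes, c(2L, 2L))

  # the published gain table groups into the five expected arm blocks
  ct <- cna_table_calls()
  gain_loc <- ct$locations[1:27, ]
  rg3 <- summarize_region_groups(gain_loc)
  expect_equal(rg3$n_genes[match(c("1q", "3q", "8q", "12p", "20q"),
                                 rg3$group)],
               c(3L, 6L, 4L, 5L, 7L))
  expect_equal(rg3$n_genes[rg3$group == "remainder"], 2L)
})
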