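test_that("configuration validation names the offending field", {
  expect_error(sim_config(planted_overlap = 1000, n_estrous_genes = 900),
               "planted_overlap")
  expect_error(sim_config(per_dataset_de_sizes = c(50, 99999),
                          n_genes_universe = 1000), "per_dataset_de_sizes")
  expect_error(sim_config(censor_rate = 1.2), "censor_rate")
  expect_error(sim_config(cna_gain_freq = 0.6, cna_loss_freq = 0.6),
               "cna_gain_freq")
})

test_that("generated studies honor the configured dimensions and truth", {
  cfg <- sim_config(n_genes_universe = 1200, n_estrous_genes = 80,
                    per_dataset_de_sizes = c(200, 120, 60, 20, 15),
                    planted_overlap = 25, samples_per_group = 5, seed = 23)
  st <- generate_study(cfg)
  expect_equal(lengths(st$truth$per_dataset_de),
               c(200L, 120L, 60L, 20L, 15L))
  expect_equal(length(st$truth$overlap_genes), 25L)
  # truth genes are estrous orthologs
  expect_true(all(st$truth$overlap_genes %in% st$ortholog_map$hugo_symbol))
  # every planted overlap gene is dysregulated in at least one dataset
  expect_true(all(st$truth$overlap_genes %in%
                    unlist(st$truth$per_dataset_de)))
  # matrices have the configured shape
  for (m in st$expression_matrices) {
    expect_equal(dim(m$values), c(1200L, 10L))
    expect_equal(nlevels(m$groups), 2L)
  }
  # planted genes have group-mean difference = effect (up to noise);
  # unplanted genes ~0
  m1 <- st$expression_matrices[[1]]
  tum <- m1$groups == "tumor"
  diff <- rowMeans(m1$values[, tum]) - rowMeans(m1$values[, !tum])
  de1 <- m1$gene_ids %in% st$truth$per_dataset_de[[1]]
  dirs <- st$truth$directions$direction[match(m1$gene_ids,
                                              st$truth$directions$gene)]
  expect_equal(mean(abs(diff[de1])), cfg$de_log2_effect,
               tolerance = 0.05)
  # non-DE mean |difference| concentrates near its noise expectation
  # noise_sd * sqrt(2/n) * sqrt(2/pi)
  null_exp <- cfg$noise_sd * sqrt(2 / cfg$samples_per_group) * sqrt(2 / pi)
  expect_equal(mean(abs(diff[!de1])), null_exp, tolerance = 0.1)
  expect_true(all(sign(diff[de1]) == ifelse(dirs[de1] == "up", 1, -1)))
})

test_that("generation is deterministic in the seed and distinct across seeds", {
  cfg <- sim_config(n_genes_universe = 500, n_estrous_genes = 40,
                    per_dataset_de_sizes = c(60, 30), planted_overlap = 10,
                    samples_per_group = 4, seed = 77)
  a <- generate_study(cfg); b <- generate_study(cfg)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 78L
  c2 <- generate_study(cfg2)
  expect_false(identical(a$expression_matrices[[1]]$values,
                         c2$expression_matrices[[1]]$values))
})

test_that("zero effect makes the truth set behave as a null", {
  cfg <- sim_config(n_genes_universe = 400, n_estrous_genes = 40,
                    per_dataset_de_sizes = c(80, 40), planted_overlap = 10,
                    samples_per_group = 5, de_log2_effect = 0, seed = 31)
  st <- generate_study(cfg)
  m <- st$expression_matrices[[1]]
  res <- suppressMessages(call_de(m$values, m$gene_ids, m$groups,
                                  n_permutations = 252, seed = 2))
  expect_lte(mean(res$de_call), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("copy-number generator hits the planted frequencies", {
  cfg <- sim_config(cna_gain_freq = 0.4, cna_loss_freq = 0.3, seed = 3)
  genes <- sprintf("g%02d", 1:30)
  m <- generate_cna_matrix(cfg, genes, gain_genes = genes[1:10],
                           loss_genes = genes[11:20], n_samples = 500)
  # per-gene gain frequency within the exact binomial 99% interval
  lo <- qbinom(0.005, 500, 0.4) / 500; hi <- qbinom(0.995, 500, 0.4) / 500
  gf <- rowMeans(m[1:10, ] > 0.3)
  expect_true(all(gf >= lo & gf <= hi))
  lf <- rowMeans(m[11:20, ] < -0.3)
  lo2 <- qbinom(0.005, 500, 0.3) / 500; hi2 <- qbinom(0.995, 500, 0.3) / 500
  expect_true(all(lf >= lo2 & lf <= hi2))
  # unplanted genes stay within the noise tail
  expect_true(all(rowMeans(abs(m[21:30, ]) > 0.3) < 0.01))
  expect_error(generate_cna_matrix(cfg, genes, gain_genes = genes[1],
                                   loss_genes = genes[1]),
               "both gain and loss")

  # two sources with shared truth correlate gene-wise
  m2 <- generate_cna_matrix(cfg, genes, gain_genes = genes[1:10],
                            loss_genes = genes[11:20], n_samples = 500,
                            seed = 99)
  f1 <- rowMeans(m > 0.3) - rowMeans(m < -0.3)
  f2 <- rowMeans(m2 > 0.3) - rowMeans(m2 < -0.3)
  expect_gt(cor(f1, f2), 0.9)
})

test_that("IHC/survival generator matches its configured cohort", {
  cfg <- sim_config(n_patients = 96, censor_rate = 0, seed = 41)
  gs <- generate_ihc_and_survival(cfg)
  expect_equal(nrow(gs$survival), 96L)
  expect_true(all(gs$survival$event))          # censor_rate 0
  sums <- with(gs$staining, pct_strong + pct_moderate + pct_weak +
                 pct_negative)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(gs$scores$score >= 0 & gs$scores$score <= 3))

  # KM medians recover the configured exponential medians at n = 500/grp
  cfg2 <- sim_config(n_patients = 1000, censor_rate = 0,
                     survival_median_by_group = c(low = 22, high = 42),
                     seed = 43)
  gs2 <- generate_ihc_and_survival(cfg2)
  km <- lapply(split(gs2$survival, gs2$survival$stratum), km_estimate)
  expect_equal(km$low$median, 22, tolerance = 0.15)
  expect_equal(km$high$median, 42, tolerance = 0.15)
})

test_that("study export writes readable tables and a manifest", {
  cfg <- sim_config(n_genes_universe = 300, n_estrous_genes = 30,
                    per_dataset_de_sizes = c(40, 20), planted_overlap = 8,
                    samples_per_group = 3, seed = 51)
  st <- generate_study(cfg)
  dir <- tempfile("study")
  write_study(st, dir)
  m <- read_expression_matrix(file.path(dir, "expr_dataset1.tsv"))
  expect_equal(dim(m$values), dim(st$expression_matrices[[1]]$values))
  expect_equal(unname(m$values[5, 2]),
               unname(st$expression_matrices[[1]]$values[5, 2]),
               tolerance = 1e-9)
  expect_equal(as.character(m$groups),
               as.character(st$expression_matrices[[1]]$groups))
  man <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  expect_equal(man$seed, 51L)
  expect_equal(man$n_genes_universe, 300L)
  om <- read_ortholog_map(file.path(dir, "ortholog_map.tsv"))
  expect_equal(nrow(om), nrow(st$ortholog_map))
})
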