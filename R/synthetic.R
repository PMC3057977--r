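#' Synthetic study generator with planted ground truth
#'
#' Generates every input the prioritization pipeline consumes -- an
#' ortholog map, a murine estrous-regulated gene list, two-class log2
#' expression matrices for a configurable number of human datasets,
#' dual-source copy-number matrices, a mutation catalog, staining
#' profiles and survival records -- with known planted truth, so the
#' full pipeline is testable without external data. Defaults mirror the
#' emulated study design: five datasets with 5868/3479/1084/86/69
#' differentially expressed genes, a 905-gene estrous signature with a
#' 338-gene planted overlap, and a 96-patient survival cohort with
#' group medians of 22 and 42 months.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Validates and assembles the configuration for
#' \code{\link{generate_study}} and friends.
#'
#' @param n_genes_universe number of genes in the measured universe.
#' @param n_estrous_genes size of the murine estrous-regulated list.
#' @param per_dataset_de_sizes integer vector; number of planted
#'   dysregulated genes per human dataset.
#' @param planted_overlap number of estrous genes planted as
#'   dysregulated (the recoverable truth).
#' @param samples_per_group samples per class in each expression matrix.
#' @param de_log2_effect group-mean difference (log2 units) for planted
#'   genes.
#' @param noise_sd per-observation Gaussian noise SD (log2 units).
#' @param cna_gain_freq per-sample probability of gain for planted-gain
#'   genes.
#' @param cna_loss_freq per-sample probability of loss for planted-loss
#'   genes.
#' @param mutation_rate fraction of overlap genes given mutation
#'   records.
#' @param survival_median_by_group named numeric (months), e.g.
#'   \code{c(low = 22, high = 42)}.
#' @param censor_rate fraction of survival records censored.
#' @param n_patients survival/IHC cohort size.
#' @param frac_one_to_many fraction of estrous genes given a second
#'   human ortholog (exercises 1:many handling).
#' @param frac_unmapped fraction of estrous genes left without an
#'   ortholog row.
#' @param frac_pe fraction of estrous genes regulated at proestrus
#'   evening (PE) rather than estrus morning (EM).
#' @param seed integer seed; all generation is deterministic given it.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_genes_universe = 18000,
                       n_estrous_genes = 905,
                       per_dataset_de_sizes = c(5868, 3479, 1084, 86, 69),
                       planted_overlap = 338,
                       samples_per_group = 10,
                       de_log2_effect = 2,
                       noise_sd = 0.5,
                       cna_gain_freq = 0.4,
                       cna_loss_freq = 0.35,
                       mutation_rate = 0.05,
                       survival_median_by_group = c(low = 22, high = 42),
                       censor_rate = 0.2,
                       n_patients = 96,
                       frac_one_to_many = 0.03,
                       frac_unmapped = 0.02,
                       frac_pe = 0.55,
                       seed = 1L) {
  cfg <- list(n_genes_universe = n_genes_universe,
              n_estrous_genes = n_estrous_genes,
              per_dataset_de_sizes = as.integer(per_dataset_de_sizes),
              n_datasets = length(per_dataset_de_sizes),
              planted_overlap = planted_overlap,
              samples_per_group = samples_per_group,
              de_log2_effect = de_log2_effect,
              noise_sd = noise_sd,
              cna_gain_freq = cna_gain_freq,
              cna_loss_freq = cna_loss_freq,
              mutation_rate = mutation_rate,
              survival_median_by_group = survival_median_by_group,
              censor_rate = censor_rate,
              n_patients = n_patients,
              frac_one_to_many = frac_one_to_many,
              frac_unmapped = frac_unmapped,
              frac_pe = frac_pe,
              seed = as.integer(seed))
  for (f in c("mutation_rate", "censor_rate", "cna_gain_freq",
              "cna_loss_freq", "frac_one_to_many", "frac_unmapped",
              "frac_pe"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("configuration error: %s must lie in [0,1]", f))
  if (cfg$planted_overlap > cfg$n_estrous_genes)
    stop("configuration error: planted_overlap exceeds n_estrous_genes")
  if (any(cfg$per_dataset_de_sizes > cfg$n_genes_universe))
    stop("configuration error: per_dataset_de_sizes exceeds n_genes_universe")
  if (cfg$planted_overlap > max(cfg$per_dataset_de_sizes))
    stop("configuration error: planted_overlap exceeds the largest per_dataset_de_size")
  if (cfg$cna_gain_freq + cfg$cna_loss_freq > 1)
    stop("configuration error: cna_gain_freq + cna_loss_freq exceeds 1")
  if (cfg$samples_per_group < 2)
    stop("configuration error: samples_per_group must be >= 2")
  class(cfg) <- "sim_config"
  cfg
}

.gene_universe <- function(n) sprintf("GENE%05d", seq_len(n))

#' Generate a synthetic cross-species study
#'
#' Builds the gene universe, an ortholog map covering the estrous list
#' (with a configurable sliver of one-to-many and unmapped genes), the
#' estrous-regulated list with stages (PE/EM) and directions, and one
#' two-class log2 expression matrix per dataset. Planted dysregulated
#' genes get a group-mean difference of exactly
#' \code{de_log2_effect} (signed by their planted direction); all other
#' genes have difference 0; i.i.d. Gaussian noise on the log2 scale.
#' The planted overlap genes are all members of the largest dataset's
#' truth set (and of others by chance), so every one of them is
#' dysregulated in at least one dataset. Non-planted estrous orthologs
#' are never planted, so the expected overlap equals
#' \code{planted_overlap} plus SAM false positives only.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{synthetic_study}: \code{ortholog_map},
#'   \code{estrous_list} (mouse_symbol, mouse_entrez, stage, direction),
#'   \code{expression_matrices} (per dataset: values, gene_ids, groups),
#'   \code{dataset_names}, \code{up_only} (dataset labels reporting up
#'   only), \code{truth} (list: overlap_genes, per_dataset_de,
#'   directions), \code{config}.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_genes_universe
  hugo <- .gene_universe(N)
  human_entrez <- seq_len(N) + 1000L

  ## estrous genes are the first n_estrous (identity is arbitrary)
  est_idx <- seq_len(config$n_estrous_genes)
  mouse_symbol <- paste0(substr(hugo, 1, 1),
                         tolower(substring(hugo, 2)))[est_idx]
  mouse_entrez <- est_idx + 500000L

  ## ortholog map: one row per estrous gene, minus unmapped, plus
  ## duplicated rows for one-to-many genes (second human target)
  n_est <- config$n_estrous_genes
  unmapped <- sample(est_idx, round(config$frac_unmapped * n_est))
  mapped <- setdiff(est_idx, unmapped)
  map <- data.frame(mouse_entrez = mouse_entrez[mapped],
                    mouse_symbol = mouse_symbol[mapped],
                    human_entrez = human_entrez[mapped],
                    hugo_symbol = hugo[mapped],
                    stringsAsFactors = FALSE)
  n12 <- round(config$frac_one_to_many * n_est)
  if (n12 > 0) {
    ## second ortholog points at a non-estrous human gene
    src <- sample(mapped, n12)
    tgt <- sample(setdiff(seq_len(N), est_idx), n12)
    map <- rbind(map, data.frame(mouse_entrez = mouse_entrez[src],
                                 mouse_symbol = mouse_symbol[src],
                                 human_entrez = human_entrez[tgt],
                                 hugo_symbol = hugo[tgt],
                                 stringsAsFactors = FALSE))
  }

  estrous_list <- data.frame(mouse_symbol = mouse_symbol,
                             mouse_entrez = mouse_entrez,
                             stage = sample(c("PE", "EM"), n_est, TRUE,
                                            prob = c(config$frac_pe,
                                                     1 - config$frac_pe)),
                             direction = sample(c("up", "down"), n_est,
                                                TRUE, prob = c(0.7, 0.3)),
                             stringsAsFactors = FALSE)

  ## planted overlap: estrous genes that are mapped and 1:1
  eligible_overlap <- setdiff(mapped, if (n12 > 0) src else integer(0))
  if (length(eligible_overlap) < config$planted_overlap)
    stop("configuration error: planted_overlap exceeds mapped 1:1 estrous genes")
  overlap_idx <- sort(sample(eligible_overlap, config$planted_overlap))
  overlap_genes <- hugo[overlap_idx]

  ## per-dataset truth: overlap genes all in the largest dataset;
  ## fillers drawn from non-estrous genes so the realized overlap is
  ## exactly the planted one (up to SAM errors)
  pool <- setdiff(seq_len(N), setdiff(est_idx, overlap_idx))
  sizes <- config$per_dataset_de_sizes
  largest <- which.max(sizes)
  per_dataset_de <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    if (d == largest) {
      fill <- sample(setdiff(pool, overlap_idx),
                     sizes[d] - length(overlap_idx))
      per_dataset_de[[d]] <- sort(c(overlap_idx, fill))
    } else {
      per_dataset_de[[d]] <- sort(sample(pool, sizes[d]))
    }
  }

  ## gene-level direction, shared across datasets (70% up, as most
  ## reported dysregulation in these studies is upregulation)
  dir_sign <- ifelse(stats::runif(N) < 0.7, 1, -1)

  dataset_names <- sprintf("dataset%d", seq_len(config$n_datasets))
  n_per <- config$samples_per_group
  groups <- factor(rep(c("normal", "tumor"), each = n_per),
                   levels = c("normal", "tumor"))
  base_mu <- stats::rnorm(N, mean = 7, sd = 1)
  mats <- lapply(seq_len(config$n_datasets), function(d) {
    eff <- numeric(N)
    eff[per_dataset_de[[d]]] <-
      config$de_log2_effect * dir_sign[per_dataset_de[[d]]]
    mu <- cbind(matrix(base_mu, N, n_per),
                matrix(base_mu + eff, N, n_per))
    vals <- mu + matrix(stats::rnorm(N * 2 * n_per, sd = config$noise_sd),
                        N, 2 * n_per)
    colnames(vals) <- sprintf("%s_S%02d", dataset_names[d],
                              seq_len(2 * n_per))
    list(values = vals, gene_ids = hugo, groups = groups)
  })
  names(mats) <- dataset_names

  ## the last two datasets report upregulated genes only, mirroring the
  ## reporting bias of the emulated study roster
  up_only <- if (config$n_datasets >= 5)
    dataset_names[(config$n_datasets - 1):config$n_datasets]
  else character(0)

  structure(list(ortholog_map = map,
                 estrous_list = estrous_list,
                 expression_matrices = mats,
                 dataset_names = dataset_names,
                 up_only = up_only,
                 truth = list(overlap_genes = overlap_genes,
                              per_dataset_de = lapply(per_dataset_de,
                                                      function(i) hugo[i]),
                              directions = data.frame(
                                gene = hugo,
                                direction = ifelse(dir_sign > 0, "up", "down"),
                                stringsAsFactors = FALSE)),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d-gene universe, %d estrous genes, %d datasets, planted overlap %d\n",
              x$config$n_genes_universe, x$config$n_estrous_genes,
              x$config$n_datasets, x$config$planted_overlap))
  invisible(x)
}

#' Generate a copy-number log2-ratio matrix
#'
#' For planted-gain genes each sample independently carries a log2
#' ratio above 0.3 with probability \code{cna_gain_freq} (drawn
#' uniformly in (0.35, 1.2)) and a near-zero ratio otherwise
#' (N(0, 0.08)); losses are symmetric below -0.3. Unplanted genes are
#' near-zero throughout.
#'
#' @param config a \code{\link{sim_config}}.
#' @param gene_ids character vector of gene identifiers (non-empty).
#' @param gain_genes,loss_genes subsets of \code{gene_ids} planted as
#'   gained/lost (no gene may be in both).
#' @param n_samples number of samples (columns).
#' @param seed optional seed override (defaults to \code{config$seed}).
#' @return numeric gene-by-sample matrix with \code{gene_ids} rownames.
#' @export
generate_cna_matrix <- function(config, gene_ids,
                                gain_genes = character(0),
                                loss_genes = character(0),
                                n_samples = 100,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(gene_ids)) stop("gene_ids must be non-empty")
  if (length(intersect(gain_genes, loss_genes)))
    stop("configuration error: gene planted as both gain and loss")
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  G <- length(gene_ids)
  m <- matrix(stats::rnorm(G * n_samples, sd = 0.08), G, n_samples,
              dimnames = list(gene_ids,
                              sprintf("P%03d", seq_len(n_samples))))
  plant <- function(genes, freq, sign) {
    idx <- match(genes, gene_ids)
    idx <- idx[!is.na(idx)]
    for (i in idx) {
      hit <- stats::runif(n_samples) < freq
      m[i, hit] <<- sign * stats::runif(sum(hit), 0.35, 1.2)
    }
  }
  plant(gain_genes, config$cna_gain_freq, 1)
  plant(loss_genes, config$cna_loss_freq, -1)
  m
}

#' Generate staining profiles and survival records
#'
#' One staining profile per patient (EOC compartment): percentages of
#' strong/moderate/weak/negative cells drawn from a Dirichlet-style
#' gamma normalization (summing to 100). Survival times are exponential
#' with stratum-specific medians (\code{survival_median_by_group}):
#' patients with a histoscore above the cohort median get the "high"
#' median, the rest the "low" one, planting a band-survival
#' association. A fraction \code{censor_rate} of records is censored at
#' a uniform fraction of the drawn event time.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional seed override.
#' @return list with \code{staining} (patient, antigen, compartment,
#'   pct_strong, pct_moderate, pct_weak, pct_negative), \code{scores}
#'   (patient, score), \code{survival} (patient, time, event, stratum).
#' @export
generate_ihc_and_survival <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed + 1L else as.integer(seed))
  n <- config$n_patients
  patient <- sprintf("PT%03d", seq_len(n))
  ## heterogeneous staining: gamma weights, normalized to 100%
  w <- matrix(stats::rgamma(4 * n, shape = c(1.2, 1.8, 1.2, 0.8)), n, 4,
              byrow = TRUE)
  pct <- 100 * w / rowSums(w)
  staining <- data.frame(patient = patient, antigen = "CANDIDATE",
                         compartment = "EOC",
                         pct_strong = pct[, 1L], pct_moderate = pct[, 2L],
                         pct_weak = pct[, 3L], pct_negative = pct[, 4L],
                         stringsAsFactors = FALSE)
  hs <- compute_histoscore(pct[, 1L], pct[, 2L], pct[, 3L])
  scores <- data.frame(patient = patient, score = hs$value,
                       stringsAsFactors = FALSE)

  med <- stats::median(scores$score)
  stratum <- ifelse(scores$score > med, "high", "low")
  med_by_group <- config$survival_median_by_group
  rate <- log(2) / med_by_group[stratum]       # exponential: median = log2/rate
  t_event <- stats::rexp(n, rate = rate)
  censored <- stats::runif(n) < config$censor_rate
  time <- ifelse(censored, t_event * stats::runif(n), t_event)
  surv <- data.frame(patient = patient, time = time,
                     event = !censored, stratum = stratum,
                     stringsAsFactors = FALSE)
  list(staining = staining, scores = scores, survival = surv)
}

#' Write all synthetic study inputs to a directory
#'
#' Tab-delimited files with header rows (matrices gene-by-sample with a
#' leading identifier column) plus a YAML manifest recording the
#' configuration and seed.
#'
#' @param study a \code{\link{generate_study}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(study$ortholog_map, file.path(dir, "ortholog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$estrous_list, file.path(dir, "estrous_list.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (d in names(study$expression_matrices)) {
    m <- study$expression_matrices[[d]]
    write_expression_matrix(m$values, m$gene_ids, m$groups,
                            file.path(dir, paste0("expr_", d, ".tsv")))
  }
  manifest <- c(list(generator = "ovcand::generate_study",
                     datasets = study$dataset_names,
                     up_only = study$up_only),
                unclass(study$config))
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
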