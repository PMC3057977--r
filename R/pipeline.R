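#' End-to-end candidate prioritization pipeline
#'
#' Runs every stage on a (typically synthetic) study: per-dataset SAM
#' differential expression, ortholog harmonization, cross-dataset
#' support counting, intersection with the estrous signature,
#' enrichment testing, dual-source copy-number consensus and
#' expression concordance, mutation-catalog triage, histoscore
#' categorization and median-dichotomized survival analysis, producing
#' a per-gene candidate evidence report.
#'
#' @name pipeline
NULL

#' Run the full prioritization pipeline
#'
#' All thresholds default to the printed conventions of the emulated
#' study: q < 0.05 and linear fold change > 2 for dysregulation, |log2
#' ratio| > 0.3 in > 30% of samples for copy-number calls, support >= 3
#' for mutation triage. Deterministic given the study's seed. Evidence
#' layers that cannot be assessed for a gene are marked
#' \code{"not assessed"} rather than left empty.
#'
#' @param study a \code{\link{generate_study}} result (or a list with
#'   the same shape built from real data files).
#' @param outdir optional directory; when given, every stage's
#'   intermediate table is written there as tab-delimited text along
#'   with a run log.
#' @param n_permutations SAM permutations per dataset.
#' @param q_threshold,fc_threshold SAM call thresholds.
#' @param gain_thr,loss_thr,freq_thr copy-number call thresholds.
#' @param min_support support threshold for mutation triage.
#' @param universe_size gene universe for the enrichment test; defaults
#'   to the study's configured universe.
#' @return list of class \code{candidate_report}: \code{report}
#'   (per-gene evidence data.frame), \code{overlap}, \code{enrichment},
#'   \code{cna}, \code{mutation}, \code{ihc}, \code{survival},
#'   \code{sam_results}, \code{log} (character vector of decision
#'   lines).
#' @export
run_pipeline <- function(study, outdir = NULL,
                         n_permutations = 100,
                         q_threshold = 0.05, fc_threshold = 2,
                         gain_thr = 0.3, loss_thr = -0.3, freq_thr = 0.30,
                         min_support = 3L,
                         universe_size = NULL) {
  cfg <- study$config
  if (is.null(universe_size)) universe_size <- cfg$n_genes_universe
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("seed=%d", cfg$seed)
  say("thresholds: q<%g, FC>%g, |log2|>%g, freq>%g, support>=%d",
      q_threshold, fc_threshold, gain_thr, freq_thr, min_support)

  ## --- stage 1: per-dataset differential expression -----------------
  sam_results <- list()
  calls <- list()
  for (d in study$dataset_names) {
    m <- study$expression_matrices[[d]]
    res <- call_de(m$values, m$gene_ids, m$groups,
                   n_permutations = n_permutations,
                   seed = cfg$seed + match(d, study$dataset_names),
                   q_threshold = q_threshold, fc_threshold = fc_threshold)
    sam_results[[d]] <- res
    de <- res[res$de_call, , drop = FALSE]
    if (d %in% study$up_only) {
      de <- de[de$direction == "up", , drop = FALSE]
      say("dataset %s declared up-only; %d down calls dropped", d,
          sum(res$de_call & res$direction == "down"))
    }
    if (nrow(de))
      calls[[d]] <- data.frame(gene = de$gene, dataset = d,
                               direction = de$direction,
                               fold_change = signif(de$fold_change, 3),
                               stringsAsFactors = FALSE)
    say("dataset %s: %d DE calls (s0=%.4g)", d, nrow(de), attr(res, "s0"))
  }
  calls <- do.call(rbind, calls)

  ## --- stage 2: harmonize the estrous list --------------------------
  mapping <- map_orthologs(study$estrous_list, study$ortholog_map)
  est_human <- dedupe_harmonized(mapping$mapped)
  say("estrous list: %d mouse genes -> %d human symbols (%d unmapped)",
      nrow(study$estrous_list), nrow(est_human), nrow(mapping$unmapped))

  ## --- stage 3: support counting, overlap, enrichment ---------------
  if (is.null(calls) || nrow(calls) == 0L) {
    warning("no dysregulation calls in any dataset; report is empty")
    out <- list(report = data.frame(), overlap = data.frame(),
                enrichment = NULL, cna = NULL, mutation = NULL,
                ihc = NULL, survival = NULL, sam_results = sam_results,
                log = c(log, "empty: no DE calls"))
    class(out) <- "candidate_report"
    return(out)
  }
  summaries <- count_support(calls, roster = study$dataset_names,
                             up_only = study$up_only)
  overlap <- intersect_with_estrous(
    summaries,
    data.frame(hugo_symbol = est_human$hugo_symbol,
               stage = est_human$stage, stringsAsFactors = FALSE))
  n_dys <- nrow(summaries)
  enr <- test_overlap_enrichment(nrow(overlap), nrow(est_human), n_dys,
                                 universe_size)
  overlap <- rank_candidates(overlap,
                             reference_dataset = study$dataset_names[1L])
  say("overlap: %d genes (expected %.1f by chance; chi-square p=%.3g)",
      nrow(overlap), enr$expected_overlap, enr$p_chisq)

  ## --- stage 4: copy-number evidence ---------------------------------
  cna <- NULL
  if (nrow(overlap) > 0L) {
    dirs <- study$truth$directions
    ov_dir <- dirs$direction[match(overlap$gene, dirs$gene)]
    n_cna <- max(1L, round(0.19 * nrow(overlap)))  # ~19% of overlap in CNA regions
    cna_genes <- overlap$gene[seq_len(min(n_cna, nrow(overlap)))]
    gain_genes <- cna_genes[ov_dir[seq_along(cna_genes)] == "up"]
    loss_genes <- setdiff(cna_genes, gain_genes)
    arms <- c("1q21", "3q27", "8q24.1", "12p12.1", "20q13.12",
              "4q28.1", "22q13.2")
    set.seed(cfg$seed + 101L)
    cyto <- sample(arms, length(cna_genes), replace = TRUE)
    src_calls <- list()
    mats <- list()
    for (s in c("sourceA", "sourceB")) {
      m <- generate_cna_matrix(cfg, overlap$gene, gain_genes, loss_genes,
                               n_samples = 100,
                               seed = cfg$seed + 200L +
                                 match(s, c("sourceA", "sourceB")))
      mats[[s]] <- m
      cc <- call_cna(list(gene_ids = rownames(m), values = m),
                     gain_thr = gain_thr, loss_thr = loss_thr,
                     freq_thr = freq_thr)
      src_calls[[s]] <- data.frame(gene = cc$gene, source = s,
                                   call = cc$call,
                                   stringsAsFactors = FALSE)
    }
    cons <- dual_source_consensus(do.call(rbind, src_calls),
                                  sources = c("sourceA", "sourceB"))
    conc <- test_expression_concordance(
      cons$consensus,
      data.frame(gene = overlap$gene,
                 direction = overlap$consensus_direction,
                 stringsAsFactors = FALSE))
    per_sample <- mats$sourceA[rownames(mats$sourceA) %in% cons$consensus$gene, ,
                               drop = FALSE] > gain_thr |
      mats$sourceA[rownames(mats$sourceA) %in% cons$consensus$gene, ,
                   drop = FALSE] < loss_thr
    regions <- summarize_region_groups(
      data.frame(gene = cna_genes,
                 cytoband = cyto, stringsAsFactors = FALSE)[
                   cna_genes %in% cons$consensus$gene, , drop = FALSE],
      per_sample_calls = per_sample)
    cna <- list(consensus = cons$consensus, excluded = cons$excluded,
                concordance = conc, regions = regions,
                planted = list(gain = gain_genes, loss = loss_genes),
                cytobands = stats::setNames(cyto, cna_genes))
    say("CNA: %d consensus genes, %d/%d concordant with expression",
        nrow(cons$consensus), conc$n_concordant, conc$n_tested)
  }

  ## --- stage 5: mutation triage --------------------------------------
  mut <- NULL
  if (nrow(overlap) > 0L) {
    set.seed(cfg$seed + 300L)
    n_mut <- stats::rbinom(1L, nrow(overlap), cfg$mutation_rate)
    mut_genes <- sample(overlap$gene, n_mut)
    catalog <- if (n_mut > 0)
      data.frame(gene = mut_genes,
                 tissue = sample(c("ovary", "breast", "lung", "CNS"),
                                 n_mut, TRUE, prob = c(0.4, 0.2, 0.2, 0.2)),
                 n_mutated = stats::rbinom(n_mut, 50, 0.05),
                 n_screened = 50L,
                 fusion_partner = NA_character_,
                 stringsAsFactors = FALSE)
    else data.frame(gene = character(0), tissue = character(0),
                    n_mutated = integer(0), n_screened = integer(0),
                    fusion_partner = character(0))
    sel <- select_catalog_queries(overlap, min_support = min_support)
    evidence <- classify_mutation_evidence(sel$gene, catalog)
    mut <- list(selected = sel, evidence = evidence,
                fusions = collect_fusion_partners(evidence),
                catalog = catalog)
    say("mutation triage: %d genes selected, %d with catalog records",
        nrow(sel), sum(evidence$class != "no-record"))
  }

  ## --- stage 6: IHC and survival -------------------------------------
  ihc_surv <- generate_ihc_and_survival(cfg)
  categ <- categorize_cohort(ihc_surv$scores$score)
  surv_res <- dichotomize_at_median(ihc_surv$scores, ihc_surv$survival)
  say("survival: median %s=%.1f, %s=%.1f months; log-rank p=%.3g",
      names(surv_res$medians)[1L], surv_res$medians[1L],
      names(surv_res$medians)[2L], surv_res$medians[2L],
      surv_res$logrank$p)

  ## --- candidate report ----------------------------------------------
  na_mark <- "not assessed"
  report <- overlap[, c("gene", "estrous_stage", "support_count",
                        "consensus_direction", "rank")]
  if (!is.null(cna)) {
    cc <- cna$consensus$call[match(report$gene, cna$consensus$gene)]
    report$cna_consensus <- ifelse(is.na(cc), na_mark, cc)
    report$cna_concordant <- ifelse(
      is.na(cc), na_mark,
      ifelse(report$gene %in% cna$concordance$concordant, "yes", "no"))
    arm <- cytoband_arm(cna$cytobands[report$gene])
    report$region_group <- ifelse(is.na(cc), na_mark,
                                  ifelse(is.na(arm), "remainder", arm))
  }
  if (!is.null(mut)) {
    mc <- mut$evidence$class[match(report$gene, mut$evidence$gene)]
    report$mutation_class <- ifelse(is.na(mc), na_mark, mc)
  }
  report$survival_association <-
    ifelse(seq_len(nrow(report)) > 0 & !is.na(surv_res$logrank$p) &
             surv_res$logrank$p < 0.05, "cohort-level", na_mark)

  out <- list(report = report, overlap = overlap, enrichment = enr,
              summaries = summaries, cna = cna, mutation = mut,
              ihc = list(staining = ihc_surv$staining,
                         scores = ihc_surv$scores, categories = categ),
              survival = surv_res, sam_results = sam_results, log = log)
  class(out) <- "candidate_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    for (d in names(sam_results))
      write_sam_result(sam_results[[d]],
                       file.path(outdir, paste0("sam_", d, ".tsv")))
    wt(summaries, "support_summaries.tsv")
    wt(overlap, "overlap_candidates.tsv")
    wt(report, "candidate_report.tsv")
    if (!is.null(cna)) {
      wt(cna$consensus, "cna_consensus.tsv")
      wt(cna$regions, "cna_region_groups.tsv")
    }
    if (!is.null(mut)) wt(mut$evidence, "mutation_evidence.tsv")
    wt(categ, "ihc_categories.tsv")
    for (s in names(surv_res$km))
      write_km_curve(surv_res$km[[s]],
                     file.path(outdir, paste0("km_", s, ".tsv")))
    writeLines(log, file.path(outdir, "run_log.txt"))
  }
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("Candidate report: %d overlap genes\n", nrow(x$report)))
  if (!is.null(x$enrichment))
    cat(sprintf("  enrichment: chi-square %.2f, p = %.3g (exact %.3g)\n",
                x$enrichment$chisq, x$enrichment$p_chisq,
                x$enrichment$p_exact))
  if (!is.null(x$cna))
    cat(sprintf("  CNA: %d consensus, %d concordant\n",
                nrow(x$cna$consensus), x$cna$concordance$n_concordant))
  if (!is.null(x$survival))
    cat(sprintf("  survival: log-rank p = %.3g\n", x$survival$logrank$p))
  invisible(x)
}
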