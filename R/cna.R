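#' Copy-number aberration evidence
#'
#' Per-gene gain/loss calling from log2 copy-number ratios (gain: ratio
#' > 0.3; loss: ratio < -0.3; called when seen in strictly more than
#' 30% of samples), dual-source consensus, concordance of copy-number
#' direction with expression direction, and chromosome-arm region
#' summaries.
#'
#' @name cna_evidence
NULL

#' Call per-gene copy-number status
#'
#' A gene is called "gain" when the fraction of samples with log2 ratio
#' strictly above \code{gain_thr} strictly exceeds \code{freq_thr};
#' "loss" symmetrically below \code{loss_thr}; otherwise "neutral". A
#' gene flagged as lying in a reported peak region of recurrent
#' aberration (\code{in_peak_region}) qualifies regardless of
#' frequency, since peak membership is an alternative reporting route
#' in the source datasets. Input is either a gene-by-sample matrix of
#' log2 ratios or a precomputed frequency table.
#'
#' @param profile either a list with \code{gene_ids} and \code{values}
#'   (gene x sample log2 matrix), or a data.frame with columns
#'   \code{gene}, \code{gain_freq}, \code{loss_freq} and optionally
#'   \code{in_peak_region}, \code{peak_direction}.
#' @param gain_thr log2 ratio above which a sample counts as gained.
#' @param loss_thr log2 ratio below which a sample counts as lost.
#' @param freq_thr sample-fraction threshold (strict) for a gene-level
#'   call.
#' @return data.frame with columns \code{gene}, \code{gain_freq},
#'   \code{loss_freq}, \code{call} ("gain"/"loss"/"neutral").
#' @export
call_cna <- function(profile, gain_thr = 0.3, loss_thr = -0.3,
                     freq_thr = 0.30) {
  if (is.list(profile) && !is.data.frame(profile) &&
      all(c("gene_ids", "values") %in% names(profile))) {
    v <- as.matrix(profile$values)
    gain_freq <- rowMeans(v > gain_thr)
    loss_freq <- rowMeans(v < loss_thr)
    out <- data.frame(gene = profile$gene_ids, gain_freq = gain_freq,
                      loss_freq = loss_freq, stringsAsFactors = FALSE)
    out$in_peak <- FALSE
    out$peak_dir <- NA_character_
  } else if (is.data.frame(profile) &&
             all(c("gene", "gain_freq", "loss_freq") %in% names(profile))) {
    if (any(profile$gain_freq + profile$loss_freq > 1 + 1e-9))
      stop("gain_freq + loss_freq > 1 for gene(s): ",
           paste(profile$gene[profile$gain_freq + profile$loss_freq > 1 + 1e-9],
                 collapse = ", "))
    out <- profile[, c("gene", "gain_freq", "loss_freq")]
    out$in_peak <- if ("in_peak_region" %in% names(profile))
      isTRUE_vec(profile$in_peak_region) else rep(FALSE, nrow(profile))
    out$peak_dir <- if ("peak_direction" %in% names(profile))
      profile$peak_direction else rep(NA_character_, nrow(profile))
  } else {
    stop("profile must provide per-sample log2 ratios or gain/loss frequencies")
  }
  call <- rep("neutral", nrow(out))
  call[out$gain_freq > freq_thr] <- "gain"
  call[out$loss_freq > freq_thr] <- "loss"
  both <- out$gain_freq > freq_thr & out$loss_freq > freq_thr
  if (any(both))  # keep the more frequent direction
    call[both] <- ifelse(out$gain_freq[both] >= out$loss_freq[both],
                         "gain", "loss")
  peak <- out$in_peak & call == "neutral" & !is.na(out$peak_dir)
  call[peak] <- out$peak_dir[peak]
  out$call <- call
  out$in_peak <- NULL; out$peak_dir <- NULL
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Dual-source copy-number consensus
#'
#' A gene reaches consensus when both declared sources call the same
#' non-neutral direction. Genes present in only one source are excluded
#' with reason code \code{SINGLE_SOURCE}; genes with opposite calls are
#' flagged \code{DISCORDANT}; neutral-in-either genes get
#' \code{NO_ABERRATION}.
#'
#' @param calls data.frame with columns \code{gene}, \code{source},
#'   \code{call} ("gain"/"loss"/"neutral").
#' @param sources character vector naming exactly the two sources.
#' @return list with \code{consensus} (data.frame \code{gene},
#'   \code{call}) and \code{excluded} (data.frame \code{gene},
#'   \code{reason}).
#' @export
dual_source_consensus <- function(calls, sources = NULL) {
  if (!all(c("gene", "source", "call") %in% names(calls)))
    stop("calls must have columns gene, source, call")
  if (is.null(sources)) sources <- unique(calls$source)
  if (length(sources) != 2L)
    stop("exactly two sources required, got: ",
         paste(sources, collapse = ", "))
  genes <- unique(calls$gene)
  cons <- character(0); cons_gene <- character(0)
  excl_gene <- character(0); excl_reason <- character(0)
  for (g in genes) {
    c1 <- calls$call[calls$gene == g & calls$source == sources[1L]]
    c2 <- calls$call[calls$gene == g & calls$source == sources[2L]]
    if (!length(c1) || !length(c2)) {
      excl_gene <- c(excl_gene, g); excl_reason <- c(excl_reason, "SINGLE_SOURCE")
    } else if (c1[1L] != "neutral" && c2[1L] != "neutral" && c1[1L] != c2[1L]) {
      excl_gene <- c(excl_gene, g); excl_reason <- c(excl_reason, "DISCORDANT")
    } else if (c1[1L] == c2[1L] && c1[1L] != "neutral") {
      cons_gene <- c(cons_gene, g); cons <- c(cons, c1[1L])
    } else {
      excl_gene <- c(excl_gene, g); excl_reason <- c(excl_reason, "NO_ABERRATION")
    }
  }
  list(consensus = data.frame(gene = cons_gene, call = cons,
                              stringsAsFactors = FALSE),
       excluded = data.frame(gene = excl_gene, reason = excl_reason,
                             stringsAsFactors = FALSE))
}

#' Test concordance of copy number with expression direction
#'
#' A consensus-aberrant gene is concordant when gain co-occurs with
#' upregulation or loss with downregulation. Association between
#' aberration direction and expression direction is tested on the 2x2
#' table {gain, loss} x {up, down} with a Pearson chi-square (no
#' continuity correction) and, as cross-check, Fisher's exact test.
#' Genes whose expression direction is "inconsistent" (or missing) are
#' excluded and reported.
#'
#' @param consensus data.frame from \code{\link{dual_source_consensus}}
#'   (\code{gene}, \code{call}).
#' @param directions data.frame with columns \code{gene},
#'   \code{direction} ("up"/"down"/"inconsistent").
#' @return list with \code{concordant} (character vector of genes),
#'   \code{n_concordant}, \code{n_tested}, \code{table}, \code{chisq},
#'   \code{p_chisq}, \code{p_exact}, \code{excluded} (data.frame).
#' @export
test_expression_concordance <- function(consensus, directions) {
  dir <- directions$direction[match(consensus$gene, directions$gene)]
  bad <- is.na(dir) | !(dir %in% c("up", "down"))
  excluded <- data.frame(gene = consensus$gene[bad],
                         reason = ifelse(is.na(dir[bad]), "NO_DIRECTION",
                                         "INCONSISTENT_DIRECTION"),
                         stringsAsFactors = FALSE)
  keep <- consensus[!bad, , drop = FALSE]
  dir <- dir[!bad]
  conc <- (keep$call == "gain" & dir == "up") |
    (keep$call == "loss" & dir == "down")
  tab <- table(factor(keep$call, levels = c("gain", "loss")),
               factor(dir, levels = c("up", "down")))
  chisq <- p_chisq <- p_exact <- NA_real_
  if (all(dim(tab) == 2L) && sum(tab) > 0) {
    p_exact <- stats::fisher.test(tab)$p.value
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chisq <- unname(ct$statistic); p_chisq <- ct$p.value
    }
  }
  list(concordant = keep$gene[conc], n_concordant = sum(conc),
       n_tested = nrow(keep), table = tab, chisq = chisq,
       p_chisq = p_chisq, p_exact = p_exact, excluded = excluded)
}

#' Extract the chromosome-arm prefix of a cytoband
#'
#' "8q24.3" -> "8q"; "12pter-q12" -> "12p"; bands without a p/q arm
#' (e.g. a bare chromosome number "19") return NA.
#'
#' @param cytoband character vector of cytoband strings.
#' @return character vector of arm labels (or NA).
#' @export
cytoband_arm <- function(cytoband) {
  pos <- regexpr("^([0-9]{1,2}|X|Y)[pq]", cytoband)
  hit <- !is.na(cytoband) & pos > 0
  out <- rep(NA_character_, length(cytoband))
  out[hit] <- substr(cytoband[hit], 1L,
                     attr(pos, "match.length")[hit])
  out
}

#' Summarize consensus genes by chromosomal region group
#'
#' Groups genes by chromosome arm (the arm prefix of their cytoband);
#' arms with fewer than \code{min_group} genes, and genes with an
#' unparseable location, fall into the "remainder" group. When a
#' gene-by-sample call matrix is supplied, reports per group how many
#' patients have the aberration in at least one gene
#' (\code{n_patients_any}) and in all genes (\code{n_patients_all}).
#'
#' @param genes data.frame with columns \code{gene}, \code{cytoband}.
#' @param per_sample_calls optional logical gene-by-sample matrix
#'   (rownames = genes) of per-patient aberration calls.
#' @param min_group minimum genes per named arm group (default 3).
#' @return data.frame with columns \code{group}, \code{n_genes},
#'   \code{genes} (comma-separated), \code{n_patients_any},
#'   \code{n_patients_all}, \code{fraction_all}.
#' @export
summarize_region_groups <- function(genes, per_sample_calls = NULL,
                                    min_group = 3L) {
  arm <- cytoband_arm(genes$cytoband)
  arm[is.na(arm)] <- "remainder"
  counts <- table(arm)
  small <- names(counts)[counts < min_group & names(counts) != "remainder"]
  arm[arm %in% small] <- "remainder"
  groups <- unique(arm)
  named <- sort(setdiff(groups, "remainder"))
  groups <- c(named, intersect("remainder", groups))
  rows <- lapply(groups, function(g) {
    gg <- genes$gene[arm == g]
    any_n <- all_n <- NA_integer_; frac <- NA_real_
    if (!is.null(per_sample_calls) && g != "remainder") {
      sub <- per_sample_calls[rownames(per_sample_calls) %in% gg, , drop = FALSE]
      if (nrow(sub)) {
        any_n <- sum(colSums(sub) >= 1L)
        all_n <- sum(colSums(sub) == nrow(sub))
        frac <- if (any_n > 0) all_n / any_n else NA_real_
      }
    }
    data.frame(group = g, n_genes = length(gg),
               genes = paste(sort(gg), collapse = ","),
               n_patients_any = any_n, n_patients_all = all_n,
               fraction_all = frac, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
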