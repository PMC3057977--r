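#' Cross-dataset evidence aggregation and estrous-overlap integration
#'
#' Aggregates per-dataset dysregulation calls into per-gene evidence
#' summaries (how many datasets support the gene, and in which
#' direction), intersects the dysregulated set with the harmonized
#' estrous-regulated signature, tests the overlap for enrichment, and
#' ranks candidates.
#'
#' @name overlap_integration
NULL

#' Aggregate dysregulation calls per gene
#'
#' One summary row per gene: the number of datasets with a call
#' (\code{support_count}), the consensus direction ("up", "down", or
#' "inconsistent" when both directions occur), and a per-dataset
#' direction/fold-change string. Datasets declared "up-only" (studies
#' that reported upregulated genes only) cannot contribute evidence of
#' down-consistency; a gene called only in up-only datasets is never
#' labelled "down".
#'
#' @param calls data.frame of dysregulation calls with columns
#'   \code{gene}, \code{dataset}, \code{direction} ("up"/"down") and
#'   optionally \code{fold_change} (numeric or qualitative text such as
#'   ">3").
#' @param roster character vector of all dataset labels; defaults to
#'   those present in \code{calls}.
#' @param up_only character vector of dataset labels that reported
#'   upregulated genes only.
#' @return data.frame with columns \code{gene}, \code{support_count},
#'   \code{consensus_direction}, and one \code{fc_<dataset>} column per
#'   roster dataset; ordered by decreasing support.
#' @export
count_support <- function(calls, roster = NULL, up_only = character(0)) {
  need <- c("gene", "dataset", "direction")
  if (!all(need %in% names(calls)))
    stop("calls must have columns gene, dataset, direction")
  if (!all(calls$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  if (is.null(roster)) roster <- unique(calls$dataset)
  if (!all(calls$dataset %in% roster))
    stop("calls contain datasets not on the roster: ",
         paste(setdiff(calls$dataset, roster), collapse = ", "))
  if (!all(up_only %in% roster))
    stop("up_only datasets must be on the roster")
  bad_dn <- calls$direction == "down" & calls$dataset %in% up_only
  if (any(bad_dn)) {
    warning(sprintf("%d down call(s) in up-only dataset(s) dropped", sum(bad_dn)))
    calls <- calls[!bad_dn, , drop = FALSE]
  }
  key <- paste(calls$gene, calls$dataset, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conf <- vapply(unique(dup), function(k)
      length(unique(calls$direction[key == k])) > 1L, logical(1))
    if (any(conf))
      stop("conflicting duplicate calls for: ",
           paste(gsub("\r", "/", unique(dup)[conf]), collapse = ", "))
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  has_fc <- "fold_change" %in% names(calls)
  genes <- unique(calls$gene)
  res <- lapply(genes, function(g) {
    cg <- calls[calls$gene == g, , drop = FALSE]
    dirs <- unique(cg$direction)
    cons <- if (length(dirs) == 1L) dirs else "inconsistent"
    fcs <- stats::setNames(rep(NA_character_, length(roster)), roster)
    if (has_fc)
      fcs[cg$dataset] <- as.character(cg$fold_change)
    else
      fcs[cg$dataset] <- cg$direction
    c(list(gene = g, support_count = nrow(cg), consensus_direction = cons),
      as.list(fcs))
  })
  out <- do.call(rbind, lapply(res, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(out)[-(1:3)] <- paste0("fc_", roster)
  out <- out[order(-out$support_count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "roster") <- roster
  attr(out, "up_only") <- up_only
  out
}

.check_harmonized_symbols <- function(x, what) {
  ## whitespace, or mouse-style title case (2nd char lower) -- HUGO
  ## symbols are upper case apart from the "orf" convention (C5orf34)
  bad <- grepl("\\s", x) | grepl("^[A-Za-z][a-z]", x)
  if (any(bad))
    stop(what, " contains unharmonized symbols (whitespace or lower case): ",
         paste(utils::head(unique(x[bad]), 5L), collapse = ", "))
  invisible(x)
}

#' Intersect dysregulated genes with the estrous signature
#'
#' Set intersection on harmonized HUGO symbols. Each overlap row carries
#' the estrous stage (PE, EM or PE/EM) and the cross-dataset cancer
#' evidence. Both inputs must already be harmonized (upper-case symbols,
#' no whitespace); unharmonized symbols raise an error rather than
#' silently failing to join.
#'
#' @param summaries evidence summary table from \code{\link{count_support}}
#'   with a \code{gene} column of HUGO symbols.
#' @param estrous_human data.frame of the harmonized estrous signature
#'   with columns \code{hugo_symbol} and optionally \code{stage}.
#' @return data.frame: the summary rows of overlapping genes plus an
#'   \code{estrous_stage} column.
#' @export
intersect_with_estrous <- function(summaries, estrous_human) {
  .check_harmonized_symbols(summaries$gene, "summaries")
  .check_harmonized_symbols(estrous_human$hugo_symbol, "estrous list")
  est <- estrous_human[!duplicated(estrous_human$hugo_symbol), , drop = FALSE]
  hit <- summaries$gene %in% est$hugo_symbol
  out <- summaries[hit, , drop = FALSE]
  stage <- if ("stage" %in% names(est))
    est$stage[match(out$gene, est$hugo_symbol)]
  else rep(NA_character_, nrow(out))
  out$estrous_stage <- stage
  rownames(out) <- NULL
  out
}

#' Test gene-list overlap for enrichment
#'
#' Builds the 2x2 table {in/out estrous signature} x {in/out
#' dysregulated set} over a stated gene universe and reports the Pearson
#' chi-square statistic (no continuity correction) with its p-value, the
#' expected overlap under independence, and an exact hypergeometric
#' upper-tail p-value as a cross-check. If any expected cell is below 1
#' the chi-square is suppressed (NA) and only the exact test is
#' reported.
#'
#' @param k_overlap observed overlap size.
#' @param n_estrous size of the estrous signature (within the universe).
#' @param n_dysregulated size of the dysregulated set.
#' @param n_universe size of the gene universe on which both lists were
#'   measured.
#' @return list with \code{chisq}, \code{p_chisq}, \code{p_exact}
#'   (hypergeometric upper tail, P[X >= k]), \code{expected_overlap},
#'   \code{table} (the 2x2 matrix).
#' @export
test_overlap_enrichment <- function(k_overlap, n_estrous, n_dysregulated,
                                    n_universe) {
  if (k_overlap > min(n_estrous, n_dysregulated))
    stop("overlap cannot exceed the smaller list")
  if (max(n_estrous, n_dysregulated) > n_universe)
    stop("lists cannot exceed the universe")
  tab <- matrix(c(k_overlap,
                  n_estrous - k_overlap,
                  n_dysregulated - k_overlap,
                  n_universe - n_estrous - n_dysregulated + k_overlap),
                nrow = 2,
                dimnames = list(estrous = c("in", "out"),
                                dysregulated = c("in", "out")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  p_exact <- stats::phyper(k_overlap - 1, n_estrous,
                           n_universe - n_estrous, n_dysregulated,
                           lower.tail = FALSE)
  if (any(expected < 1)) {
    chisq <- NA_real_; p_chisq <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chisq <- unname(ct$statistic); p_chisq <- ct$p.value
  }
  list(chisq = chisq, p_chisq = p_chisq, p_exact = p_exact,
       expected_overlap = n_estrous * n_dysregulated / n_universe,
       table = tab)
}

## fold-change sort key: numeric magnitude first, qualitative flags
## (">3", "up", "down") after all numeric values, absent last
.fc_sort_key <- function(fc) {
  v <- suppressWarnings(as.numeric(fc))
  key <- abs(v)
  qual <- is.na(v) & !is.na(fc) & !(fc %in% c("-", "na", ""))
  key[qual] <- -1        # after all numeric magnitudes (sorted decreasing)
  key[is.na(key)] <- -2  # absent: last
  key
}

#' Rank candidate genes
#'
#' Primary sort: decreasing dataset support. Secondary: decreasing fold
#' change in a designated reference dataset (qualitative fold changes
#' such as ">3" or "up" order after all numeric values). Ties broken
#' alphabetically by symbol, so the order is a deterministic function of
#' the table content, not of input row order.
#'
#' @param overlap data.frame with \code{gene}, \code{support_count} and
#'   \code{fc_<dataset>} columns (from \code{\link{count_support}} /
#'   \code{\link{intersect_with_estrous}}).
#' @param reference_dataset label of the dataset whose fold change is
#'   the secondary key; defaults to the first \code{fc_} column.
#' @return the table sorted into rank order, with a \code{rank} column.
#' @export
rank_candidates <- function(overlap, reference_dataset = NULL) {
  fc_cols <- grep("^fc_", names(overlap), value = TRUE)
  ref <- if (is.null(reference_dataset)) {
    if (length(fc_cols)) fc_cols[1L] else NULL
  } else paste0("fc_", reference_dataset)
  key <- if (!is.null(ref) && ref %in% names(overlap))
    .fc_sort_key(overlap[[ref]]) else rep(0, nrow(overlap))
  ord <- order(-overlap$support_count, -key, overlap$gene)
  out <- overlap[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
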