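#' Two-class SAM-style differential expression
#'
#' Permutation-based differential-expression calling for two-class
#' (unpaired) log2 expression matrices, built around the relative
#' difference statistic d = (mean2 - mean1) / (s + s0), where s is the
#' gene-wise pooled standard error and s0 a small positive "fudge
#' factor" that stabilizes the variance of d across the range of s.
#' q-values are estimated from permutations of the group labels.
#'
#' @name sam
NULL

## Validate and canonicalize a two-class expression matrix.
## Returns list(values, gene_ids, groups, levels).
.sam_check_matrix <- function(values, gene_ids, groups) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("expression values must be finite numerics")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length must equal number of rows")
  if (anyNA(gene_ids) || any(gene_ids == ""))
    stop("missing gene identifiers are not allowed")
  groups <- as.factor(groups)
  if (length(groups) != ncol(values))
    stop("group labels must match number of samples")
  if (nlevels(groups) != 2L)
    stop("exactly two group levels required")
  n <- table(groups)
  if (any(n < 2L))
    stop("each group needs at least 2 samples")
  list(values = values, gene_ids = as.character(gene_ids),
       groups = groups, levels = levels(groups))
}

## Per-gene mean difference (level2 - level1) and pooled standard error
## for an arbitrary label assignment, vectorized over genes.
.sam_r_s <- function(values, idx2) {
  n <- ncol(values)
  i2 <- logical(n); i2[idx2] <- TRUE
  n2 <- sum(i2); n1 <- n - n2
  m1 <- rowMeans(values[, !i2, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  ss1 <- rowSums((values[, !i2, drop = FALSE] - m1)^2)
  ss2 <- rowSums((values[, i2, drop = FALSE] - m2)^2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  list(r = m2 - m1, s = sqrt(a * (ss1 + ss2)))
}

#' Compute SAM d statistics
#'
#' Computes, for every gene, the relative difference
#' \eqn{d = (\bar x_2 - \bar x_1) / (s + s_0)} between the two groups,
#' where \eqn{s} is the pooled standard error of the mean difference.
#' Group 2 is the second factor level of \code{groups} (by convention
#' the condition of interest, e.g. tumor), so positive d means higher
#' expression in group 2.
#'
#' @param values numeric gene-by-sample matrix of log2 intensities.
#' @param gene_ids character vector of gene identifiers, one per row.
#' @param groups two-level factor (or coercible) of sample group labels.
#' @param s0 non-negative fudge factor added to the denominator.
#' @return data.frame with columns \code{gene}, \code{d}, \code{s},
#'   \code{mean_diff}. Genes with zero variance in both groups and
#'   \code{s0 = 0} get \code{d = NA} with a warning (never infinity).
#' @export
compute_d_statistics <- function(values, gene_ids, groups, s0 = 0) {
  if (!is.numeric(s0) || length(s0) != 1L || s0 < 0)
    stop("s0 must be a single non-negative number")
  m <- .sam_check_matrix(values, gene_ids, groups)
  rs <- .sam_r_s(m$values, which(m$groups == m$levels[2L]))
  denom <- rs$s + s0
  d <- rs$r / denom
  bad <- denom == 0
  if (any(bad)) {
    warning(sprintf("%d gene(s) with zero pooled variance and s0 = 0 excluded (d set to NA)",
                    sum(bad)))
    d[bad] <- NA_real_
  }
  data.frame(gene = m$gene_ids, d = d, s = rs$s, mean_diff = rs$r,
             stringsAsFactors = FALSE)
}

#' Estimate the SAM fudge factor s0
#'
#' Percentile search: candidate values are 0 and the 5th to 100th
#' percentiles of the gene-wise pooled standard errors s, in steps of 5.
#' For each candidate the genes are partitioned into windows by
#' percentile of s, the median absolute deviation of d within each
#' window is computed, and the candidate minimizing the coefficient of
#' variation of these window MADs is chosen. This picks the s0 that
#' makes the spread of d approximately independent of s.
#'
#' @inheritParams compute_d_statistics
#' @param n_windows number of s-percentile windows (default 100, capped
#'   at the number of genes).
#' @return a single non-negative number, an element of the candidate
#'   set; 0 (with a warning) for a degenerate all-zero-variance matrix.
#' @export
estimate_s0 <- function(values, gene_ids, groups, n_windows = 100) {
  m <- .sam_check_matrix(values, gene_ids, groups)
  rs <- .sam_r_s(m$values, which(m$groups == m$levels[2L]))
  s <- rs$s; r <- rs$r
  if (all(s == 0)) {
    warning("all genes have zero pooled variance; s0 set to 0")
    return(0)
  }
  cand <- c(0, unname(stats::quantile(s, probs = seq(0.05, 1, by = 0.05))))
  nw <- max(2L, min(as.integer(n_windows), length(s) %/% 2L))
  win <- cut(rank(s, ties.method = "first"), breaks = nw, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, stats::mad)
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

## All distinct assignments of n2 samples (to group 2) out of n, as a
## list of index vectors; the observed assignment is included.
.sam_assignments <- function(n, idx2) {
  comb <- utils::combn(n, length(idx2))
  lapply(seq_len(ncol(comb)), function(j) comb[, j])
}

#' Call differentially expressed genes (SAM)
#'
#' Full SAM-style pipeline: d statistics with an estimated (or supplied)
#' s0, a permutation null over group-label reassignments, per-gene
#' q-values, linear fold changes, and the boolean dysregulation call
#' \code{de_call = (q_value < q_threshold) AND (fold_change >
#' fc_threshold OR fold_change < 1/fc_threshold)}.
#'
#' The q-value attached to the gene of rank i (by decreasing |d|) is the
#' median over permutations of the number of null |d*| values at or
#' above |d_(i)|, divided by i (the observed count), capped at 1 and
#' made monotone non-decreasing from the top rank down.
#'
#' If the number of distinct label assignments is at most
#' \code{n_permutations} (or at most 10000), all assignments are
#' enumerated exhaustively and a message is emitted; otherwise
#' \code{n_permutations} random assignments are drawn using \code{seed}.
#'
#' @inheritParams compute_d_statistics
#' @param n_permutations number of label permutations (>= 1).
#' @param seed integer seed for the permutation draw (required, logged).
#' @param q_threshold q-value cutoff (default 0.05, i.e. q < 5\%).
#' @param fc_threshold linear fold-change cutoff (default 2). Fold
#'   change is the ratio of anti-logged group means, 2^(mean2 - mean1).
#' @param s0 optional fudge factor; estimated by \code{\link{estimate_s0}}
#'   when NULL.
#' @return object of class \code{sam_result}: a data.frame with columns
#'   \code{gene}, \code{d}, \code{s}, \code{fold_change},
#'   \code{q_value}, \code{direction} ("up"/"down"), \code{de_call};
#'   attributes \code{s0}, \code{n_permutations_used},
#'   \code{exhaustive}, \code{seed}, \code{group_levels}.
#' @export
call_de <- function(values, gene_ids, groups, n_permutations = 200,
                    seed, q_threshold = 0.05, fc_threshold = 2,
                    s0 = NULL) {
  if (missing(seed)) stop("seed is required")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  m <- .sam_check_matrix(values, gene_ids, groups)
  idx2 <- which(m$groups == m$levels[2L])
  n <- ncol(m$values)
  if (is.null(s0)) s0 <- estimate_s0(m$values, m$gene_ids, m$groups)

  obs <- .sam_r_s(m$values, idx2)
  denom <- obs$s + s0
  d_obs <- ifelse(denom > 0, obs$r / denom, NA_real_)

  n_total <- choose(n, length(idx2))
  exhaustive <- n_total <= max(n_permutations, 10000)
  if (exhaustive) {
    if (n_total > n_permutations)
      message(sprintf("enumerating all %d label assignments exhaustively", n_total))
    perms <- .sam_assignments(n, idx2)
  } else {
    set.seed(as.integer(seed))
    perms <- lapply(seq_len(n_permutations),
                    function(i) sort(sample.int(n, length(idx2))))
  }

  ## null |d| per permutation, genes x perms
  null_absd <- vapply(perms, function(ix) {
    rs <- .sam_r_s(m$values, ix)
    abs(rs$r / (rs$s + s0))
  }, numeric(nrow(m$values)))
  if (is.null(dim(null_absd)))
    null_absd <- matrix(null_absd, nrow = nrow(m$values))

  ok <- which(!is.na(d_obs))
  q <- rep(NA_real_, length(d_obs))
  if (length(ok)) {
    absd <- abs(d_obs[ok])
    ord <- order(absd, decreasing = TRUE)
    thr <- absd[ord]                      # thresholds, decreasing
    obs_count <- seq_along(thr)           # exceedances at each threshold
    ## per permutation: count of null |d*| >= threshold, for all ranks
    nulls <- null_absd[ok, , drop = FALSE]
    exceed <- vapply(seq_len(ncol(nulls)), function(b) {
      sn <- sort(nulls[, b])
      length(sn) - findInterval(thr, sn, left.open = TRUE)
    }, numeric(length(thr)))
    if (is.null(dim(exceed))) exceed <- matrix(exceed, nrow = length(thr))
    med_null <- apply(exceed, 1L, stats::median)
    raw <- pmin(1, med_null / obs_count)
    qq <- cummax(raw)                     # monotone from top rank down
    q[ok[ord]] <- qq
  }

  fc <- 2^obs$r
  direction <- ifelse(obs$r >= 0, "up", "down")
  de <- !is.na(q) & q < q_threshold &
    (fc > fc_threshold | fc < 1 / fc_threshold)

  out <- data.frame(gene = m$gene_ids, d = d_obs, s = obs$s,
                    fold_change = fc, q_value = q, direction = direction,
                    de_call = de, stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  attr(out, "n_permutations_used") <- length(perms)
  attr(out, "exhaustive") <- exhaustive
  attr(out, "seed") <- seed
  attr(out, "group_levels") <- m$levels
  class(out) <- c("sam_result", "data.frame")
  out
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("SAM two-class result: %d genes, %d DE calls (s0 = %.4g, %s%d permutations)\n",
              nrow(x), sum(x$de_call, na.rm = TRUE), attr(x, "s0"),
              if (isTRUE(attr(x, "exhaustive"))) "exhaustive " else "",
              attr(x, "n_permutations_used")))
  NextMethod()
}

#' Read a two-class expression matrix
#'
#' Reads a tab-delimited gene-by-sample table with a two-line header:
#' line 1 holds sample identifiers (first field is the gene-id column
#' name), line 2 the two-level group label of each sample.
#'
#' @param path file path.
#' @return list with \code{values} (numeric matrix), \code{gene_ids},
#'   \code{groups} (factor).
#' @export
read_expression_matrix <- function(path) {
  hdr <- readLines(path, n = 2L)
  samples <- strsplit(hdr[1L], "\t", fixed = TRUE)[[1L]][-1L]
  groups <- strsplit(hdr[2L], "\t", fixed = TRUE)[[1L]][-1L]
  dat <- utils::read.delim(path, skip = 2L, header = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(dat[, -1L, drop = FALSE])
  colnames(values) <- samples
  list(values = values, gene_ids = as.character(dat[[1L]]),
       groups = factor(groups))
}

#' Write a two-class expression matrix
#'
#' Inverse of \code{\link{read_expression_matrix}}.
#'
#' @param values numeric gene-by-sample matrix.
#' @param gene_ids gene identifiers.
#' @param groups group labels, one per sample.
#' @param path output file path.
#' @export
write_expression_matrix <- function(values, gene_ids, groups, path) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- colnames(values)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  writeLines(paste(c("gene", samples), collapse = "\t"), con)
  writeLines(paste(c("group", as.character(groups)), collapse = "\t"), con)
  utils::write.table(data.frame(gene_ids, values, check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write a SAM result table
#'
#' Tab-delimited with columns gene, d, s, fold_change, q_value,
#' direction, de_call.
#'
#' @param x a \code{sam_result}.
#' @param path output file path.
#' @export
write_sam_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
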