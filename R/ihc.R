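#' Immunohistochemistry histoscore analysis
#'
#' The histoscore condenses staining intensity and extent into one
#' number per patient and tissue compartment:
#' (3 x %strong + 2 x %moderate + 1 x %weak) / 100, ranging 0-3.
#' Scores in (0,1] (and exactly 0) indicate weak, (1,2] moderate and
#' (2,3] strong staining. Compartments compared are ovarian surface
#' epithelium (OSE), inclusion cysts (IC) and fallopian tube epithelium
#' (FTE) -- same patients, paired t-tests -- and epithelial ovarian
#' cancer (EOC) from separate patients, compared by one-way ANOVA with
#' Fisher's least-significant-difference (LSD) post hoc test.
#'
#' @name ihc_scoring
NULL

#' Compute a histoscore from staining percentages
#'
#' @param pct_strong,pct_moderate,pct_weak percentages of cells staining
#'   at each intensity (vectors recycled to common length).
#' @param tol allowed rounding excess on the percentage sum (default
#'   0.5).
#' @return data.frame with columns \code{value} (0-3) and \code{band}
#'   ("weak"/"moderate"/"strong").
#' @export
compute_histoscore <- function(pct_strong, pct_moderate, pct_weak,
                               tol = 0.5) {
  p <- cbind(pct_strong, pct_moderate, pct_weak)
  if (any(p < 0 | p > 100))
    stop("staining percentages must lie in [0, 100]")
  if (any(rowSums(p) > 100 + tol))
    stop("staining percentages sum above 100 (beyond rounding tolerance)")
  value <- (3 * p[, 1L] + 2 * p[, 2L] + 1 * p[, 3L]) / 100
  data.frame(value = value, band = histoscore_band(value),
             stringsAsFactors = FALSE)
}

#' Band a histoscore
#'
#' Half-open-from-the-left bins: 0 and (0,1] weak; (1,2] moderate;
#' (2,3] strong.
#'
#' @param value numeric histoscores in [0,3].
#' @return character vector of bands.
#' @export
histoscore_band <- function(value) {
  if (any(value < 0 | value > 3)) stop("histoscore must lie in [0, 3]")
  ifelse(value <= 1, "weak", ifelse(value <= 2, "moderate", "strong"))
}

## Fisher's LSD: pairwise t on group means with the pooled ANOVA MSE,
## df = N - k, unadjusted for multiplicity (the classical procedure).
.lsd_pairwise <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2L]
  df <- an[["Df"]][2L]
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  combs <- utils::combn(levels(groups), 2L)
  p <- apply(combs, 2L, function(pr) {
    se <- sqrt(mse * (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
    tval <- (means[pr[1L]] - means[pr[2L]]) / se
    2 * stats::pt(-abs(tval), df)
  })
  data.frame(group1 = combs[1L, ], group2 = combs[2L, ], p = unname(p),
             stringsAsFactors = FALSE)
}

#' Compare histoscores across tissue compartments
#'
#' Paired two-tailed t-tests for every pair among the within-patient
#' compartments (OSE, IC, FTE), restricted to patients with both
#' measurements; a one-way ANOVA over all four groups with LSD post hoc
#' p-values for every pair involving EOC (scored on separate patients).
#' Pairs with fewer than 2 complete pairs are skipped with a notice.
#'
#' @param paired data.frame with columns \code{patient} and one numeric
#'   histoscore column per within-patient compartment (e.g. \code{OSE},
#'   \code{IC}, \code{FTE}; NA where not assessed).
#' @param eoc numeric vector of histoscores from the cancer cohort.
#' @param alpha significance level for the NS marker (default 0.05).
#' @return data.frame with columns \code{group1}, \code{group2},
#'   \code{test} ("paired-t" or "anova-lsd"), \code{p},
#'   \code{significant}, \code{label} (formatted p or "NS").
#' @export
compare_compartments <- function(paired, eoc, alpha = 0.05) {
  comp <- setdiff(names(paired), "patient")
  rows <- list()
  degenerate_p <- function(x, y) {
    d <- x - y
    if (stats::sd(d) == 0) {
      if (all(d == 0)) return(1)          # t = 0/0 -> no difference
      warning("constant non-zero paired difference; p reported as NA (degenerate)")
      return(NA_real_)
    }
    stats::t.test(x, y, paired = TRUE)$p.value
  }
  for (i in seq_along(comp)) for (j in seq_len(i - 1L)) {
    a <- comp[j]; b <- comp[i]
    ok <- stats::complete.cases(paired[[a]], paired[[b]])
    if (sum(ok) < 2L) {
      message(sprintf("skipping %s vs %s: fewer than 2 complete pairs", a, b))
      next
    }
    p <- degenerate_p(paired[[a]][ok], paired[[b]][ok])
    rows[[length(rows) + 1L]] <-
      data.frame(group1 = a, group2 = b, test = "paired-t", p = p,
                 stringsAsFactors = FALSE)
  }
  ## ANOVA across all four groups; LSD for EOC pairs
  long_vals <- c(unlist(lapply(comp, function(cc) paired[[cc]][!is.na(paired[[cc]])])),
                 eoc)
  long_grp <- c(unlist(lapply(comp, function(cc)
    rep(cc, sum(!is.na(paired[[cc]]))))), rep("EOC", length(eoc)))
  anova_p <- NA_real_
  if (length(unique(long_grp)) >= 2L && length(eoc) >= 2L) {
    fit <- stats::aov(long_vals ~ factor(long_grp))
    anova_p <- stats::anova(fit)[["Pr(>F)"]][1L]
    lsd <- .lsd_pairwise(long_vals, long_grp)
    lsd <- lsd[lsd$group1 == "EOC" | lsd$group2 == "EOC", , drop = FALSE]
    for (r in seq_len(nrow(lsd)))
      rows[[length(rows) + 1L]] <-
        data.frame(group1 = lsd$group1[r], group2 = lsd$group2[r],
                   test = "anova-lsd", p = lsd$p[r],
                   stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group1 = character(0), group2 = character(0),
                      test = character(0), p = numeric(0))
  out$significant <- !is.na(out$p) & out$p < alpha
  out$label <- ifelse(out$significant, formatC(out$p, digits = 2, format = "g"),
                      "NS")
  attr(out, "anova_p") <- anova_p
  rownames(out) <- NULL
  out
}

#' Categorize a cohort by histoscore band
#'
#' @param scores numeric histoscores.
#' @return data.frame with one row per band (weak/moderate/strong):
#'   \code{band}, \code{n}, \code{pct} (rounded to nearest integer).
#' @export
categorize_cohort <- function(scores) {
  if (!length(scores)) stop("empty score list")
  band <- factor(histoscore_band(scores),
                 levels = c("weak", "moderate", "strong"))
  n <- as.integer(table(band))
  data.frame(band = levels(band), n = n,
             pct = as.integer(round(100 * n / length(scores))),
             stringsAsFactors = FALSE)
}
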