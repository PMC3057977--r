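#' Kaplan-Meier and log-rank survival analysis
#'
#' Product-limit survival estimation, median survival, the two-group
#' log-rank test, and dichotomization of a patient cohort at the median
#' histoscore for outcome association. Estimation is delegated to the
#' survival package (survfit/survdiff); this module provides the
#' record-level interface used by the rest of the pipeline.
#'
#' @name survival_analysis
NULL

.check_records <- function(records) {
  need <- c("time", "event")
  if (!all(need %in% names(records)))
    stop("survival records need columns time, event")
  if (any(records$time < 0)) stop("negative survival times")
  records$event <- as.logical(records$event)
  records
}

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator over the pooled records. The median is the
#' smallest time at which the survival curve is at or below 0.5;
#' \code{NA} ("not reached") when the curve never crosses 0.5.
#'
#' @param records data.frame with columns \code{time} (months, >= 0) and
#'   \code{event} (TRUE = event observed, FALSE = censored).
#' @return object of class \code{km_curve}: list with \code{time}
#'   (ascending), \code{surv} (non-increasing, starts below 1 only after
#'   the first event), \code{n_risk}, \code{n_event}, \code{median},
#'   \code{n}.
#' @export
km_estimate <- function(records) {
  records <- .check_records(records)
  if (nrow(records) < 1L) stop("at least one record required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  med <- {
    at <- which(fit$surv <= 0.5)
    if (length(at)) fit$time[min(at)] else NA_real_
  }
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s months\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Write a KM curve as a step-function table
#'
#' Tab-delimited columns time, surv, n_risk, n_event; suitable for step
#' plotting.
#'
#' @param curve a \code{km_curve}.
#' @param path output file path.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.table(data.frame(time = curve$time, surv = curve$surv,
                                n_risk = curve$n_risk,
                                n_event = curve$n_event),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank over the pooled event
#' times, 1 degree of freedom. With zero events overall the statistic is
#' undefined and reported as NA.
#'
#' @param records data.frame with columns \code{time}, \code{event},
#'   \code{stratum} (two levels).
#' @return list with \code{chisq}, \code{p}, \code{n} (per stratum),
#'   \code{observed}, \code{expected} (per stratum).
#' @export
logrank_test <- function(records) {
  records <- .check_records(records)
  if (!"stratum" %in% names(records)) stop("records need a stratum column")
  records$stratum <- factor(records$stratum)
  if (nlevels(records$stratum) != 2L) stop("exactly two strata required")
  if (any(table(records$stratum) == 0L)) stop("both strata must be non-empty")
  if (sum(records$event) == 0L) {
    warning("no events in either stratum; log-rank statistic undefined")
    return(list(chisq = NA_real_, p = NA_real_,
                n = table(records$stratum), observed = NULL, expected = NULL))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                           data = records)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = sd$n, observed = sd$obs, expected = sd$exp)
}

#' Dichotomize a cohort at the median score and test survival
#'
#' Patients are split at the median score: scores strictly above the
#' median form the "high" stratum; scores at or below it (ties at the
#' median deliberately included) form the "low" stratum. Per-stratum KM
#' medians and the log-rank comparison are reported.
#'
#' @param scores data.frame with columns \code{patient}, \code{score}.
#' @param records data.frame with columns \code{patient}, \code{time},
#'   \code{event}.
#' @return list with \code{cutoff} (the median score), \code{strata}
#'   (data.frame patient/score/stratum), \code{km} (list of
#'   \code{km_curve} for low and high), \code{medians} (named numeric),
#'   \code{logrank} (see \code{\link{logrank_test}}).
#' @export
dichotomize_at_median <- function(scores, records) {
  joined <- merge(scores, records, by = "patient")
  if (!nrow(joined)) stop("no patients shared between scores and records")
  med <- stats::median(joined$score)
  if (all(joined$score == joined$score[1L]))
    stop("all scores identical; dichotomization impossible")
  joined$stratum <- ifelse(joined$score > med, "high", "low")
  km <- lapply(split(joined, joined$stratum), km_estimate)
  medians <- vapply(km, function(k) k$median, numeric(1))
  lr <- logrank_test(joined)
  list(cutoff = med,
       strata = joined[, c("patient", "score", "stratum")],
       km = km, medians = medians, logrank = lr)
}
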