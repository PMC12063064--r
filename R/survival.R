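#' Build survival records from a patients table
#'
#' Time-to-event records from one of the two time origins: primary
#' diagnosis (`followup_from_primary_months`) or metastasis diagnosis
#' (`followup_from_mets_months`). For synchronous patients the two origins
#' coincide; for metachronous patients the metastasis-origin clock starts
#' `months_primary_to_mets` later.
#'
#' @param patients Validated patients data.frame (see [read_cohort()]).
#' @param origin `"primary_dx"` or `"metastasis_dx"`.
#' @param group Optional column name used as the group label (e.g.
#'   `"timing"`, `"sex"`, `"primary_location"`), or a vector of labels of
#'   length `nrow(patients)`.
#' @return Data.frame `patient_id`, `time_months`, `event` (1 = death,
#'   0 = censored), `origin`, and `group` if requested.
#' @export
survival_records <- function(patients, origin = c("primary_dx", "metastasis_dx"),
                             group = NULL) {
  origin <- match.arg(origin)
  time <- switch(origin,
                 primary_dx = patients$followup_from_primary_months,
                 metastasis_dx = patients$followup_from_mets_months)
  out <- data.frame(
    patient_id = patients$patient_id,
    time_months = time,
    event = as.integer(patients$event == "died"),
    origin = origin,
    stringsAsFactors = FALSE
  )
  if (!is.null(group)) {
    out$group <- if (length(group) == 1L && group %in% names(patients)) {
      patients[[group]]
    } else {
      group
    }
  }
  out
}

#' Kaplan-Meier fit
#'
#' Product-limit estimate of the survival function with Greenwood-variance
#' confidence intervals on the complementary log-log scale, wrapping
#' [survival::survfit()]. The median is the smallest time at which the
#' estimated survival drops to 0.5 or below; with all records censored it
#' is not reached and reported as `NA`.
#'
#' @param records Data.frame from [survival_records()] (needs
#'   `time_months`, `event`). All records must share one origin.
#' @param conf_level Confidence level for the pointwise intervals and the
#'   median CI (default 0.95).
#' @return A `km_curve` object: `time`, `n_risk`, `n_event`, `surv`,
#'   `ci_low`, `ci_high` (step function at the event/censoring times),
#'   `median_months`, `median_ci`, `n`, `n_events`, and the underlying
#'   `survfit` object in `$fit`.
#' @export
km_fit <- function(records, conf_level = 0.95) {
  if (nrow(records) == 0L) stop("no survival records", call. = FALSE)
  if ("origin" %in% names(records) && length(unique(records$origin)) > 1L) {
    stop("records mix time origins", call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(records$time_months, records$event) ~ 1,
    conf.type = "log-log", conf.int = conf_level
  )
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  structure(
    list(
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      surv = fit$surv, ci_low = fit$lower, ci_high = fit$upper,
      median_months = if (is.na(med)) NA_real_ else med,
      median_ci = c(low = unname(tab["0.95LCL"]), high = unname(tab["0.95UCL"])),
      n = unname(tab["records"]), n_events = unname(tab["events"]),
      conf_level = conf_level,
      fit = fit
    ),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median_months)) "not reached" else
    sprintf("%.1f months (%s %.1f, %.1f)",
            x$median_months, paste0(round(100 * x$conf_level), "% CI"),
            x$median_ci[["low"]], x$median_ci[["high"]])
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median %s\n",
              x$n, x$n_events, med))
  invisible(x)
}

#' Survival probability at fixed horizons
#'
#' Evaluates the right-continuous Kaplan-Meier step function at the given
#' horizons (the value *at* the horizon, after any events occurring exactly
#' then). `S(0) = 1` always; horizons beyond the last observed time carry
#' the last estimate forward.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param horizons Numeric vector of non-negative times (months).
#' @return Numeric vector of survival probabilities in `[0, 1]`.
#' @export
survival_at <- function(curve, horizons) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(horizons < 0)) stop("negative horizon", call. = FALSE)
  s <- summary(curve$fit, times = horizons, extend = TRUE)
  s$surv
}

#' Gehan-Breslow generalized Wilcoxon test
#'
#' Compares two survival curves with the generalized Wilcoxon test of
#' Gehan/Breslow: a weighted log-rank statistic in which each distinct
#' event time is weighted by the total number at risk, so early deaths
#' carry more weight than under the log-rank test. The statistic is
#' referred to a chi-square distribution on 1 degree of freedom.
#'
#' @param records_a,records_b Survival records (see [survival_records()])
#'   for the two groups, sharing one time origin.
#' @param weights `"gehan"` (at-risk weights, default) or `"logrank"`
#'   (unit weights) for sensitivity analysis.
#' @return A `curve_test` object: `statistic` (chi-square), `df`,
#'   `p_value`, `test`, `n`, and `zero_events` flag set when either group
#'   contributes no events (the p-value is then uninformative).
#' @export
wilcoxon_compare <- function(records_a, records_b,
                             weights = c("gehan", "logrank")) {
  weights <- match.arg(weights)
  if (nrow(records_a) == 0L || nrow(records_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  time <- c(records_a$time_months, records_b$time_months)
  event <- c(records_a$event, records_b$event)
  in_a <- c(rep(TRUE, nrow(records_a)), rep(FALSE, nrow(records_b)))

  ev_times <- sort(unique(time[event == 1]))
  obs_minus_exp <- 0
  variance <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & in_a)
    d_j <- sum(event == 1 & time == t)
    d1_j <- sum(event == 1 & time == t & in_a)
    w <- if (weights == "gehan") n_j else 1
    obs_minus_exp <- obs_minus_exp + w * (d1_j - d_j * n1_j / n_j)
    if (n_j > 1) {
      variance <- variance +
        w^2 * d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  zero_events <- sum(records_a$event) == 0L || sum(records_b$event) == 0L
  if (variance == 0) {
    chisq <- 0; p <- 1
  } else {
    chisq <- obs_minus_exp^2 / variance
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  structure(
    list(statistic = chisq, df = 1L, p_value = p,
         test = if (weights == "gehan") "Gehan-Breslow Wilcoxon" else "log-rank",
         n = c(nrow(records_a), nrow(records_b)),
         zero_events = zero_events),
    class = "curve_test"
  )
}

#' @export
print.curve_test <- function(x, ...) {
  cat(sprintf("%s test: chi-square = %.3f (df %d), p = %.4g%s\n",
              x$test, x$statistic, x$df, x$p_value,
              if (x$zero_events) " [a group has zero events]" else ""))
  invisible(x)
}

#' Dual-origin survival analysis by metastasis timing
#'
#' Fits Kaplan-Meier curves for synchronous and metachronous patients from
#' both time origins (primary diagnosis and metastasis diagnosis), compares
#' the two groups at each origin with the Gehan-Wilcoxon test, and reports
#' the lead-time difference: the gap between group medians from the primary
#' origin minus the gap from the metastasis origin. Under lead-time-only
#' dynamics the metastasis-origin curves coincide and the difference equals
#' the median detection lead time.
#'
#' @param patients Validated patients data.frame.
#' @param weights Passed to [wilcoxon_compare()].
#' @return A `dual_origin` object: per origin a list of `km_curve`s named
#'   by timing group and a `curve_test`; plus `median_table` and
#'   `lead_time_months`.
#' @export
dual_origin_analysis <- function(patients, weights = "gehan") {
  res <- list()
  meds <- list()
  for (origin in c("primary_dx", "metastasis_dx")) {
    rec <- survival_records(patients, origin, group = "timing")
    sync <- rec[rec$group == "synchronous", , drop = FALSE]
    meta <- rec[rec$group == "metachronous", , drop = FALSE]
    curves <- list(synchronous = km_fit(sync), metachronous = km_fit(meta))
    res[[origin]] <- list(
      curves = curves,
      comparison = wilcoxon_compare(meta, sync, weights = weights)
    )
    meds[[origin]] <- c(synchronous = curves$synchronous$median_months,
                        metachronous = curves$metachronous$median_months)
  }
  gap <- function(m) m[["metachronous"]] - m[["synchronous"]]
  structure(
    list(
      primary_dx = res$primary_dx,
      metastasis_dx = res$metastasis_dx,
      median_table = do.call(rbind, lapply(names(meds), function(o) {
        data.frame(origin = o,
                   synchronous_median = meds[[o]][["synchronous"]],
                   metachronous_median = meds[[o]][["metachronous"]],
                   p_value = res[[o]]$comparison$p_value,
                   stringsAsFactors = FALSE)
      })),
      lead_time_months = gap(meds$primary_dx) - gap(meds$metastasis_dx)
    ),
    class = "dual_origin"
  )
}

#' @export
print.dual_origin <- function(x, ...) {
  cat("Dual-origin survival analysis (synchronous vs. metachronous)\n")
  print(x$median_table, row.names = FALSE)
  cat(sprintf("Lead-time difference: %.1f months\n", x$lead_time_months))
  invisible(x)
}

#' Kaplan-Meier curves by an arbitrary grouping
#'
#' Convenience wrapper: per-level [km_fit()] plus a pooled Gehan-Wilcoxon
#' comparison of the first two levels (comparisons across > 2 groups are
#' made pairwise by the caller).
#'
#' @param patients Validated patients data.frame.
#' @param by Column name of the grouping factor.
#' @param origin Time origin; see [survival_records()].
#' @param weights Passed to [wilcoxon_compare()].
#' @return List with `curves` (named list of `km_curve`), and `comparison`
#'   (`curve_test`, `NULL` for a single group).
#' @export
km_by_group <- function(patients, by, origin = "primary_dx",
                        weights = "gehan") {
  rec <- survival_records(patients, origin, group = by)
  levels <- unique(rec$group)
  curves <- lapply(levels, function(l) km_fit(rec[rec$group == l, , drop = FALSE]))
  names(curves) <- levels
  comparison <- NULL
  if (length(levels) >= 2L) {
    comparison <- wilcoxon_compare(rec[rec$group == levels[1L], , drop = FALSE],
                                   rec[rec$group == levels[2L], , drop = FALSE],
                                   weights = weights)
  } else {
    warning("single group: comparison skipped", call. = FALSE)
  }
  list(curves = curves, comparison = comparison)
}
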