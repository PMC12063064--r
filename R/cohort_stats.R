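# parameters reported per patient-organ set, in table row order
SUMMARY_PARAMS <- c(
  number = "n_total",
  lpr = "lpr",
  average_diameter_mm = "mean_diameter_mm",
  sd_diameter_mm = "sd_diameter_mm",
  largest_diameter_mm = "largest_diameter_mm",
  n_clusters = "n_waves",
  n_single = "n_isolated"
)

.qtype <- function(quantile_rule) {
  switch(match.arg(quantile_rule, c("linear", "nearest")), linear = 7L, nearest = 1L)
}

.median_iqr <- function(x, qtype) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = qtype, names = FALSE)
  c(iqr_low = q[1L], median = q[2L], iqr_high = q[3L], n = length(x))
}

#' Cohort summary table of metastasis parameters
#'
#' Aggregates per-patient summaries (one organ at a time) into a table of
#' medians with interquartile ranges, one row per parameter: number of
#' metastases, LPR, average diameter, diameter SD, largest diameter, number
#' of waves, number of single (isolated) metastases.
#'
#' @param summaries Data.frame from [summarize_cohort()].
#' @param organ Organ filter, `"lung"` or `"liver"`.
#' @param quantile_rule `"linear"` (interpolated quantiles, default) or
#'   `"nearest"` (nearest-rank).
#' @return Data.frame with columns `parameter`, `median`, `iqr_low`,
#'   `iqr_high`, `n`.
#' @export
cohort_table <- function(summaries, organ, quantile_rule = "linear") {
  organ <- match.arg(organ, ORGANS)
  s <- summaries[summaries$organ == organ, , drop = FALSE]
  if (nrow(s) == 0L) {
    stop(sprintf("no patients with organ = '%s' after filtering", organ),
         call. = FALSE)
  }
  qtype <- .qtype(quantile_rule)
  rows <- lapply(names(SUMMARY_PARAMS), function(par) {
    v <- .median_iqr(s[[SUMMARY_PARAMS[[par]]]], qtype)
    data.frame(parameter = par, median = v[["median"]],
               iqr_low = v[["iqr_low"]], iqr_high = v[["iqr_high"]],
               n = v[["n"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare metastasis parameters between timing groups
#'
#' For one organ, compares every per-patient parameter between metachronous
#' and synchronous patients: group medians with IQRs, plus a two-sided
#' two-sample Student's t-test on the raw per-patient values (pooled
#' variance by default, Welch optionally). The medians describe the skewed
#' distributions; the t-test is the comparison applied to the raw values.
#'
#' @param summaries Data.frame from [summarize_cohort()]; must carry a
#'   `timing` column (join with the patients table first, or pass
#'   `patients`).
#' @param organ Organ filter.
#' @param patients Optional patients table used to attach `timing` by
#'   `patient_id`.
#' @param var_equal `TRUE` for the pooled-variance test (default), `FALSE`
#'   for Welch.
#' @param quantile_rule See [cohort_table()].
#' @return Data.frame with one row per parameter: medians and IQRs per
#'   group, `p_value` (NA when a group has < 2 usable values), and
#'   `significant` at the 0.05 level.
#' @export
compare_groups <- function(summaries, organ, patients = NULL,
                           var_equal = TRUE, quantile_rule = "linear") {
  organ <- match.arg(organ, ORGANS)
  if (!"timing" %in% names(summaries)) {
    if (is.null(patients)) {
      stop("summaries lack a 'timing' column; supply `patients`", call. = FALSE)
    }
    summaries$timing <- patients$timing[match(summaries$patient_id,
                                              patients$patient_id)]
  }
  s <- summaries[summaries$organ == organ, , drop = FALSE]
  meta <- s[s$timing == "metachronous", , drop = FALSE]
  sync <- s[s$timing == "synchronous", , drop = FALSE]
  if (nrow(meta) == 0L || nrow(sync) == 0L) {
    stop("both timing groups must be non-empty", call. = FALSE)
  }
  qtype <- .qtype(quantile_rule)
  rows <- lapply(names(SUMMARY_PARAMS), function(par) {
    col <- SUMMARY_PARAMS[[par]]
    a <- meta[[col]][!is.na(meta[[col]])]
    b <- sync[[col]][!is.na(sync[[col]])]
    qa <- .median_iqr(a, qtype); qb <- .median_iqr(b, qtype)
    p <- if (length(a) >= 2L && length(b) >= 2L &&
             (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      stats::t.test(a, b, var.equal = var_equal)$p.value
    } else if (length(a) >= 2L && length(b) >= 2L) {
      1  # identical constant groups: no evidence of a difference
    } else {
      NA_real_
    }
    data.frame(
      parameter = par,
      metachronous_median = qa[["median"]], metachronous_iqr_low = qa[["iqr_low"]],
      metachronous_iqr_high = qa[["iqr_high"]], n_metachronous = qa[["n"]],
      synchronous_median = qb[["median"]], synchronous_iqr_low = qb[["iqr_low"]],
      synchronous_iqr_high = qb[["iqr_high"]], n_synchronous = qb[["n"]],
      p_value = p, significant = !is.na(p) && p < 0.05,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Cohort composition table
#'
#' Categorical counts with percentages (one decimal) for sex, primary
#' tumour location, metastasis timing, and organ involvement pattern
#' (liver-only / lung-only / both), mirroring a clinical "basic features"
#' table.
#'
#' @param patients Validated patients data.frame.
#' @param metastases Validated metastases data.frame (or a `cohort`);
#'   used to derive the organ pattern per patient.
#' @return Data.frame with columns `category`, `level`, `count`, `percent`.
#'   Within each category the counts sum to the number of patients.
#' @export
composition_table <- function(patients, metastases) {
  if (inherits(patients, "cohort")) {
    metastases <- patients$metastases
    patients <- patients$patients
  }
  organs_by_patient <- split(metastases$organ, metastases$patient_id)
  pattern <- vapply(patients$patient_id, function(id) {
    o <- unique(organs_by_patient[[id]])
    if (is.null(o)) return("none")
    if (all(ORGANS %in% o)) "both" else if ("liver" %in% o) "liver_only"
    else "lung_only"
  }, "")
  n <- nrow(patients)
  one <- function(category, values, levels) {
    counts <- vapply(levels, function(l) sum(values == l), 0L)
    data.frame(category = category, level = levels, count = unname(counts),
               percent = round(100 * unname(counts) / n, 1),
               stringsAsFactors = FALSE)
  }
  pat_levels <- intersect(c("liver_only", "lung_only", "both", "none"),
                          unique(c(pattern, "liver_only", "lung_only", "both")))
  if (!"none" %in% pattern) pat_levels <- setdiff(pat_levels, "none")
  rbind(
    one("sex", patients$sex, SEXES),
    one("primary_location", patients$primary_location, LOCATIONS),
    one("timing", patients$timing, TIMINGS),
    one("organ_pattern", pattern, pat_levels)
  )
}
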