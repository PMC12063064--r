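#' Organ-specific clustering tolerance
#'
#' Default diameter tolerance used to decide whether two metastases belong to
#' the same dispatch wave: 1 mm for lung metastases, 3 mm for liver
#' metastases (liver diameters are measured with lower precision on CT).
#'
#' @param organ `"lung"` or `"liver"`.
#' @return Tolerance in millimetres.
#' @export
#' @examples
#' default_tolerance("lung")   # 1
#' default_tolerance("liver")  # 3
default_tolerance <- function(organ) {
  organ <- match.arg(organ, c("lung", "liver"))
  switch(organ, lung = 1.0, liver = 3.0)
}

#' Cluster metastasis diameters into waves
#'
#' Partitions one patient-organ set of diameters into waves (clusters of
#' size >= 2) and isolated metastases, using a one-dimensional gap rule on
#' the sorted diameters. Under single linkage a wave breaks wherever an
#' adjacent gap exceeds the tolerance; under complete linkage waves are
#' formed greedily from the smallest diameter upward and capped at a total
#' width of one tolerance (a new wave starts at the first value exceeding
#' the current wave's minimum + tolerance). Boundary ties are clustered:
#' the rule is "difference <= tolerance".
#'
#' The result is independent of the input order (diameters are sorted first)
#' and conserves the input multiset: every diameter lands in exactly one
#' cluster or in `isolated`.
#'
#' @param diameters Numeric vector of positive diameters (mm), length >= 1.
#'   Duplicates are allowed and meaningful.
#' @param tolerance_mm Positive clustering tolerance in mm. See
#'   [default_tolerance()].
#' @param linkage `"single"` (default) or `"complete"`.
#' @return A `wave_partition` object: list with `clusters` (list of numeric
#'   vectors, each length >= 2, ascending), `isolated` (numeric vector),
#'   `tolerance_mm`, and `linkage`.
#' @export
#' @examples
#' cluster_waves(c(5.0, 5.5, 6.0, 8.0), tolerance_mm = 1)
#' cluster_waves(c(5.0, 5.8, 6.6), tolerance_mm = 1, linkage = "complete")
cluster_waves <- function(diameters, tolerance_mm, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (length(diameters) == 0L) {
    stop("empty metastasis set", call. = FALSE)
  }
  if (!is.numeric(diameters) || anyNA(diameters) || any(!is.finite(diameters)) ||
      any(diameters <= 0)) {
    stop("diameters must be positive finite numbers", call. = FALSE)
  }
  if (!is.numeric(tolerance_mm) || length(tolerance_mm) != 1L || tolerance_mm <= 0) {
    stop("tolerance_mm must be a single positive number", call. = FALSE)
  }
  d <- sort(as.numeric(diameters))
  n <- length(d)
  # block id per sorted value under the chosen rule
  block <- integer(n)
  block[1L] <- 1L
  if (n > 1L) {
    if (linkage == "single") {
      for (i in 2:n) {
        block[i] <- if (d[i] - d[i - 1L] <= tolerance_mm) block[i - 1L] else block[i - 1L] + 1L
      }
    } else {
      block_min <- d[1L]
      for (i in 2:n) {
        if (d[i] - block_min <= tolerance_mm) {
          block[i] <- block[i - 1L]
        } else {
          block[i] <- block[i - 1L] + 1L
          block_min <- d[i]
        }
      }
    }
  }
  groups <- split(d, block)
  sizes <- lengths(groups)
  structure(
    list(
      clusters = unname(groups[sizes >= 2L]),
      isolated = as.numeric(unlist(groups[sizes < 2L], use.names = FALSE)),
      tolerance_mm = tolerance_mm,
      linkage = linkage
    ),
    class = "wave_partition"
  )
}

#' @export
print.wave_partition <- function(x, ...) {
  cat(sprintf(
    "Wave partition (%s linkage, tolerance %.1f mm): %d wave(s), %d isolated\n",
    x$linkage, x$tolerance_mm, length(x$clusters), length(x$isolated)
  ))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  wave %d: %s\n", i, paste(format(x$clusters[[i]]), collapse = ", ")))
  }
  if (length(x$isolated)) {
    cat("  isolated:", paste(format(x$isolated), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Linear/parallel ratio from a wave partition
#'
#' LPR = (sum_c - sum_i) / (sum_c + sum_i), where `sum_c` counts metastases
#' assigned to waves (clusters of size >= 2) and `sum_i` counts isolated
#' metastases. LPR is +1 when every metastasis clusters (pure linear
#' dissemination) and -1 when none do (pure parallel). The value is always
#' computed, but sets with fewer than `min_n` metastases carry a `low_n`
#' flag: with very few metastases the statistic is formally defined yet
#' carries little evidence (a singleton is always isolated, hence LPR -1).
#'
#' @param partition A `wave_partition` from [cluster_waves()].
#' @param min_n Sets with `n_total < min_n` are flagged low-confidence.
#'   Default 3.
#' @return An `lpr_result`: list with `sum_clustered`, `sum_isolated`,
#'   `lpr`, `n_waves`, `n_isolated`, `n_total`, `low_n`.
#' @export
#' @examples
#' p <- cluster_waves(c(5.0, 5.5, 6.0, 8.0), tolerance_mm = 1)
#' compute_lpr(p)  # sum_c 3, sum_i 1, LPR 0.5
compute_lpr <- function(partition, min_n = 3L) {
  stopifnot(inherits(partition, "wave_partition"))
  sum_c <- sum(lengths(partition$clusters))
  sum_i <- length(partition$isolated)
  n <- sum_c + sum_i
  structure(
    list(
      sum_clustered = sum_c,
      sum_isolated = sum_i,
      lpr = (sum_c - sum_i) / n,
      n_waves = length(partition$clusters),
      n_isolated = sum_i,
      n_total = n,
      low_n = n < min_n
    ),
    class = "lpr_result"
  )
}

#' @export
print.lpr_result <- function(x, ...) {
  cat(sprintf(
    "LPR %.3f (sum_c %d, sum_i %d, %d wave(s), n = %d)%s\n",
    x$lpr, x$sum_clustered, x$sum_isolated, x$n_waves, x$n_total,
    if (x$low_n) " [low n]" else ""
  ))
  invisible(x)
}

#' Per-patient metastasis summary
#'
#' Clusters one patient-organ diameter set and reports the per-patient
#' parameters: total count, mean and sample SD of diameters, largest
#' diameter, number of waves, number of isolated metastases, and the LPR.
#'
#' @param diameters Numeric vector of positive diameters (mm).
#' @param organ `"lung"` or `"liver"`; sets the default tolerance.
#' @param tolerance_mm Override for the organ tolerance.
#' @param linkage Passed to [cluster_waves()].
#' @param min_n Passed to [compute_lpr()].
#' @return One-row data.frame with columns `n_total`, `mean_diameter_mm`,
#'   `sd_diameter_mm` (NA for n = 1), `largest_diameter_mm`, `n_waves`,
#'   `n_isolated`, `lpr`, `low_n`, `linkage`, `tolerance_mm`.
#' @export
#' @examples
#' summarize_patient(c(6.0, 6.5, 6.5, 12.0), organ = "lung")
summarize_patient <- function(diameters, organ = c("lung", "liver"),
                              tolerance_mm = NULL,
                              linkage = c("single", "complete"),
                              min_n = 3L) {
  organ <- match.arg(organ)
  linkage <- match.arg(linkage)
  if (is.null(tolerance_mm)) tolerance_mm <- default_tolerance(organ)
  part <- cluster_waves(diameters, tolerance_mm, linkage)
  lpr <- compute_lpr(part, min_n = min_n)
  data.frame(
    n_total = lpr$n_total,
    mean_diameter_mm = mean(diameters),
    sd_diameter_mm = if (length(diameters) > 1L) stats::sd(diameters) else NA_real_,
    largest_diameter_mm = max(diameters),
    n_waves = lpr$n_waves,
    n_isolated = lpr$n_isolated,
    lpr = lpr$lpr,
    low_n = lpr$low_n,
    linkage = linkage,
    tolerance_mm = tolerance_mm,
    stringsAsFactors = FALSE
  )
}

#' Per-patient summaries for a whole cohort
#'
#' Applies [summarize_patient()] to every (patient, organ) metastasis set,
#' using the organ default tolerance unless overridden.
#'
#' @param sets Data.frame of metastasis sets from
#'   [group_by_patient_organ()], or a validated metastases table
#'   (patient_id, organ, diameter_mm) which is grouped first.
#' @param linkage,min_n Passed through.
#' @param tolerances Named numeric vector of per-organ tolerances; defaults
#'   to `c(lung = 1, liver = 3)`.
#' @return Data.frame with one row per patient-organ set: `patient_id`,
#'   `organ`, plus the [summarize_patient()] columns.
#' @export
summarize_cohort <- function(sets, linkage = c("single", "complete"),
                             min_n = 3L,
                             tolerances = c(lung = 1.0, liver = 3.0)) {
  linkage <- match.arg(linkage)
  if (is.data.frame(sets) && "diameter_mm" %in% names(sets)) {
    sets <- group_by_patient_organ(sets)
  }
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    organ <- sets$organ[i]
    s <- summarize_patient(sets$diameters[[i]], organ = organ,
                           tolerance_mm = unname(tolerances[[organ]]),
                           linkage = linkage, min_n = min_n)
    cbind(data.frame(patient_id = sets$patient_id[i], organ = organ,
                     stringsAsFactors = FALSE), s)
  })
  do.call(rbind, rows)
}
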