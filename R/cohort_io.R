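#' @keywords internal
ORGANS <- c("lung", "liver")
SEXES <- c("female", "male")
LOCATIONS <- c("head", "body", "tail")
TIMINGS <- c("synchronous", "metachronous")
EVENTS <- c("died", "censored")

# months are recorded to integer or half-month precision in clinical tables;
# allow this much slack when checking additivity of intervals
MONTH_TOL <- 0.51

.norm_names <- function(df, col_map) {
  nm <- tolower(trimws(names(df)))
  if (!is.null(col_map)) {
    # col_map: c(canonical = "actual_name_in_file")
    for (canon in names(col_map)) {
      hit <- which(nm == tolower(col_map[[canon]]))
      if (length(hit)) nm[hit[1L]] <- canon
    }
  }
  names(df) <- nm
  df
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.reject <- function(table, line, reason) {
  data.frame(table = table, line = line, reason = reason,
             stringsAsFactors = FALSE)
}

#' Read and validate a metastasis cohort
#'
#' Reads the two canonical delimited tables — per-metastasis rows
#' (`patient_id, organ, diameter_mm`) and per-patient rows (`patient_id,
#' sex, primary_location, timing, months_primary_to_mets,
#' followup_from_primary_months, event`) — validates every row against the
#' schema invariants, and returns accepted rows in file order together with
#' a rejection report. Column names are matched case-insensitively; a
#' column-mapping vector adapts files whose headers differ from the
#' canonical names.
#'
#' Row-level validation (rejected rows are reported, not fatal):
#' non-positive, non-finite or non-numeric diameters; unknown organ, sex,
#' location, timing or event tokens; negative intervals; synchronous
#' patients with a nonzero primary-to-metastasis interval; follow-up from
#' primary shorter than the primary-to-metastasis interval; duplicated
#' patient ids; metastasis rows whose patient is absent from the patients
#' table (orphans). A missing required column is a hard error.
#'
#' @param metastases_file,patients_file Paths to delimited text files with
#'   a header row (UTF-8).
#' @param sep Field delimiter, `","` by default (use `"\t"` for TSV).
#' @param metastases_map,patients_map Optional named character vectors
#'   mapping canonical column names to the names used in the file, e.g.
#'   `c(diameter_mm = "Diameter")`.
#' @return A list of class `cohort`: `metastases` (accepted metastasis
#'   rows), `patients` (accepted patient rows, with derived
#'   `followup_from_mets_months`), `rejected` (data.frame of table, line
#'   number, reason).
#' @export
read_cohort <- function(metastases_file, patients_file, sep = ",",
                        metastases_map = NULL, patients_map = NULL) {
  mets <- utils::read.table(metastases_file, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE,
                            colClasses = "character", encoding = "UTF-8")
  pats <- utils::read.table(patients_file, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE,
                            colClasses = "character", encoding = "UTF-8")
  mets <- .norm_names(mets, metastases_map)
  pats <- .norm_names(pats, patients_map)
  .require_cols(mets, c("patient_id", "organ", "diameter_mm"), "metastases")
  .require_cols(pats, c("patient_id", "sex", "primary_location", "timing",
                        "months_primary_to_mets",
                        "followup_from_primary_months", "event"),
                "patients")
  validate_cohort(mets, pats)
}

#' Validate in-memory cohort tables
#'
#' Same validation as [read_cohort()] but starting from data.frames
#' (e.g. simulator output). Values may be character or numeric.
#'
#' @param metastases,patients Data.frames in the canonical schemas.
#' @return A `cohort` list; see [read_cohort()].
#' @export
validate_cohort <- function(metastases, patients) {
  rej <- list()

  # --- patients -------------------------------------------------------
  p <- patients
  p$patient_id <- as.character(p$patient_id)
  keep <- rep(TRUE, nrow(p))
  tok <- function(x) tolower(trimws(as.character(x)))
  p$sex <- tok(p$sex); p$primary_location <- tok(p$primary_location)
  p$timing <- tok(p$timing); p$event <- tok(p$event)
  num <- function(x) suppressWarnings(as.numeric(x))
  p$months_primary_to_mets <- num(p$months_primary_to_mets)
  p$followup_from_primary_months <- num(p$followup_from_primary_months)

  for (i in seq_len(nrow(p))) {
    reason <- NULL
    if (!p$sex[i] %in% SEXES) reason <- sprintf("unknown sex token '%s'", p$sex[i])
    else if (!p$primary_location[i] %in% LOCATIONS)
      reason <- sprintf("unknown primary_location token '%s'", p$primary_location[i])
    else if (!p$timing[i] %in% TIMINGS)
      reason <- sprintf("unknown timing token '%s'", p$timing[i])
    else if (!p$event[i] %in% EVENTS)
      reason <- sprintf("unknown event token '%s'", p$event[i])
    else if (is.na(p$months_primary_to_mets[i]) || p$months_primary_to_mets[i] < 0)
      reason <- "non-numeric or negative months_primary_to_mets"
    else if (is.na(p$followup_from_primary_months[i]) ||
             p$followup_from_primary_months[i] < 0)
      reason <- "non-numeric or negative followup_from_primary_months"
    else if (p$timing[i] == "synchronous" && p$months_primary_to_mets[i] != 0)
      reason <- "synchronous patient with nonzero months_primary_to_mets"
    else if (p$followup_from_primary_months[i] - p$months_primary_to_mets[i] <
             -MONTH_TOL)
      reason <- "followup_from_primary_months shorter than months_primary_to_mets"
    else if (anyDuplicated(p$patient_id[seq_len(i)]) == i)
      reason <- sprintf("duplicate patient_id '%s'", p$patient_id[i])
    if (!is.null(reason)) {
      keep[i] <- FALSE
      rej[[length(rej) + 1L]] <- .reject("patients", i, reason)
    }
  }
  p <- p[keep, , drop = FALSE]
  p$followup_from_mets_months <-
    pmax(p$followup_from_primary_months - p$months_primary_to_mets, 0)

  # --- metastases -----------------------------------------------------
  m <- metastases
  m$patient_id <- as.character(m$patient_id)
  m$organ <- tok(m$organ)
  m$diameter_mm <- num(m$diameter_mm)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    reason <- NULL
    if (!m$organ[i] %in% ORGANS) reason <- sprintf("unknown organ token '%s'", m$organ[i])
    else if (is.na(m$diameter_mm[i]) || !is.finite(m$diameter_mm[i]))
      reason <- "non-numeric diameter"
    else if (m$diameter_mm[i] <= 0) reason <- "non-positive diameter"
    else if (!m$patient_id[i] %in% p$patient_id)
      reason <- sprintf("orphan metastasis: patient_id '%s' not in patients table",
                        m$patient_id[i])
    if (!is.null(reason)) {
      keep[i] <- FALSE
      rej[[length(rej) + 1L]] <- .reject("metastases", i, reason)
    }
  }
  m <- m[keep, , drop = FALSE]
  rownames(m) <- NULL; rownames(p) <- NULL

  structure(
    list(
      metastases = m[, c("patient_id", "organ", "diameter_mm")],
      patients = p[, c("patient_id", "sex", "primary_location", "timing",
                       "months_primary_to_mets", "followup_from_primary_months",
                       "followup_from_mets_months", "event")],
      rejected = if (length(rej)) do.call(rbind, rej)
                 else .reject(character(), integer(), character())
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d metastases (%d rejected rows)\n",
              nrow(x$patients), nrow(x$metastases), nrow(x$rejected)))
  invisible(x)
}

#' Group metastasis records into per-patient-organ sets
#'
#' @param metastases Validated metastases data.frame (`patient_id, organ,
#'   diameter_mm`), or a `cohort` object.
#' @return Data.frame sorted by patient_id then organ, one row per
#'   (patient_id, organ) pair, with a list-column `diameters` and `n`.
#'   The sum of `n` equals the input row count.
#' @export
group_by_patient_organ <- function(metastases) {
  if (inherits(metastases, "cohort")) metastases <- metastases$metastases
  if (nrow(metastases) == 0L) {
    return(data.frame(patient_id = character(), organ = character(),
                      n = integer(), diameters = I(list()),
                      stringsAsFactors = FALSE))
  }
  key <- paste(metastases$patient_id, metastases$organ, sep = "\r")
  groups <- split(metastases$diameter_mm, key)
  groups <- groups[order(names(groups))]
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(
    patient_id = vapply(parts, `[`, "", 1L),
    organ = vapply(parts, `[`, "", 2L),
    n = unname(lengths(groups)),
    stringsAsFactors = FALSE
  )
  out$diameters <- unname(groups)
  rownames(out) <- NULL
  out
}

#' Write a cohort back to delimited files
#'
#' Inverse of [read_cohort()]: writes the canonical metastases and patients
#' tables so that reading them back reproduces the cohort.
#'
#' @param cohort A `cohort` object.
#' @param metastases_file,patients_file Output paths.
#' @param sep Field delimiter.
#' @export
write_cohort <- function(cohort, metastases_file, patients_file, sep = ",") {
  utils::write.table(cohort$metastases, metastases_file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  p <- cohort$patients
  p <- p[, setdiff(names(p), "followup_from_mets_months")]
  utils::write.table(p, patients_file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' Write the row-rejection report as JSON lines
#'
#' One JSON object per rejected row: source table, line number (1-based,
#' excluding the header), and reason.
#'
#' @param cohort A `cohort` object.
#' @param path Output path.
#' @export
write_validation_report <- function(cohort, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  rej <- cohort$rejected
  for (i in seq_len(nrow(rej))) {
    writeLines(jsonlite::toJSON(as.list(rej[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
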