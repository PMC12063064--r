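#' Resolve a pipeline run configuration
#'
#' Fills defaults for the knobs shared by the pipeline entry points and the
#' command-line front-end. The resolved configuration is serialized next to
#' the outputs of every run so any run is reproducible from config + inputs.
#'
#' @param ... Overrides: `metastases_file`, `patients_file`, `sep`,
#'   `tolerances` (named, mm), `linkage`, `min_n`, `quantile_rule`,
#'   `wilcoxon_weights`, `var_equal`, `out_dir`, `seed`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    metastases_file = NULL, patients_file = NULL, sep = ",",
    tolerances = c(lung = 1.0, liver = 3.0),
    linkage = "single", min_n = 3L, quantile_rule = "linear",
    wilcoxon_weights = "gehan", var_equal = TRUE,
    out_dir = NULL, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

.write_out <- function(obj, cfg, name) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  path <- file.path(cfg$out_dir, name)
  if (is.data.frame(obj)) {
    utils::write.table(obj, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

.save_config <- function(cfg) {
  .write_out(unclass(cfg), cfg, "config.json")
}

#' Run the wave/LPR stage of the pipeline
#'
#' Reads and validates the cohort, computes per-patient wave partitions and
#' LPR summaries, and builds the cohort tables: composition, per-organ
#' parameter medians/IQRs, and the synchronous-vs-metachronous comparison.
#' If `out_dir` is set, writes `patient_summaries.csv`, the per-organ
#' `cohort_table_<organ>.csv` and `comparison_<organ>.csv`,
#' `composition.csv`, `rejected.jsonl` and `config.json`.
#'
#' @param config A `run_config` with `metastases_file` and `patients_file`
#'   set, or a `cohort` object already in memory (then pass config
#'   overrides via `...`).
#' @param ... Config overrides when `config` is a cohort.
#' @return List: `cohort`, `summaries`, `composition`, `tables` (per
#'   organ), `comparisons` (per organ).
#' @export
run_lpr <- function(config, ...) {
  if (inherits(config, "cohort")) {
    cohort <- config
    cfg <- run_config(...)
  } else {
    cfg <- config
    cohort <- read_cohort(cfg$metastases_file, cfg$patients_file, sep = cfg$sep)
  }
  if (nrow(cohort$metastases) == 0L) stop("no valid metastasis records", call. = FALSE)
  message(sprintf("lpr: %d patients, %d metastases accepted, %d rows rejected",
                  nrow(cohort$patients), nrow(cohort$metastases),
                  nrow(cohort$rejected)))
  summ <- summarize_cohort(cohort$metastases, linkage = cfg$linkage,
                           min_n = cfg$min_n, tolerances = cfg$tolerances)
  summ$timing <- cohort$patients$timing[match(summ$patient_id,
                                              cohort$patients$patient_id)]
  organs <- unique(summ$organ)
  tables <- lapply(organs, function(o)
    cohort_table(summ, o, quantile_rule = cfg$quantile_rule))
  names(tables) <- organs
  comparisons <- lapply(organs, function(o) {
    if (length(unique(summ$timing[summ$organ == o])) < 2L) return(NULL)
    compare_groups(summ, o, var_equal = cfg$var_equal,
                   quantile_rule = cfg$quantile_rule)
  })
  names(comparisons) <- organs
  comp <- composition_table(cohort$patients, cohort$metastases)

  .save_config(cfg)
  .write_out(summ, cfg, "patient_summaries.csv")
  .write_out(comp, cfg, "composition.csv")
  for (o in organs) {
    .write_out(tables[[o]], cfg, sprintf("cohort_table_%s.csv", o))
    if (!is.null(comparisons[[o]]))
      .write_out(comparisons[[o]], cfg, sprintf("comparison_%s.csv", o))
  }
  if (!is.null(cfg$out_dir)) {
    write_validation_report(cohort, file.path(cfg$out_dir, "rejected.jsonl"))
  }
  list(cohort = cohort, summaries = summ, composition = comp,
       tables = tables, comparisons = comparisons)
}

#' Run the survival stage of the pipeline
#'
#' Kaplan-Meier curves and Gehan-Wilcoxon comparisons for the standard
#' prognostic groupings — sex, primary location, organ pattern, and timing
#' from both origins — plus the overall curve. If `out_dir` is set, writes
#' per-grouping curve CSVs and a `survival_tests.json`.
#'
#' @inheritParams run_lpr
#' @return List: `overall` (`km_curve`), `by_sex`, `by_location`,
#'   `by_pattern`, `dual_origin`.
#' @export
run_survival <- function(config, ...) {
  if (inherits(config, "cohort")) {
    cohort <- config
    cfg <- run_config(...)
  } else {
    cfg <- config
    cohort <- read_cohort(cfg$metastases_file, cfg$patients_file, sep = cfg$sep)
  }
  pats <- cohort$patients
  if (nrow(pats) == 0L) stop("no valid patient records", call. = FALSE)
  message(sprintf("survival: %d patients, %d deaths", nrow(pats),
                  sum(pats$event == "died")))
  comp <- composition_table(pats, cohort$metastases)
  pat_lv <- comp$level[comp$category == "organ_pattern"]
  pattern <- local({
    organs_by_patient <- split(cohort$metastases$organ, cohort$metastases$patient_id)
    vapply(pats$patient_id, function(id) {
      o <- unique(organs_by_patient[[id]])
      if (is.null(o)) "none"
      else if (all(c("lung", "liver") %in% o)) "both"
      else if ("liver" %in% o) "liver_only" else "lung_only"
    }, "")
  })
  pats$organ_pattern <- pattern

  overall <- km_fit(survival_records(pats, "primary_dx"))
  by_sex <- km_by_group(pats, "sex", weights = cfg$wilcoxon_weights)
  by_location <- km_by_group(pats, "primary_location",
                             weights = cfg$wilcoxon_weights)
  by_pattern <- km_by_group(pats, "organ_pattern",
                            weights = cfg$wilcoxon_weights)
  duo <- if (length(unique(pats$timing)) == 2L)
    dual_origin_analysis(pats, weights = cfg$wilcoxon_weights) else NULL

  .save_config(cfg)
  if (!is.null(cfg$out_dir)) {
    curve_df <- function(c) data.frame(time = c$time, n_at_risk = c$n_risk,
                                       n_events = c$n_event, survival = c$surv,
                                       ci_low = c$ci_low, ci_high = c$ci_high)
    .write_out(curve_df(overall), cfg, "km_overall.csv")
    tests <- list()
    for (nm in c("by_sex", "by_location", "by_pattern")) {
      g <- get(nm)
      if (!is.null(g$comparison)) {
        tests[[nm]] <- list(test = g$comparison$test,
                            statistic = g$comparison$statistic,
                            df = g$comparison$df, p = g$comparison$p_value)
      }
    }
    if (!is.null(duo)) {
      for (o in c("primary_dx", "metastasis_dx")) {
        tests[[paste0("timing_", o)]] <- list(
          test = duo[[o]]$comparison$test,
          statistic = duo[[o]]$comparison$statistic,
          df = duo[[o]]$comparison$df, p = duo[[o]]$comparison$p_value)
      }
    }
    .write_out(tests, cfg, "survival_tests.json")
  }
  list(overall = overall, by_sex = by_sex, by_location = by_location,
       by_pattern = by_pattern, dual_origin = duo)
}

#' Run the simulation stage of the pipeline
#'
#' Generates a synthetic cohort from a scenario, optionally writes it in
#' the canonical schemas (so it is a valid input for [run_lpr()] and
#' [run_survival()] with no transformation), and produces a recovery
#' report via [recovery_experiment()].
#'
#' @param scenario A `sim_scenario`; defaults to `sim_scenario(seed = seed)`.
#' @param config A `run_config` (for `out_dir` and `seed`).
#' @return List: `cohort`, `report`.
#' @export
run_simulate <- function(scenario = NULL, config = run_config()) {
  cfg <- config
  if (is.null(scenario)) scenario <- sim_scenario(seed = cfg$seed)
  validate_scenario(scenario)
  cohort <- simulate_cohort(scenario, dir = cfg$out_dir)
  message(sprintf("simulate: %d patients, %d metastases",
                  nrow(cohort$patients), nrow(cohort$metastases)))
  report <- recovery_experiment(list(scenario = scenario),
                                linkage = cfg$linkage)
  .save_config(cfg)
  .write_out(report, cfg, "recovery_report.csv")
  list(cohort = cohort, report = report)
}
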