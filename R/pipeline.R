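#' Validate a judgment-record table
#'
#' Schema- and range-checks a records file (or in-memory table): required
#' columns, confidence within 0--100, recognised group / difficulty /
#' judgment levels, non-missing flags, and uniqueness of
#' (judge_id, scenario_id) pairs. Issues are reported with row numbers; in
#' strict mode any issue aborts.
#'
#' @param x File path or data frame of judgment records.
#' @param strict If `TRUE`, abort on the first validation pass with issues.
#' @return A list with `records` (the tibble) and `issues` (tibble with
#'   columns `row`, `field`, `issue`).
#' @export
validate_records <- function(x, strict = FALSE) {
  records <- if (is.character(x)) read_records(x) else check_record_columns(x)
  issues <- list()
  flag <- function(rows, field, issue) {
    if (length(rows) > 0) {
      issues[[length(issues) + 1L]] <<- tibble::tibble(row = rows, field = field,
                                                       issue = issue)
    }
  }
  flag(which(is.na(records$confidence) | records$confidence < 0 | records$confidence > 100),
       "confidence", "confidence outside [0, 100]")
  flag(which(!records$group %in% c("student", "experienced")),
       "group", "unknown group level")
  flag(which(!records$difficulty %in% c("easy", "difficult")),
       "difficulty", "unknown difficulty level")
  flag(which(!records$judgment %in% c("at_risk", "not_at_risk")),
       "judgment", "unknown judgment level")
  flag(which(is.na(records$correct)), "correct", "missing correctness flag")
  flag(which(is.na(records$time_pressure)), "time_pressure", "missing time-pressure flag")
  key <- paste(records$judge_id, records$scenario_id, sep = "\r")
  flag(which(duplicated(key)), "judge_id/scenario_id", "duplicate (judge_id, scenario_id) pair")
  issues <- if (length(issues) > 0) dplyr::bind_rows(issues) else {
    tibble::tibble(row = integer(), field = character(), issue = character())
  }
  if (strict && nrow(issues) > 0) {
    rlang::abort(sprintf("record validation failed with %d issue(s); first: row %d, %s (%s)",
                         nrow(issues), issues$row[1], issues$field[1], issues$issue[1]),
                 class = "confcal_validation_error")
  }
  list(records = records, issues = issues)
}

#' Configure an end-to-end analysis run
#'
#' A run either reads an existing judgment-record CSV (`input`) or generates a
#' synthetic cohort (`cohort`); exactly one of the two must be supplied.
#'
#' @param input Path to a judgment-record CSV, or `NULL`.
#' @param cohort A [cohort_config()], or `NULL`.
#' @param edges Confidence bin edges (default [calibration_edges()]).
#' @param min_confidence Curve exclusion threshold (default 0.5).
#' @param curve_strata List of character vectors; each defines one family of
#'   pooled calibration curves.
#' @param out_dir Output directory for the report bundle; created if absent.
#' @param scale Confidence scale of the input (`"auto"`, `"percent"`,
#'   `"probability"`).
#' @param alpha Significance cut-off for the comparisons stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, cohort = NULL, edges = calibration_edges(),
                       min_confidence = 0.5,
                       curve_strata = list("group", c("difficulty", "time_pressure")),
                       out_dir = NULL, scale = "auto", alpha = 0.05) {
  if (is.null(input) == is.null(cohort)) {
    rlang::abort("supply exactly one input source: `input` file or `cohort` config")
  }
  if (!is.null(cohort) && !inherits(cohort, "cohort_config")) {
    cohort <- validate_cohort_config(cohort)
  }
  check_edges(edges)
  structure(list(input = input, cohort = cohort, edges = edges,
                 min_confidence = min_confidence, curve_strata = curve_strata,
                 out_dir = out_dir, scale = scale, alpha = alpha),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds [run_config()] fields by name; a `cohort` block holds
#' [cohort_config()] fields by name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cohort <- if (!is.null(raw$cohort)) do.call(cohort_config, raw$cohort)
  args <- raw[setdiff(names(raw), "cohort")]
  args$cohort <- cohort
  if (!is.null(args$edges)) args$edges <- as.numeric(args$edges)
  if (!is.null(args$curve_strata)) args$curve_strata <- lapply(args$curve_strata, as.character)
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                 parent = e, class = "confcal_stage_error")
  })
}

#' Run the full calibration analysis pipeline
#'
#' Orchestrates an end-to-end run: load or generate judgment records,
#' validate them, compute per-judge calibration summaries, pooled stratum
#' summaries (difficulty x time pressure), calibration curves per configured
#' stratification, and the group-comparison and factorial-ANOVA stages. When
#' `out_dir` is set, writes a report bundle of CSV tables plus a YAML
#' manifest (configuration echo, package version, exclusion fractions);
#' identical configurations produce byte-identical CSV payloads.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with elements `records`, `judge_summaries`,
#'   `stratum_summaries`, `curves`, `curve_exclusions`, `comparisons`,
#'   `anova`, `issues`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    rlang::abort("`config` must be a run_config object")
  }
  records <- stage("input", {
    if (!is.null(config$cohort)) generate_cohort(config$cohort) else read_records(config$input)
  })
  validated <- stage("validate", validate_records(records, strict = is.null(config$cohort)))
  records <- validated$records

  judge_summaries <- stage("calibrate", {
    calibrate_judges(records, edges = config$edges, scale = config$scale)
  })
  stratum_summaries <- stage("stratify", {
    records2 <- records
    records2$confidence <- as_probability(records2$confidence, config$scale)
    records2 |>
      dplyr::group_by(.data$difficulty, .data$time_pressure) |>
      dplyr::group_modify(function(d, key) {
        calibration_summary(d, config$edges, scale = "probability")
      }) |>
      dplyr::ungroup()
  })
  curves <- stage("curves", {
    lapply(config$curve_strata, function(by) {
      calibration_curves(records, by = by, edges = config$edges,
                         min_confidence = config$min_confidence, scale = config$scale)
    })
  })
  curve_tab <- dplyr::bind_rows(lapply(curves, function(cv) {
    strat_cols <- setdiff(names(cv), c("j", "lower", "upper", "x", "y", "n"))
    cv$stratum <- do.call(paste, c(lapply(strat_cols, function(s) {
      paste0(s, "=", cv[[s]])
    }), sep = ";"))
    cv[c("stratum", "lower", "upper", "x", "y", "n")]
  }))
  exclusions <- dplyr::bind_rows(lapply(curves, function(cv) {
    ex <- attr(cv, "exclusions")
    strat_cols <- setdiff(names(ex), c("n_total", "n_excluded", "excluded_fraction"))
    ex$stratum <- do.call(paste, c(lapply(strat_cols, function(s) {
      paste0(s, "=", ex[[s]])
    }), sep = ";"))
    ex[c("stratum", "n_total", "n_excluded", "excluded_fraction")]
  }))

  comparisons <- stage("compare", {
    if (length(unique(records$group)) == 2L) {
      compare_groups(judge_summaries, alpha = config$alpha)
    } else {
      tibble::tibble(analysis = character(), term = character(),
                     statistic = numeric(), df1 = numeric(), df2 = numeric(),
                     p_value = numeric(), significant = logical())
    }
  })
  anova_tab <- stage("anova", {
    cm <- cell_means(records, scale = config$scale)
    dplyr::bind_rows(
      dplyr::mutate(factorial_anova(cm, "prop_correct", config$alpha),
                    analysis = "anova_prop_correct", .before = 1),
      dplyr::mutate(factorial_anova(cm, "mean_confidence", config$alpha),
                    analysis = "anova_mean_confidence", .before = 1)
    )
  })

  manifest <- list(
    package = "confcal",
    version = as.character(utils::packageVersion("confcal")),
    input = if (is.null(config$input)) "synthetic" else config$input,
    cohort = if (!is.null(config$cohort)) unclass(config$cohort),
    edges = config$edges,
    min_confidence = config$min_confidence,
    alpha = config$alpha,
    n_records = nrow(records),
    n_judges = length(unique(records$judge_id)),
    n_validation_issues = nrow(validated$issues),
    curve_exclusions = as.list(stats::setNames(exclusions$excluded_fraction,
                                               exclusions$stratum))
  )

  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(records, file.path(config$out_dir, "records.csv"))
      readr::write_csv(judge_summaries, file.path(config$out_dir, "judge_summaries.csv"))
      readr::write_csv(stratum_summaries, file.path(config$out_dir, "stratum_summaries.csv"))
      readr::write_csv(curve_tab, file.path(config$out_dir, "curves.csv"))
      readr::write_csv(exclusions, file.path(config$out_dir, "curve_exclusions.csv"))
      readr::write_csv(comparisons, file.path(config$out_dir, "comparisons.csv"))
      readr::write_csv(anova_tab, file.path(config$out_dir, "anova.csv"))
      yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    })
  }

  invisible(list(records = records, judge_summaries = judge_summaries,
                 stratum_summaries = stratum_summaries, curves = curve_tab,
                 curve_exclusions = exclusions, comparisons = comparisons,
                 anova = anova_tab, issues = validated$issues, manifest = manifest))
}
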