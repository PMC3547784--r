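#' Modified Early Warning Score (MEWS) scoring table
#'
#' The default scoring table embeds the MEWS cut-offs published by Subbe and
#' colleagues (2001): five cues — systolic blood pressure (mmHg), heart rate
#' (beats/min), respiratory rate (breaths/min), temperature (degrees C) and
#' level of consciousness — each mapped to a 0--3 subscore. Consciousness is
#' coded on the AVPU ordinal scale (`alert` = 0, `voice` = 1, `pain` = 2,
#' `unresponsive` = 3) and scored through the same interval mechanism as the
#' numeric cues. Intervals are half-open, lower-inclusive (`[lower, upper)`),
#' with each cue's topmost interval closed at its upper bound; per cue they
#' are contiguous and non-overlapping, and their union defines the
#' physiologically admissible range — values outside it are rejected rather
#' than silently clamped.
#'
#' `read_mews_table()` loads and validates a user-supplied table in the same
#' CSV layout (`cue, lower, upper, score`), allowing other MEWS dialects.
#'
#' @param path Path to a scoring-table CSV.
#' @return A validated tibble with columns `cue`, `lower`, `upper`, `score`.
#' @references Subbe CP, Kruger M, Rutherford P, Gemmel L. Validation of a
#'   modified Early Warning Score in medical admissions. QJM 2001;94:521-6.
#' @export
mews_table <- function() {
  read_mews_table(system.file("extdata", "mews_subbe2001.csv",
                              package = "confcal", mustWork = TRUE))
}

#' @rdname mews_table
#' @export
read_mews_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    cue = readr::col_character(),
    lower = readr::col_double(),
    upper = readr::col_double(),
    score = readr::col_integer()
  ))
  validate_mews_table(tab)
}

mews_cues <- c("systolic_bp", "heart_rate", "respiratory_rate",
               "temperature", "consciousness")

avpu_levels <- c("alert", "voice", "pain", "unresponsive")

validate_mews_table <- function(tab) {
  if (!all(c("cue", "lower", "upper", "score") %in% names(tab))) {
    rlang::abort("scoring table must have columns cue, lower, upper, score")
  }
  if (!setequal(unique(tab$cue), mews_cues)) {
    rlang::abort(sprintf("scoring table must cover exactly the cues: %s",
                         paste(mews_cues, collapse = ", ")))
  }
  if (any(tab$score < 0L | tab$score > 3L)) {
    rlang::abort("scoring-table subscores must lie in 0..3")
  }
  for (cue in mews_cues) {
    rows <- tab[tab$cue == cue, ]
    rows <- rows[order(rows$lower), ]
    if (any(rows$upper <= rows$lower)) {
      rlang::abort(sprintf("scoring table: empty interval for cue '%s'", cue))
    }
    if (nrow(rows) > 1L && any(rows$lower[-1] != rows$upper[-nrow(rows)])) {
      rlang::abort(sprintf("scoring table: intervals for cue '%s' are not contiguous", cue))
    }
  }
  tibble::as_tibble(tab)
}

score_one_cue <- function(values, cue, tab) {
  rows <- tab[tab$cue == cue, ]
  rows <- rows[order(rows$lower), ]
  edges <- c(rows$lower, rows$upper[nrow(rows)])
  bad <- is.na(values) | values < edges[1] | values > edges[length(edges)]
  if (any(bad)) {
    v <- values[bad][1]
    rlang::abort(sprintf("scoring error: cue '%s' value %s outside the table's coverage [%g, %g]",
                         cue, format(v), edges[1], edges[length(edges)]),
                 class = "confcal_scoring_error")
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  rows$score[idx]
}

#' Score vital signs with a MEWS table
#'
#' Converts each of the five vital-sign cues into its 0--3 subscore by table
#' lookup, and sums them into the total MEWS (0--15). Consciousness may be
#' given as the AVPU labels `alert`/`voice`/`pain`/`unresponsive` or as their
#' ordinal codes 0--3.
#'
#' @param vitals Data frame with columns `systolic_bp`, `heart_rate`,
#'   `respiratory_rate`, `temperature`, `consciousness`.
#' @param table Scoring table (default [mews_table()]).
#' @return A tibble with one row per input row: the five `*_score` subscore
#'   columns and their sum `total`.
#' @examples
#' mews_subscores(data.frame(systolic_bp = 120, heart_rate = 75,
#'                           respiratory_rate = 14, temperature = 37,
#'                           consciousness = "alert"))
#' @export
mews_subscores <- function(vitals, table = mews_table()) {
  needed <- mews_cues
  missing <- setdiff(needed, names(vitals))
  if (length(missing) > 0) {
    rlang::abort(sprintf("vital-signs table is missing columns: %s",
                         paste(missing, collapse = ", ")))
  }
  table <- validate_mews_table(table)
  cons <- vitals$consciousness
  if (is.character(cons) || is.factor(cons)) {
    code <- match(tolower(as.character(cons)), avpu_levels) - 1L
    if (anyNA(code)) {
      rlang::abort(sprintf("scoring error: cue 'consciousness' value '%s' is not an AVPU level",
                           as.character(cons[is.na(code)][1])),
                   class = "confcal_scoring_error")
    }
  } else {
    code <- as.numeric(cons)
  }
  out <- tibble::tibble(
    systolic_bp_score = score_one_cue(as.numeric(vitals$systolic_bp), "systolic_bp", table),
    heart_rate_score = score_one_cue(as.numeric(vitals$heart_rate), "heart_rate", table),
    respiratory_rate_score = score_one_cue(as.numeric(vitals$respiratory_rate),
                                           "respiratory_rate", table),
    temperature_score = score_one_cue(as.numeric(vitals$temperature), "temperature", table),
    consciousness_score = score_one_cue(code, "consciousness", table)
  )
  out$total <- as.integer(rowSums(out))
  out
}

#' Classify at-risk status from a total MEWS
#'
#' A patient is classified at risk of a critical event when the total MEWS
#' exceeds the trigger threshold; the default threshold of 5 applies the
#' strict rule "total greater than five".
#'
#' @param total Integer total MEWS in \[0, 15\].
#' @param threshold Trigger threshold (default 5); at risk iff
#'   `total > threshold`.
#' @return Logical vector.
#' @export
classify_risk <- function(total, threshold = 5L) {
  if (any(is.na(total) | total < 0 | total > 15 | total != floor(total))) {
    rlang::abort("`total` must be integers in [0, 15]")
  }
  total > threshold
}

#' Classify judgment-task difficulty by score/outcome concordance
#'
#' A scenario is an easy judgment task when the risk classification implied by
#' its MEWS total agrees with what actually happened to the patient
#' (critical event or not), and a difficult one when score and outcome
#' disagree — the cues then point away from the truth.
#'
#' @param at_risk_predicted Logical: MEWS-implied at-risk classification.
#' @param outcome_critical Logical: whether a critical event (death, ICU/HDU
#'   admission, or cardiopulmonary resuscitation) occurred.
#' @return Character vector, `"easy"` or `"difficult"`.
#' @export
classify_difficulty <- function(at_risk_predicted, outcome_critical) {
  if (anyNA(at_risk_predicted) || anyNA(outcome_critical)) {
    rlang::abort("missing at_risk_predicted or outcome_critical flag")
  }
  ifelse(at_risk_predicted == outcome_critical, "easy", "difficult")
}

#' Score and label a scenario table
#'
#' End-to-end scenario labelling: MEWS subscores and total from the vital
#' signs, at-risk classification from the total, and easy/difficult labelling
#' from score/outcome concordance.
#'
#' @param scenarios Data frame with a `scenario_id` column, the five
#'   vital-sign columns (see [mews_subscores()]) and a logical
#'   `outcome_critical` column.
#' @inheritParams mews_subscores
#' @inheritParams classify_risk
#' @return A tibble with `scenario_id`, the five subscores, `total`,
#'   `at_risk_predicted`, `outcome_critical` and `difficulty`.
#' @export
score_scenarios <- function(scenarios, table = mews_table(), threshold = 5L) {
  for (col in c("scenario_id", "outcome_critical")) {
    if (!col %in% names(scenarios)) {
      rlang::abort(sprintf("scenario table must have a `%s` column", col))
    }
  }
  sub <- mews_subscores(scenarios, table)
  tibble::tibble(
    scenario_id = scenarios$scenario_id,
    sub[setdiff(names(sub), "total")],
    total = sub$total,
    at_risk_predicted = classify_risk(sub$total, threshold),
    outcome_critical = as.logical(scenarios$outcome_critical),
    difficulty = classify_difficulty(classify_risk(sub$total, threshold),
                                     as.logical(scenarios$outcome_critical))
  )
}
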