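#' Configure a synthetic judge cohort
#'
#' Builds the generative configuration for a simulated study in which two
#' groups of judges (students and experienced clinicians) each assess the same
#' set of clinical scenarios, give a dichotomous at-risk/not-at-risk judgment,
#' and attach a 0--100 confidence rating. The defaults reproduce the design of
#' a two-group high-fidelity simulation study: 63 students and 34 experienced
#' nurses, 25 scenarios of which 8 are difficult and the first 12 are judged
#' under time pressure.
#'
#' Correctness is Bernoulli with a per-difficulty success probability.
#' Confidence is drawn from a truncated normal on the probability scale,
#' centred at the judge's true correctness probability for that scenario plus
#' a group-level bias and (under time pressure) a difficulty-specific shift,
#' with standard deviation `1 / self_knowledge`, then rescaled to 0--100 and
#' rounded to integers.
#'
#' @param n_students,n_experienced Number of judges per group.
#' @param n_scenarios Number of scenarios each judge assesses.
#' @param n_difficult Number of difficult scenarios (spread evenly over the
#'   scenario sequence so both time-pressure blocks contain both difficulties).
#' @param n_time_pressured Number of time-pressured scenarios; the first
#'   `n_time_pressured` scenario ids form the pressured block.
#' @param p_correct_easy,p_correct_difficult Probability that a judgment on an
#'   easy / difficult scenario is correct.
#' @param confidence_bias Signed offset, on the probability scale, added to the
#'   centre of the confidence distribution. A scalar applies to both groups; a
#'   length-2 vector (or named vector with elements `student` and
#'   `experienced`) sets per-group biases.
#' @param self_knowledge Positive precision of confidence around its target:
#'   the truncated-normal standard deviation is `1 / self_knowledge` on the
#'   probability scale (the default 7 gives roughly 14 confidence points).
#' @param tp_conf_shift_easy,tp_conf_shift_difficult Signed confidence shifts
#'   applied only to time-pressured scenarios, by difficulty.
#' @param at_risk_rate Base rate of truly at-risk scenarios; used only to
#'   synthesise the dichotomous judgment labels, which do not enter the
#'   calibration statistics.
#' @param difficulty_blind If `TRUE`, confidence is centred on the judge's
#'   overall expected accuracy rather than the per-difficulty accuracy; this
#'   makes the cohort exhibit the hard-easy effect (overconfidence on
#'   difficult items, underconfidence on easy ones) with zero global bias.
#' @param seed Integer seed; the generator derives one sub-stream per judge so
#'   that enlarging the cohort never perturbs earlier judges' draws.
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_students = 63L,
                          n_experienced = 34L,
                          n_scenarios = 25L,
                          n_difficult = 8L,
                          n_time_pressured = 12L,
                          p_correct_easy = 0.85,
                          p_correct_difficult = 0.5,
                          confidence_bias = c(student = -0.0105, experienced = 0.0656),
                          self_knowledge = 7,
                          tp_conf_shift_easy = 0.03,
                          tp_conf_shift_difficult = -0.04,
                          at_risk_rate = 0.4,
                          difficulty_blind = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_students = n_students, n_experienced = n_experienced,
    n_scenarios = n_scenarios, n_difficult = n_difficult,
    n_time_pressured = n_time_pressured,
    p_correct_easy = p_correct_easy, p_correct_difficult = p_correct_difficult,
    confidence_bias = confidence_bias, self_knowledge = self_knowledge,
    tp_conf_shift_easy = tp_conf_shift_easy,
    tp_conf_shift_difficult = tp_conf_shift_difficult,
    at_risk_rate = at_risk_rate, difficulty_blind = difficulty_blind,
    seed = seed
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  count_fields <- c("n_students", "n_experienced", "n_scenarios",
                    "n_difficult", "n_time_pressured")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != floor(v)) {
      rlang::abort(sprintf("configuration error: `%s` must be a single non-negative integer", f),
                   class = "confcal_config_error")
    }
    cfg[[f]] <- as.integer(v)
  }
  prob_fields <- c("p_correct_easy", "p_correct_difficult", "at_risk_rate")
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      rlang::abort(sprintf("configuration error: `%s` must be a probability in [0, 1]", f),
                   class = "confcal_config_error")
    }
  }
  if (cfg$n_difficult > cfg$n_scenarios) {
    rlang::abort("configuration error: `n_difficult` exceeds `n_scenarios`",
                 class = "confcal_config_error")
  }
  if (cfg$n_time_pressured > cfg$n_scenarios) {
    rlang::abort("configuration error: `n_time_pressured` exceeds `n_scenarios`",
                 class = "confcal_config_error")
  }
  b <- cfg$confidence_bias
  if (!is.numeric(b) || !length(b) %in% c(1L, 2L) || anyNA(b) || any(abs(b) > 1)) {
    rlang::abort("configuration error: `confidence_bias` must be 1 or 2 values in [-1, 1]",
                 class = "confcal_config_error")
  }
  if (length(b) == 1L) b <- c(student = unname(b), experienced = unname(b))
  if (is.null(names(b)) || !all(nzchar(names(b)))) names(b) <- c("student", "experienced")
  if (!setequal(names(b), c("student", "experienced"))) {
    rlang::abort("configuration error: `confidence_bias` names must be 'student' and 'experienced'",
                 class = "confcal_config_error")
  }
  cfg$confidence_bias <- b[c("student", "experienced")]
  if (!is.numeric(cfg$self_knowledge) || length(cfg$self_knowledge) != 1L ||
      is.na(cfg$self_knowledge) || cfg$self_knowledge <= 0 || !is.finite(cfg$self_knowledge)) {
    rlang::abort("configuration error: `self_knowledge` must be a single positive finite number",
                 class = "confcal_config_error")
  }
  for (f in c("tp_conf_shift_easy", "tp_conf_shift_difficult")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || abs(v) > 1) {
      rlang::abort(sprintf("configuration error: `%s` must be a single value in [-1, 1]", f),
                   class = "confcal_config_error")
    }
  }
  if (!is.logical(cfg$difficulty_blind) || length(cfg$difficulty_blind) != 1L ||
      is.na(cfg$difficulty_blind)) {
    rlang::abort("configuration error: `difficulty_blind` must be TRUE or FALSE",
                 class = "confcal_config_error")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed) ||
      cfg$seed != floor(cfg$seed)) {
    rlang::abort("configuration error: `seed` must be a single integer",
                 class = "confcal_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cohort_config")
}

# Deterministic per-judge sub-seed so that adding judges to a cohort never
# changes the draws of earlier judges.
judge_seed <- function(seed, judge_index) {
  as.integer((as.numeric(seed) %% 2147483647 + 1000003 * judge_index) %% 2147483647)
}

# Truncated normal on [0, 1] via inverse-CDF sampling.
rtrunc01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Scenario ids labelled difficult: evenly spaced over 1..n_scenarios so both
# the pressured and unpressured blocks contain easy and difficult items.
difficult_scenario_ids <- function(n_scenarios, n_difficult) {
  if (n_difficult == 0L) return(integer(0))
  ceiling((seq_len(n_difficult) - 0.5) * n_scenarios / n_difficult)
}

empty_records <- function() {
  tibble::tibble(
    judge_id = character(), group = character(), scenario_id = character(),
    difficulty = character(), time_pressure = logical(), judgment = character(),
    correct = logical(), confidence = integer()
  )
}

#' Generate a synthetic judgment-record table
#'
#' Draws one judgment record per judge x scenario under the generative model
#' described in [cohort_config()]. The output is the package's canonical
#' long-format table: one row per judge x scenario with group, difficulty,
#' time-pressure flag, the dichotomous judgment, its correctness, and the
#' 0--100 integer confidence rating.
#'
#' The generator is fully reproducible: identical configurations (including
#' the seed) yield identical tables, and each judge consumes an independent
#' random sub-stream, so growing the cohort leaves existing judges' records
#' unchanged.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with columns `judge_id`, `group`, `scenario_id`,
#'   `difficulty`, `time_pressure`, `judgment`, `correct`, `confidence`.
#' @examples
#' records <- generate_cohort(cohort_config(n_students = 5, n_experienced = 3))
#' nrow(records)  # 8 judges x 25 scenarios
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- validate_cohort_config(config)
  n_judges <- config$n_students + config$n_experienced
  if (n_judges == 0L || config$n_scenarios == 0L) return(empty_records())

  n_sc <- config$n_scenarios
  difficult <- seq_len(n_sc) %in% difficult_scenario_ids(n_sc, config$n_difficult)
  pressured <- seq_len(n_sc) <= config$n_time_pressured
  p_vec <- ifelse(difficult, config$p_correct_difficult, config$p_correct_easy)
  overall_acc <- mean(p_vec)
  shift <- ifelse(pressured,
                  ifelse(difficult, config$tp_conf_shift_difficult, config$tp_conf_shift_easy),
                  0)
  sd_conf <- 1 / config$self_knowledge

  # Scenario-level truth labels come from a stream of their own so they are
  # shared by all judges and unaffected by cohort size.
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(judge_seed(config$seed, 0))
  truth_at_risk <- stats::rbinom(n_sc, 1L, config$at_risk_rate) == 1L

  groups <- c(rep("student", config$n_students), rep("experienced", config$n_experienced))
  ids <- c(sprintf("stu%03d", seq_len(config$n_students)),
           sprintf("exp%03d", seq_len(config$n_experienced)))

  per_judge <- vector("list", n_judges)
  for (i in seq_len(n_judges)) {
    set.seed(judge_seed(config$seed, i))
    correct <- stats::rbinom(n_sc, 1L, p_vec) == 1L
    centre <- if (config$difficulty_blind) rep(overall_acc, n_sc) else p_vec
    mu <- centre + unname(config$confidence_bias[[groups[i]]]) + shift
    conf <- as.integer(round(100 * rtrunc01(n_sc, mu, sd_conf)))
    conf <- pmin(100L, pmax(0L, conf))
    judgment <- ifelse(correct, truth_at_risk, !truth_at_risk)
    per_judge[[i]] <- tibble::tibble(
      judge_id = ids[i],
      group = groups[i],
      scenario_id = sprintf("sc%02d", seq_len(n_sc)),
      difficulty = ifelse(difficult, "difficult", "easy"),
      time_pressure = pressured,
      judgment = ifelse(judgment, "at_risk", "not_at_risk"),
      correct = correct,
      confidence = conf
    )
  }
  dplyr::bind_rows(per_judge)
}

#' Write and read judgment-record tables
#'
#' Judgment records are stored as UTF-8 CSV with the fixed column set
#' `judge_id, group, scenario_id, difficulty, time_pressure, judgment,
#' correct, confidence`. `write_records()` / `read_records()` round-trip a
#' table losslessly.
#'
#' @param records A judgment-record tibble (see [generate_cohort()]).
#' @param path Destination (or source) file path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns the records tibble.
#' @export
write_records <- function(records, path) {
  records <- check_record_columns(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("cannot read records: no such file '%s'", path))
  }
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      judge_id = readr::col_character(),
      group = readr::col_character(),
      scenario_id = readr::col_character(),
      difficulty = readr::col_character(),
      time_pressure = readr::col_logical(),
      judgment = readr::col_character(),
      correct = readr::col_logical(),
      confidence = readr::col_integer()
    )
  )
  check_record_columns(records)
}

record_columns <- c("judge_id", "group", "scenario_id", "difficulty",
                    "time_pressure", "judgment", "correct", "confidence")

check_record_columns <- function(records) {
  missing <- setdiff(record_columns, names(records))
  if (length(missing) > 0) {
    rlang::abort(sprintf("records table is missing columns: %s",
                         paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(records[record_columns])
}
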