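#' Pooled-variance two-sample t test
#'
#' Student's t test with pooled variance and `df = n_a + n_b - 2`, two-sided,
#' as used to compare per-judge calibration statistics between two groups.
#'
#' @param values_a,values_b Numeric vectors, each with at least two values.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    rlang::abort("each group needs at least two values")
  }
  pooled_ss <- sum((values_a - mean(values_a))^2) + sum((values_b - mean(values_b))^2)
  if (pooled_ss == 0 && mean(values_a) == mean(values_b)) {
    # identical constant groups: no evidence against equal means
    return(tibble::tibble(statistic = 0,
                          df = length(values_a) + length(values_b) - 2L,
                          p_value = 1))
  }
  if (pooled_ss == 0) {
    rlang::abort("degenerate (zero) pooled variance with unequal means")
  }
  fit <- stats::t.test(values_a, values_b, var.equal = TRUE)
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value)
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided Wilcoxon rank-sum test via the normal approximation with tie
#' correction, reporting the z statistic. Used for calibration indices whose
#' per-judge distributions are unsuitable for the t test.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return One-row tibble: `statistic` (z), `p_value`.
#' @export
rank_sum <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    rlang::abort("each group must be non-empty")
  }
  pooled <- c(values_a, values_b)
  n_a <- length(values_a); n_b <- length(values_b); n <- n_a + n_b
  r <- rank(pooled)
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    if (w == mu) return(tibble::tibble(statistic = 0, p_value = 1))
    rlang::abort("all values tied across both groups; rank-sum test undefined")
  }
  z <- (w - mu) / sqrt(sigma2)
  tibble::tibble(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Judge-by-condition cell means
#'
#' Collapses raw judgment records to one row per judge x time-pressure x
#' difficulty cell, carrying the proportion correct and mean confidence
#' (probability scale) in that cell — the layout on which the factorial
#' ANOVA operates.
#'
#' @inheritParams bin_confidence
#' @return A tibble with columns `judge_id`, `group`, `time_pressure`,
#'   `difficulty`, `prop_correct`, `mean_confidence`, `n_items`.
#' @export
cell_means <- function(records, scale = "auto") {
  records <- check_records(records)
  for (col in c("judge_id", "time_pressure", "difficulty")) {
    if (!col %in% names(records)) {
      rlang::abort(sprintf("`records` must have a `%s` column", col))
    }
  }
  records$confidence <- as_probability(records$confidence, scale)
  by <- intersect(c("judge_id", "group", "time_pressure", "difficulty"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(prop_correct = mean(as.numeric(.data$correct)),
                     mean_confidence = mean(.data$confidence),
                     n_items = dplyr::n(),
                     .groups = "drop")
}

#' Factorial ANOVA on judge-by-condition cell means
#'
#' Fits a sequential sums-of-squares ANOVA of a cell-level response on time
#' pressure, task difficulty, participant, and the time-pressure x difficulty
#' interaction. Operating on judge-level cell means (each judge contributing
#' one value per 2 x 2 condition cell) gives the participant term
#' `n_judges - 1` degrees of freedom and, with a full layout, a residual of
#' about `4 n_judges - n_judges - 4` degrees of freedom.
#'
#' @param cells Cell-mean table from [cell_means()]; every judge must have a
#'   complete 2 x 2 layout.
#' @param response `"prop_correct"` or `"mean_confidence"`.
#' @param alpha Significance cut-off (default 0.05).
#' @return Tidy tibble, one row per model term: `term`, `df1`, `df2`,
#'   `statistic` (F), `p_value`, `significant`.
#' @export
factorial_anova <- function(cells, response = c("prop_correct", "mean_confidence"),
                            alpha = 0.05) {
  response <- match.arg(response)
  needed <- c("judge_id", "time_pressure", "difficulty", response)
  missing <- setdiff(needed, names(cells))
  if (length(missing) > 0) {
    rlang::abort(sprintf("cell table is missing columns: %s",
                         paste(missing, collapse = ", ")))
  }
  incomplete <- cells |>
    dplyr::count(.data$judge_id, name = "n_cells") |>
    dplyr::filter(.data$n_cells != 4L)
  if (nrow(incomplete) > 0) {
    rlang::abort(sprintf("incomplete 2 x 2 layout for judges: %s",
                         paste(incomplete$judge_id, collapse = ", ")))
  }
  dup <- cells |>
    dplyr::count(.data$judge_id, .data$time_pressure, .data$difficulty) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    rlang::abort("duplicated judge x condition cells")
  }
  d <- data.frame(
    y = cells[[response]],
    tp = factor(cells$time_pressure),
    diff = factor(cells$difficulty),
    judge = factor(cells$judge_id)
  )
  fit <- stats::aov(y ~ tp + diff + judge + tp:diff, data = d)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  resid_row <- terms == "Residuals"
  df2 <- tab[resid_row, "Df"]
  ms_resid <- tab[resid_row, "Mean Sq"]
  keep <- !resid_row
  term_names <- c(tp = "time_pressure", diff = "difficulty",
                  judge = "participant", `tp:diff` = "time_pressure:difficulty")
  f_vals <- tab[keep, "F value"]
  p_vals <- tab[keep, "Pr(>F)"]
  ss <- tab[keep, "Sum Sq"]
  # a constant response yields 0/0; report F = 0 (no effect), p = 1
  zero <- ss < 1e-12
  f_vals[zero] <- 0
  p_vals[zero] <- 1
  tibble::tibble(
    term = unname(term_names[terms[keep]]),
    df1 = tab[keep, "Df"],
    df2 = df2,
    statistic = f_vals,
    p_value = p_vals,
    significant = p_vals < alpha
  )
}

#' Compare per-judge calibration statistics between two groups
#'
#' Runs both the pooled-variance t test (difference of means) and the
#' Wilcoxon rank-sum test (difference of medians) on each per-judge
#' calibration statistic between the two judge groups, returning one tidy
#' results table.
#'
#' @param judge_summaries Per-judge summary table from [calibrate_judges()],
#'   with a `group` column holding exactly two levels.
#' @param statistics Columns to compare.
#' @param alpha Significance cut-off (default 0.05).
#' @return Tidy tibble: `analysis` (`"t"` or `"rank_sum"`), `term` (the
#'   statistic compared), `statistic`, `df1`, `df2`, `p_value`, `significant`.
#' @export
compare_groups <- function(judge_summaries,
                           statistics = c("e_bar", "p_bar", "calibration",
                                          "over_under", "resolution",
                                          "normalised_resolution"),
                           alpha = 0.05) {
  if (!"group" %in% names(judge_summaries)) {
    rlang::abort("`judge_summaries` must have a `group` column")
  }
  groups <- sort(unique(judge_summaries$group))
  if (length(groups) != 2L) {
    rlang::abort("group comparison requires exactly two groups")
  }
  a <- judge_summaries[judge_summaries$group == groups[1], ]
  b <- judge_summaries[judge_summaries$group == groups[2], ]
  rows <- lapply(statistics, function(s) {
    tt <- two_sample_t(a[[s]], b[[s]])
    ww <- rank_sum(a[[s]], b[[s]])
    dplyr::bind_rows(
      tibble::tibble(analysis = "t", term = s, statistic = tt$statistic,
                     df1 = tt$df, df2 = NA_real_, p_value = tt$p_value),
      tibble::tibble(analysis = "rank_sum", term = s, statistic = ww$statistic,
                     df1 = NA_real_, df2 = NA_real_, p_value = ww$p_value)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value < alpha
  out
}
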