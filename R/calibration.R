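#' Default confidence bin edges
#'
#' The statistics bin confidence on the probability scale into one pooled
#' sub-0.5 category followed by deciles: `[0, 0.5)`, `[0.5, 0.6)`, ...,
#' `[0.9, 1.0]` (top bin closed). A rating of 59 therefore falls in
#' `[0.5, 0.6)`. Pooling everything below 0.5 keeps the bin counts summing to
#' the total number of responses, so the `1/n` weighting of the calibration
#' score is exact; sub-0.5 ratings are excluded only from calibration curves
#' (see [curve_points()]), never from the statistics.
#'
#' @return Numeric vector of strictly increasing edges spanning \[0, 1\].
#' @export
calibration_edges <- function() c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1)

# Canonical internal scale is probability. Ratings are elicited on 0-100 and
# divided by 100; `scale = "auto"` treats a vector as percent when any value
# exceeds 1. Convert whole tables once, before any stratification, so every
# subset is interpreted identically.
as_probability <- function(confidence, scale = c("auto", "percent", "probability")) {
  scale <- match.arg(scale)
  if (!is.numeric(confidence)) {
    rlang::abort("`confidence` must be numeric")
  }
  if (scale == "auto") {
    scale <- if (any(confidence > 1, na.rm = TRUE)) "percent" else "probability"
  }
  p <- if (scale == "percent") confidence / 100 else as.numeric(confidence)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("confidence outside [0, 1] after scale conversion")
  }
  p
}

check_records <- function(records, require_rows = TRUE) {
  if (!is.data.frame(records)) {
    rlang::abort("`records` must be a data frame of judgment records")
  }
  for (col in c("confidence", "correct")) {
    if (!col %in% names(records)) {
      rlang::abort(sprintf("`records` must have a `%s` column", col))
    }
  }
  if (require_rows && nrow(records) == 0L) {
    rlang::abort("`records` is empty", class = "confcal_empty_error")
  }
  records
}

check_edges <- function(edges) {
  if (!is.numeric(edges) || length(edges) < 2L || anyNA(edges) ||
      any(diff(edges) <= 0)) {
    rlang::abort("`edges` must be strictly increasing numeric bounds")
  }
  if (edges[1] != 0 || edges[length(edges)] != 1) {
    rlang::abort("`edges` must span [0, 1] (first edge 0, last edge 1)")
  }
  edges
}

#' Bin confidence ratings into ordinal categories
#'
#' Assigns every judgment record to exactly one confidence category
#' (lower-inclusive, upper-exclusive, top bin closed at 1) and returns the
#' per-bin response count, mean confidence and proportion correct — the
#' `n_j`, `p-bar_j` and `e-bar_j` ingredients of the binned calibration and
#' resolution statistics. Empty bins are retained with `n_j = 0`.
#'
#' @param records Data frame with `confidence` and logical/0-1 `correct`
#'   columns; must be non-empty.
#' @param edges Strictly increasing probability bounds spanning \[0, 1\];
#'   default [calibration_edges()].
#' @param scale `"auto"` (default), `"percent"`, or `"probability"` —
#'   how to interpret the `confidence` column.
#' @return A tibble with one row per bin: `j`, `lower`, `upper`, `n_j`,
#'   `p_bar_j`, `e_bar_j` (`NA` for empty bins).
#' @export
bin_confidence <- function(records, edges = calibration_edges(), scale = "auto") {
  records <- check_records(records)
  edges <- check_edges(edges)
  p <- as_probability(records$confidence, scale)
  correct <- as.numeric(records$correct)
  j <- findInterval(p, edges, rightmost.closed = TRUE)
  n_bins <- length(edges) - 1L
  n_j <- tabulate(j, nbins = n_bins)
  sum_p <- vapply(seq_len(n_bins), function(b) sum(p[j == b]), numeric(1))
  sum_e <- vapply(seq_len(n_bins), function(b) sum(correct[j == b]), numeric(1))
  tibble::tibble(
    j = seq_len(n_bins),
    lower = edges[-length(edges)],
    upper = edges[-1],
    n_j = n_j,
    p_bar_j = ifelse(n_j > 0, sum_p / n_j, NA_real_),
    e_bar_j = ifelse(n_j > 0, sum_e / n_j, NA_real_)
  )
}

check_bins <- function(bins, n = NULL) {
  if (!is.data.frame(bins) || !all(c("n_j", "p_bar_j", "e_bar_j") %in% names(bins))) {
    rlang::abort("`bins` must be a bin table from bin_confidence()")
  }
  if (is.null(n)) n <- sum(bins$n_j)
  if (n <= 0) {
    rlang::abort("bin table holds no responses (n = 0)", class = "confcal_empty_error")
  }
  if (sum(bins$n_j) != n) {
    rlang::abort("`n` does not equal the total bin count")
  }
  n
}

#' Calibration score
#'
#' The weighted mean squared deviation between each confidence category's mean
#' confidence and its proportion correct:
#' \deqn{\frac{1}{n}\sum_{j=1}^{J} n_j (\bar p_j - \bar e_j)^2}
#' It ranges from 0 (perfect calibration: mean confidence equals proportion
#' correct in every category) to 1 (worst: full confidence on every incorrect
#' judgment and zero confidence on every correct one).
#'
#' @param bins Bin table from [bin_confidence()].
#' @param n Total response count; defaults to the bin total.
#' @return Calibration score in \[0, 1\].
#' @export
calibration_score <- function(bins, n = sum(bins$n_j)) {
  n <- check_bins(bins, n)
  occ <- bins$n_j > 0
  sum(bins$n_j[occ] * (bins$p_bar_j[occ] - bins$e_bar_j[occ])^2) / n
}

#' Over/underconfidence score
#'
#' Mean confidence minus overall proportion correct, on the probability scale.
#' Positive values denote overconfidence, negative values underconfidence.
#'
#' @inheritParams bin_confidence
#' @return Signed score in \[-1, 1\].
#' @export
over_underconfidence <- function(records, scale = "auto") {
  records <- check_records(records)
  mean(as_probability(records$confidence, scale)) - mean(as.numeric(records$correct))
}

#' Resolution score
#'
#' The weighted squared deviation of each confidence category's proportion
#' correct around the overall proportion correct:
#' \deqn{\frac{1}{n}\sum_{j=1}^{J} n_j (\bar e_j - \bar e)^2}
#' Resolution measures discrimination — how well confidence categories
#' separate correct from incorrect judgments — and is bounded by the
#' knowledge index \eqn{\bar e (1 - \bar e)}.
#'
#' @inheritParams calibration_score
#' @param e_bar Overall proportion correct; defaults to the bin-weighted mean.
#' @return Resolution score in \[0, e_bar (1 - e_bar)\].
#' @export
resolution <- function(bins, e_bar = NULL, n = sum(bins$n_j)) {
  n <- check_bins(bins, n)
  occ <- bins$n_j > 0
  if (is.null(e_bar)) e_bar <- sum(bins$n_j[occ] * bins$e_bar_j[occ]) / n
  sum(bins$n_j[occ] * (bins$e_bar_j[occ] - e_bar)^2) / n
}

#' Normalised resolution score
#'
#' Resolution divided by the knowledge index \eqn{\bar e(1-\bar e)}, its
#' maximum attainable value given overall accuracy, yielding a 0--1 score
#' comparable across judges with different accuracy. When all judgments share
#' one correctness value (\eqn{\bar e \in \{0, 1\}}) no discrimination is
#' measurable; the score is defined as 0 and flagged degenerate via the
#' `"degenerate"` attribute.
#'
#' @param resolution Resolution score (see [resolution()]).
#' @param e_bar Overall proportion correct.
#' @param tol Numerical tolerance for the `resolution <= e_bar(1-e_bar)` bound.
#' @return Normalised resolution in \[0, 1\], with a logical `"degenerate"`
#'   attribute.
#' @export
normalised_resolution <- function(resolution, e_bar, tol = 1e-9) {
  if (e_bar < 0 || e_bar > 1) rlang::abort("`e_bar` must be in [0, 1]")
  k <- e_bar * (1 - e_bar)
  if (k == 0) {
    return(structure(0, degenerate = TRUE))
  }
  if (resolution > k + tol) {
    rlang::abort("resolution exceeds the knowledge index e_bar * (1 - e_bar)")
  }
  structure(min(1, max(0, resolution / k)), degenerate = FALSE)
}

#' Summarise calibration for one set of judgment records
#'
#' Computes the full set of calibration statistics — overall accuracy and mean
#' confidence, calibration score, over/underconfidence, resolution and
#' normalised resolution — from one table of judgment records, using a single
#' shared bin set so the statistics are mutually consistent.
#'
#' @inheritParams bin_confidence
#' @return A one-row tibble with columns `n`, `e_bar`, `p_bar`, `calibration`,
#'   `over_under`, `resolution`, `normalised_resolution`, `degenerate`; the
#'   bin table is attached as attribute `"bins"`.
#' @examples
#' rec <- tibble::tibble(confidence = c(80, 80, 60, 60), correct = c(TRUE, TRUE, TRUE, FALSE))
#' calibration_summary(rec)
#' @export
calibration_summary <- function(records, edges = calibration_edges(), scale = "auto") {
  records <- check_records(records)
  p <- as_probability(records$confidence, scale)
  records$confidence <- p
  bins <- bin_confidence(records, edges, scale = "probability")
  n <- nrow(records)
  e_bar <- mean(as.numeric(records$correct))
  p_bar <- mean(p)
  res <- resolution(bins, e_bar, n)
  nrs <- normalised_resolution(res, e_bar)
  out <- tibble::tibble(
    n = n,
    e_bar = e_bar,
    p_bar = p_bar,
    calibration = calibration_score(bins, n),
    over_under = p_bar - e_bar,
    resolution = res,
    normalised_resolution = as.numeric(nrs),
    degenerate = attr(nrs, "degenerate")
  )
  attr(out, "bins") <- bins
  out
}

#' Per-judge calibration summaries
#'
#' Computes [calibration_summary()] independently for every judge (or any
#' other grouping), the per-participant layout on which group comparisons
#' operate.
#'
#' @inheritParams bin_confidence
#' @param by Character vector of grouping columns; defaults to
#'   `c("judge_id", "group")`.
#' @return A tibble with one row per group defined by `by`, carrying the
#'   [calibration_summary()] columns.
#' @export
calibrate_judges <- function(records, edges = calibration_edges(), scale = "auto",
                             by = c("judge_id", "group")) {
  records <- check_records(records)
  missing <- setdiff(by, names(records))
  if (length(missing) > 0) {
    rlang::abort(sprintf("grouping columns not in records: %s",
                         paste(missing, collapse = ", ")))
  }
  # Fix the scale once on the full table so all judges share one convention.
  records$confidence <- as_probability(records$confidence, scale)
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      calibration_summary(d, edges, scale = "probability")
    }) |>
    dplyr::ungroup()
}
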