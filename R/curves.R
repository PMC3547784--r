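#' Calibration-curve (reliability-diagram) points
#'
#' Builds the point set of a calibration curve: proportion correct (`y`)
#' against mean confidence (`x`) per confidence category, using the bin's mean
#' confidence — not its midpoint — as the x coordinate. Following common
#' practice for half-scale confidence instruments, ratings below
#' `min_confidence` (default 0.5) are excluded before binning, because the few
#' low-confidence responses would otherwise produce unstable curve points;
#' the excluded fraction is reported. Points on the 45-degree identity line
#' indicate perfect calibration; a curve below the line indicates
#' overconfidence and above it underconfidence.
#'
#' @inheritParams bin_confidence
#' @param min_confidence Exclusion threshold on the probability scale
#'   (default 0.5). Set to 0 to keep all records.
#' @return A tibble with one row per non-empty bin, ordered by `x`: `j`,
#'   `lower`, `upper`, `x`, `y`, `n`. Attributes `n_total`, `n_excluded` and
#'   `excluded_fraction` describe the exclusion step.
#' @export
curve_points <- function(records, edges = calibration_edges(),
                         min_confidence = 0.5, scale = "auto") {
  records <- check_records(records)
  if (!is.numeric(min_confidence) || length(min_confidence) != 1L ||
      min_confidence < 0 || min_confidence > 1) {
    rlang::abort("`min_confidence` must be a single probability in [0, 1]")
  }
  p <- as_probability(records$confidence, scale)
  n_total <- length(p)
  keep <- p >= min_confidence
  if (!any(keep)) {
    rlang::abort("all records fall below `min_confidence`; no curve can be drawn",
                 class = "confcal_empty_error")
  }
  kept <- records[keep, , drop = FALSE]
  kept$confidence <- p[keep]
  bins <- bin_confidence(kept, edges, scale = "probability")
  pts <- bins[bins$n_j > 0, ]
  out <- tibble::tibble(
    j = pts$j, lower = pts$lower, upper = pts$upper,
    x = pts$p_bar_j, y = pts$e_bar_j, n = pts$n_j
  )
  out <- out[order(out$x), ]
  attr(out, "n_total") <- n_total
  attr(out, "n_excluded") <- n_total - sum(keep)
  attr(out, "excluded_fraction") <- (n_total - sum(keep)) / n_total
  out
}

#' Curve deviation from the identity line
#'
#' The n-weighted mean of `x - y` over curve points: the average signed gap
#' between confidence and accuracy on the post-exclusion records. Positive
#' values mean the curve lies below the identity line (overconfidence),
#' negative above it (underconfidence). With `min_confidence = 0` this equals
#' [over_underconfidence()] on the same records exactly.
#'
#' @param points Curve-point tibble from [curve_points()].
#' @return Signed deviation in \[-1, 1\].
#' @export
deviation_summary <- function(points) {
  if (!is.data.frame(points) || !all(c("x", "y", "n") %in% names(points)) ||
      nrow(points) == 0L) {
    rlang::abort("`points` must be a non-empty curve-point table")
  }
  sum(points$n * (points$x - points$y)) / sum(points$n)
}

#' Calibration curves per stratum
#'
#' Computes [curve_points()] independently within each stratum (e.g. group,
#' difficulty, time-pressure condition or their crossings) on pooled records —
#' one curve per stratum, not per judge, since individual judges contribute
#' too few responses per bin for a stable curve.
#'
#' @inheritParams curve_points
#' @param by Character vector of stratifying columns.
#' @return A tibble stacking the per-stratum curve points, with the stratum
#'   columns first; per-stratum exclusion metadata is attached as the
#'   `"exclusions"` attribute (one row per stratum).
#' @export
calibration_curves <- function(records, by = "group", edges = calibration_edges(),
                               min_confidence = 0.5, scale = "auto") {
  records <- check_records(records)
  missing <- setdiff(by, names(records))
  if (length(missing) > 0) {
    rlang::abort(sprintf("stratifying columns not in records: %s",
                         paste(missing, collapse = ", ")))
  }
  records$confidence <- as_probability(records$confidence, scale)
  strata <- records |>
    dplyr::distinct(dplyr::across(dplyr::all_of(by))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  curves <- vector("list", nrow(strata))
  excl <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    sub <- dplyr::semi_join(records, strata[i, , drop = FALSE], by = by)
    pts <- curve_points(sub, edges, min_confidence, scale = "probability")
    curves[[i]] <- dplyr::bind_cols(strata[rep(i, nrow(pts)), , drop = FALSE], pts)
    excl[[i]] <- dplyr::bind_cols(
      strata[i, , drop = FALSE],
      tibble::tibble(n_total = attr(pts, "n_total"),
                     n_excluded = attr(pts, "n_excluded"),
                     excluded_fraction = attr(pts, "excluded_fraction"))
    )
  }
  out <- dplyr::bind_rows(curves)
  attr(out, "exclusions") <- dplyr::bind_rows(excl)
  out
}

#' Plot a reliability diagram
#'
#' Optional ggplot2 rendering of one or more calibration curves with the
#' 45-degree perfect-calibration reference line. The tested artifact is the
#' point table; this is a convenience view of it.
#'
#' @param points Output of [curve_points()] or [calibration_curves()].
#' @param colour Optional name of a stratum column used to colour curves.
#' @return A ggplot object.
#' @export
plot_calibration_curve <- function(points, colour = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("plotting requires the ggplot2 package")
  }
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data$x, y = .data$y)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data[[colour]])
  }
  ggplot2::ggplot(points, aes) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean confidence", y = "Proportion correct", size = "Responses") +
    ggplot2::theme_minimal()
}
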