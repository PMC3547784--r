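# Independent brute-force oracles and record fixtures shared across tests.
# The oracles deliberately use explicit per-record loops rather than any code
# path from the package.

make_records <- function(confidence, correct, ...) {
  tibble::tibble(confidence = confidence, correct = correct, ...)
}

# The adversarial responder: full confidence on every incorrect judgment,
# zero confidence on every correct one.
worst_responder <- function(n_correct = 5, n_wrong = 5) {
  make_records(confidence = c(rep(0, n_correct), rep(100, n_wrong)),
               correct = c(rep(TRUE, n_correct), rep(FALSE, n_wrong)))
}

random_records <- function(n, seed, p_correct = 0.7) {
  set.seed(seed)
  make_records(confidence = sample(0:100, n, replace = TRUE),
               correct = stats::runif(n) < p_correct)
}

# Per-record linear-scan bin assignment: lower-inclusive, upper-exclusive,
# top bin closed.
brute_bin_index <- function(p, edges) {
  J <- length(edges) - 1L
  for (j in seq_len(J)) {
    if (p >= edges[j] && (p < edges[j + 1] || (j == J && p <= edges[j + 1]))) {
      return(j)
    }
  }
  stop("value not covered by edges")
}

# Calibration, resolution, NRS and over/underconfidence recomputed from
# scratch by scanning records one at a time.
brute_calibration_stats <- function(confidence, correct,
                                    edges = c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1)) {
  p <- if (any(confidence > 1)) confidence / 100 else as.numeric(confidence)
  e <- as.numeric(correct)
  n <- length(p)
  j <- vapply(p, brute_bin_index, numeric(1), edges = edges)
  e_bar <- sum(e) / n
  cal <- 0
  res <- 0
  for (b in unique(j)) {
    idx <- which(j == b)
    cal <- cal + length(idx) * (mean(p[idx]) - mean(e[idx]))^2
    res <- res + length(idx) * (mean(e[idx]) - e_bar)^2
  }
  k <- e_bar * (1 - e_bar)
  list(calibration = cal / n,
       resolution = res / n,
       nrs = if (k == 0) 0 else (res / n) / k,
       over_under = sum(p) / n - e_bar)
}

# Classical balanced-design sums of squares computed from group means only;
# valid as a sequential-SS oracle because the complete 2 x 2 x judge layout
# is orthogonal.
balanced_anova_oracle <- function(cells, response) {
  y <- cells[[response]]
  grand <- mean(y)
  ss_level <- function(f) {
    sum(vapply(unique(f), function(l) {
      sum(f == l) * (mean(y[f == l]) - grand)^2
    }, numeric(1)))
  }
  tp <- as.character(cells$time_pressure)
  di <- as.character(cells$difficulty)
  ju <- as.character(cells$judge_id)
  ss_tp <- ss_level(tp)
  ss_diff <- ss_level(di)
  ss_judge <- ss_level(ju)
  cellkey <- paste(tp, di)
  ss_cells <- ss_level(cellkey)
  ss_int <- ss_cells - ss_tp - ss_diff
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_tp - ss_diff - ss_judge - ss_int
  df_judge <- length(unique(ju)) - 1L
  df_res <- length(y) - 1L - 2L - df_judge - 1L
  ms_res <- ss_res / df_res
  list(
    f = c(time_pressure = (ss_tp / 1) / ms_res,
          difficulty = (ss_diff / 1) / ms_res,
          participant = (ss_judge / df_judge) / ms_res,
          interaction = (ss_int / 1) / ms_res),
    df_res = df_res
  )
}
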