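test_that("binning assigns records to half-open decile categories", {
  one <- make_records(100, TRUE)
  bins <- bin_confidence(one)
  top <- bins[bins$j == 6, ]
  expect_identical(top$n_j, 1L)
  expect_identical(top$p_bar_j, 1)
  expect_identical(top$e_bar_j, 1)
  expect_identical(sum(bins$n_j), 1L)

  two <- make_records(c(55, 55), c(TRUE, FALSE))
  bins <- bin_confidence(two)
  b <- bins[bins$j == 2, ]  # [0.5, 0.6)
  expect_identical(b$n_j, 2L)
  expect_equal(b$p_bar_j, 0.55)
  expect_equal(b$e_bar_j, 0.5)

  # a rating of 59 belongs to [0.5, 0.6); empty bins are retained
  bins <- bin_confidence(make_records(59, TRUE))
  expect_identical(bins$n_j[bins$j == 2], 1L)
  expect_identical(nrow(bins), 6L)
  expect_identical(sum(bins$n_j == 0L), 5L)

  expect_error(bin_confidence(make_records(numeric(0), logical(0))),
               class = "confcal_empty_error")
  expect_error(bin_confidence(make_records(50, TRUE), edges = c(0.1, 0.5, 1)), "span")
})

test_that("bin counts match a per-record linear-scan oracle", {
  rec <- random_records(50, seed = 101)
  bins <- bin_confidence(rec)
  j <- vapply(rec$confidence / 100, brute_bin_index, numeric(1),
              edges = calibration_edges())
  for (b in bins$j) {
    expect_identical(bins$n_j[bins$j == b], sum(j == b))
  }
})

test_that("calibration score reproduces its analytic extremes and a hand-worked case", {
  worst <- worst_responder(5, 5)
  expect_identical(calibration_score(bin_confidence(worst)), 1)

  perfect <- make_records(c(rep(80, 10), rep(60, 10)),
                          c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(calibration_score(bin_confidence(perfect)), 0)

  # 3 occupied bins: (2; 0.55; 0.5), (1; 0.75; 1.0), (1; 0.95; 1.0)
  # -> (2*0.0025 + 1*0.0625 + 1*0.0025) / 4 = 0.07 / 4 = 0.0175, worked by hand
  rec <- make_records(c(55, 55, 75, 95), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(calibration_score(bin_confidence(rec)), 0.0175)
})

test_that("over/underconfidence is mean confidence minus proportion correct", {
  expect_identical(over_underconfidence(make_records(rep(100, 4), rep(TRUE, 4))), 0)
  rec <- make_records(rep(70, 10), c(rep(TRUE, 8), rep(FALSE, 2)))
  expect_equal(over_underconfidence(rec), -0.10)
  expect_error(over_underconfidence(make_records(numeric(0), logical(0))),
               class = "confcal_empty_error")
})

test_that("resolution spans zero (one bin) to the knowledge index (perfect discrimination)", {
  one_bin <- make_records(c(72, 75, 78), c(TRUE, FALSE, TRUE))
  expect_identical(resolution(bin_confidence(one_bin)), 0)

  worst <- worst_responder(5, 5)  # half correct, perfectly separated by confidence
  expect_identical(resolution(bin_confidence(worst), e_bar = 0.5), 0.25)

  rec <- random_records(50, seed = 202)
  oracle <- brute_calibration_stats(rec$confidence, rec$correct)
  expect_equal(resolution(bin_confidence(rec), e_bar = mean(rec$correct)),
               oracle$resolution, tolerance = 1e-12)
})

test_that("normalised resolution is resolution over the knowledge index, 0 when degenerate", {
  expect_identical(as.numeric(normalised_resolution(0, 0.5)), 0)
  nrs <- normalised_resolution(0.25, 0.5)
  expect_identical(as.numeric(nrs), 1)
  expect_false(attr(nrs, "degenerate"))

  all_correct <- normalised_resolution(0, 1)
  expect_identical(as.numeric(all_correct), 0)
  expect_true(attr(all_correct, "degenerate"))

  expect_error(normalised_resolution(0.3, 0.5), "knowledge index")
})

test_that("the summary composes the statistics consistently", {
  worst <- worst_responder(5, 5)
  s <- calibration_summary(worst)
  expect_identical(s$calibration, 1)
  expect_identical(s$normalised_resolution, 1)
  expect_identical(s$over_under, 0)
  expect_false(s$degenerate)
  expect_s3_class(attr(s, "bins"), "tbl_df")

  perfect <- make_records(c(rep(80, 10), rep(60, 10)),
                          c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 6), rep(FALSE, 4)))
  s <- calibration_summary(perfect)
  expect_equal(s$calibration, 0)
  expect_equal(s$over_under, 0)
})

test_that("binned statistics equal the brute-force per-record oracle on random tables", {
  for (seed in 301:325) {
    rec <- random_records(sample(10:80, 1), seed = seed)
    s <- calibration_summary(rec)
    oracle <- brute_calibration_stats(rec$confidence, rec$correct)
    expect_equal(s$calibration, oracle$calibration, tolerance = 1e-12)
    expect_equal(s$resolution, oracle$resolution, tolerance = 1e-12)
    expect_equal(s$normalised_resolution, oracle$nrs, tolerance = 1e-12)
    expect_equal(s$over_under, oracle$over_under, tolerance = 1e-12)
  }
})

test_that("statistics are invariant to the confidence representation and record order", {
  rec100 <- random_records(60, seed = 404)
  rec01 <- rec100
  rec01$confidence <- rec01$confidence / 100
  s100 <- calibration_summary(rec100, scale = "percent")
  s01 <- calibration_summary(rec01, scale = "probability")
  expect_equal(as.data.frame(s100), as.data.frame(s01))

  set.seed(1)
  shuffled <- rec100[sample(nrow(rec100)), ]
  expect_equal(as.data.frame(calibration_summary(shuffled)), as.data.frame(s100))
})

test_that("all statistics respect their bounds on random tables", {
  for (seed in 501:550) {
    rec <- random_records(sample(3:40, 1), seed = seed,
                          p_correct = stats::runif(1))
    s <- calibration_summary(rec)
    expect_true(s$calibration >= 0 && s$calibration <= 1)
    expect_true(s$normalised_resolution >= 0 && s$normalised_resolution <= 1)
    expect_true(s$over_under >= -1 && s$over_under <= 1)
    expect_true(s$resolution <= s$e_bar * (1 - s$e_bar) + 1e-12)
  }
})

test_that("per-judge summaries agree with per-table computation", {
  rec <- generate_cohort(cohort_config(n_students = 4, n_experienced = 3, seed = 8L))
  js <- calibrate_judges(rec)
  expect_identical(nrow(js), 7L)
  one <- rec[rec$judge_id == "stu002", ]
  direct <- calibration_summary(one)
  row <- js[js$judge_id == "stu002", ]
  expect_equal(row$calibration, direct$calibration)
  expect_equal(row$normalised_resolution, direct$normalised_resolution)
  expect_equal(row$over_under, direct$over_under)
})
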