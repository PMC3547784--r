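normal_vitals <- function(n = 1) {
  tibble::tibble(systolic_bp = rep(120, n), heart_rate = rep(75, n),
                 respiratory_rate = rep(14, n), temperature = rep(37, n),
                 consciousness = rep("alert", n))
}

test_that("normal vitals score zero on every cue", {
  s <- mews_subscores(normal_vitals())
  expect_identical(unname(unlist(s[1, ])), rep(0L, 6))
})

test_that("unresponsive consciousness maps to the maximal subscore", {
  v <- normal_vitals()
  v$consciousness <- "unresponsive"
  expect_identical(mews_subscores(v)$consciousness_score, 3L)
})

test_that("boundary values per cue match a hand-transcribed scoring table", {
  # independent transcription of the Subbe 2001 cut-offs
  grids <- list(
    systolic_bp = list(v = c(30, 50, 70, 71, 80, 81, 100, 101, 150, 199, 200, 300),
                       s = c(3, 3, 3, 2, 2, 1, 1, 0, 0, 0, 2, 2)),
    heart_rate = list(v = c(10, 40, 41, 50, 51, 100, 101, 110, 111, 129, 130, 300),
                      s = c(2, 2, 1, 1, 0, 0, 1, 1, 2, 2, 3, 3)),
    respiratory_rate = list(v = c(1, 8, 9, 14, 15, 20, 21, 29, 30, 80),
                            s = c(2, 2, 0, 0, 1, 1, 2, 2, 3, 3)),
    temperature = list(v = c(25, 34.9, 35, 38.4, 38.5, 45),
                       s = c(2, 2, 0, 0, 2, 2))
  )
  for (cue in names(grids)) {
    v <- normal_vitals(length(grids[[cue]]$v))
    v[[cue]] <- grids[[cue]]$v
    expect_identical(mews_subscores(v)[[paste0(cue, "_score")]],
                     as.integer(grids[[cue]]$s))
  }
  v <- normal_vitals(4)
  v$consciousness <- c("alert", "voice", "pain", "unresponsive")
  expect_identical(mews_subscores(v)$consciousness_score, 0:3)
})

test_that("values outside the table's coverage raise a scoring error naming the cue", {
  v <- normal_vitals()
  v$systolic_bp <- 10
  expect_error(mews_subscores(v), "systolic_bp.*10", class = "confcal_scoring_error")
  v <- normal_vitals()
  v$consciousness <- "sleepy"
  expect_error(mews_subscores(v), "consciousness", class = "confcal_scoring_error")
})

test_that("worsening a cue away from its normal range never lowers its subscore", {
  tab <- mews_table()
  for (cue in c("systolic_bp", "heart_rate", "respiratory_rate", "temperature")) {
    rows <- tab[tab$cue == cue, ]
    rows <- rows[order(rows$lower), ]
    zero_row <- which(rows$score == 0L)
    mids <- (rows$lower + rows$upper) / 2
    score_at <- function(vals) {
      v <- normal_vitals(length(vals))
      v[[cue]] <- vals
      mews_subscores(v)[[paste0(cue, "_score")]]
    }
    below <- rev(mids[seq_len(zero_row)])      # normal -> progressively lower
    above <- mids[zero_row:nrow(rows)]         # normal -> progressively higher
    expect_true(all(diff(score_at(below)) >= 0), label = paste(cue, "downward"))
    expect_true(all(diff(score_at(above)) >= 0), label = paste(cue, "upward"))
  }
})

test_that("total MEWS equals the sum of subscores across random valid vitals", {
  set.seed(9)
  v <- tibble::tibble(
    systolic_bp = runif(200, 30, 300), heart_rate = runif(200, 10, 300),
    respiratory_rate = runif(200, 1, 80), temperature = runif(200, 25, 45),
    consciousness = sample(c("alert", "voice", "pain", "unresponsive"), 200, TRUE)
  )
  s <- mews_subscores(v)
  expect_identical(s$total, as.integer(rowSums(s[1:5])))
  expect_true(all(unlist(s[1:5]) %in% 0:3))
})

test_that("at-risk classification applies the strict greater-than-threshold rule", {
  expect_false(classify_risk(0L))
  expect_false(classify_risk(5L))
  expect_true(classify_risk(6L))
  expect_error(classify_risk(16L))
  expect_error(classify_risk(-1L))
  expect_true(classify_risk(5L, threshold = 4L))  # configurable dialect
})

test_that("difficulty labels follow score/outcome concordance", {
  expect_identical(classify_difficulty(TRUE, TRUE), "easy")
  expect_identical(classify_difficulty(TRUE, FALSE), "difficult")
  expect_identical(classify_difficulty(FALSE, FALSE), "easy")
  expect_identical(classify_difficulty(FALSE, TRUE), "difficult")
  expect_error(classify_difficulty(NA, TRUE), "missing")
})

test_that("a scenario set with d discordant cases yields exactly d difficult labels", {
  set.seed(12)
  n <- 25
  v <- tibble::tibble(
    scenario_id = sprintf("sc%02d", 1:n),
    systolic_bp = sample(c(65, 120), n, TRUE),
    heart_rate = sample(c(75, 140), n, TRUE),
    respiratory_rate = sample(c(14, 35), n, TRUE),
    temperature = 37,
    consciousness = sample(c("alert", "unresponsive"), n, TRUE)
  )
  sub <- mews_subscores(v)
  predicted <- classify_risk(sub$total)
  # outcome agrees with the score except for 7 flipped cases
  flip <- sample(n, 7)
  outcome <- predicted
  outcome[flip] <- !outcome[flip]
  v$outcome_critical <- outcome
  labels <- score_scenarios(v)
  expect_identical(sum(labels$difficulty == "difficult"), 7L)
  expect_identical(labels$at_risk_predicted, predicted)
  expect_identical(labels$total, sub$total)
})

test_that("malformed scoring tables are rejected", {
  tab <- mews_table()
  expect_error(confcal:::validate_mews_table(tab[tab$cue != "temperature", ]), "cues")
  tab2 <- tab
  tab2$upper[tab2$cue == "heart_rate" & tab2$lower == 51] <- 90  # gap
  expect_error(confcal:::validate_mews_table(tab2), "contiguous")
})
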