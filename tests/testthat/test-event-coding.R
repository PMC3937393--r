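mkTrials <- function(congruent, run = 1L) {
  n <- length(congruent)
  data.frame(run_index = run, trial_index = seq_len(n),
             onset_ms = (seq_len(n) - 1) * 7000,
             direction = "left",
             position = ifelse(congruent, "left", "right"),
             isi_ms = 5700, congruent = congruent)
}

mkBehavior <- function(trials, rt = 500, correct = TRUE, omitted = FALSE) {
  trials$rt_ms <- rep_len(rt, nrow(trials))
  trials$correct <- rep_len(correct, nrow(trials))
  trials$omitted <- rep_len(omitted, nrow(trials))
  trials
}

test_that("the sequence coding rule labels C,I,I,C as run_initial, cI, iI, iC", {
  tr <- mkTrials(c(TRUE, FALSE, FALSE, TRUE))
  lab <- classifyTrials(tr, mkBehavior(tr))
  expect_equal(as.character(lab$condition),
               c("run_initial", "cI", "iI", "iC"))
})

test_that("incorrect trials become nuisance but still provide stimulus context", {
  tr <- mkTrials(c(TRUE, FALSE, FALSE))
  b <- mkBehavior(tr, correct = c(TRUE, FALSE, TRUE))
  # only 2 correct trials, so the SD-based outlier ceiling warns and is skipped
  expect_warning(lab <- classifyTrials(tr, b), "fewer than 3")
  # trial 2 is nuisance, yet trial 3 is iI because the preceding *stimulus*
  # was incongruent
  expect_equal(as.character(lab$condition), c("run_initial", "nuisance", "iI"))
})

test_that("conditions partition every run and relabeling is idempotent", {
  lab <- labeledTrials(tinyDesign(nRuns = 2L))
  expect_equal(sum(table(lab$condition)), nrow(lab))
  expect_equal(sum(lab$condition == "run_initial"), 2L)
  lab2 <- classifyTrials(lab, lab)
  expect_equal(lab2$condition, lab$condition)
})

test_that("misaligned inputs are rejected with the first mismatched row", {
  tr <- mkTrials(c(TRUE, FALSE, TRUE))
  b <- mkBehavior(tr)
  b$trial_index <- c(1L, 3L, 2L)
  expect_error(classifyTrials(tr, b), "row 2")
  expect_error(classifyTrials(tr, b[1:2, ]), "different numbers of rows")
})

test_that("RT outlier rule: floor catches fast trials, mean+3SD catches slow", {
  # rule applied to the listed values: mean 1625, SD 2250 -> ceiling 8375,
  # so 5000 is NOT above the ceiling in this 4-trial sample
  b4 <- data.frame(rt_ms = c(500, 510, 490, 5000),
                   correct = TRUE, omitted = FALSE)
  expect_equal(flagRTOutliers(b4), rep(FALSE, 4))
  # with a stable reference sample the slow trial is flagged:
  # mean ~514, SD ~31 -> ceiling ~607 < 5000
  rts <- c(rep(c(490, 500, 510, 540), 5), 5000)
  b <- data.frame(rt_ms = rts, correct = TRUE, omitted = FALSE)
  flags <- flagRTOutliers(b)
  expect_equal(which(flags), 21L)
  expect_true(flagRTOutliers(data.frame(rt_ms = c(150, rep(500, 10)),
                                        correct = TRUE, omitted = FALSE))[1])
})

test_that("RT outlier rule edge cases: zero variance and tiny samples", {
  b <- data.frame(rt_ms = rep(500, 6), correct = TRUE, omitted = FALSE)
  expect_equal(flagRTOutliers(b), rep(FALSE, 6))
  tiny <- data.frame(rt_ms = c(500, 5000), correct = TRUE, omitted = FALSE)
  expect_warning(flags <- flagRTOutliers(tiny), "fewer than 3")
  expect_equal(flags, c(FALSE, FALSE))
})

test_that("rtInterference is the incongruent minus congruent mean", {
  df <- data.frame(congruent = c(TRUE, TRUE, FALSE, FALSE),
                   rt_ms = c(470, 470, 520, 520),
                   correct = TRUE, omitted = FALSE)
  expect_equal(rtInterference(df), 50)
  df$rt_ms <- c(500, 500, 500, 500)
  expect_equal(rtInterference(df), 0)
  expect_error(rtInterference(df[df$congruent, ]), "each congruency")
})

test_that("rtInterference is closed under the noiseless generator", {
  lab <- labeledTrials(taskDesign(),
                       quickProfile(interference = 60, adaptation = 0,
                                    noise = 0, errorRate = 0))
  expect_equal(rtInterference(lab), 60)
})
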