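test_that("canonical HRF peaks between 4 and 7 s, vanishes at 0, has an undershoot", {
  h <- canonicalHRF()
  t <- attr(h, "times")
  expect_equal(h[1], 0)
  expect_gte(t[which.max(h)], 4)
  expect_lte(t[which.max(h)], 7)
  expect_equal(max(h), 1)           # unit-peak normalisation
  expect_lt(min(h), 0)              # late undershoot
  expect_gt(t[which.min(h)], t[which.max(h)])
  # no undershoot term: kernel everywhere non-negative
  h0 <- canonicalHRF(hrfSpec(undershootRatio = 0))
  expect_true(all(h0 >= 0))
})

oneEventTrials <- function(onsets, congruent, run = 1L) {
  n <- length(onsets)
  data.frame(run_index = run, trial_index = seq_len(n), onset_ms = onsets,
             direction = "left",
             position = ifelse(congruent, "left", "right"),
             isi_ms = 5000, congruent = congruent,
             rt_ms = 500, correct = TRUE, omitted = FALSE, rt_outlier = FALSE,
             condition = factor(
               c("run_initial",
                 if (n > 1) paste0(ifelse(congruent[-n], "c", "i"),
                                   ifelse(congruent[-1], "C", "I"))),
               levels = c("cC", "cI", "iC", "iI", "run_initial", "nuisance")))
}

test_that("design matrix columns are HRF-convolved and linear in events", {
  d <- tinyDesign()
  lab1 <- oneEventTrials(c(0, 20000), c(TRUE, FALSE))       # one cI at 20 s
  X1 <- buildDesignMatrix(lab1, d)
  lab2 <- oneEventTrials(c(0, 20000, 50000), c(TRUE, FALSE, FALSE)) # + iI at 50 s
  X2 <- buildDesignMatrix(lab2, d)
  # the shared cI regressor is identical whatever else is in the run
  expect_equal(designValues(X1)[, "run1_cI"], designValues(X2)[, "run1_cI"])
  # two events of one condition = sum of the single-event regressors
  lab3 <- oneEventTrials(c(0, 20000, 50000), c(TRUE, FALSE, FALSE))
  lab3$condition[3] <- "cI"
  X3 <- buildDesignMatrix(lab3, d)
  lab4 <- oneEventTrials(c(0, 50000), c(TRUE, FALSE))
  X4 <- buildDesignMatrix(lab4, d)
  expect_equal(designValues(X3)[, "run1_cI"],
               designValues(X1)[, "run1_cI"] + designValues(X4)[, "run1_cI"],
               tolerance = 1e-12)
})

test_that("single-event regressor reproduces the sampled HRF shape", {
  d <- tinyDesign()
  lab <- oneEventTrials(c(0, 22000), c(TRUE, FALSE))
  X <- buildDesignMatrix(lab, d)
  reg <- designValues(X)[, "run1_cI"]
  # event at 22 s = volume 10 boundary: regressor must be 0 before onset
  expect_true(all(abs(reg[1:10]) < 1e-12))
  expect_gt(max(reg), 0.9)          # ~unit-amplitude response to a 1.3 s boxcar
  expect_equal(which.max(reg), 10 + round(6.5 / 2.2) + 1, tolerance = 1)
})

test_that("the DCT high-pass basis has floor(2*T/cutoff) columns per run", {
  d <- taskDesign(nRuns = 1L)
  lab <- labeledTrials(d)
  X <- buildDesignMatrix(lab, d, hpfCutoffS = 128)
  dct <- grep("dct", regressorNames(X), value = TRUE)
  expect_length(dct, floor(2 * 140 * 2.2 / 128))   # 4
})

test_that("high-pass confounds absorb slow drifts", {
  d <- taskDesign(nRuns = 1L)
  lab <- labeledTrials(d)
  X <- buildDesignMatrix(lab, d)
  Xm <- designValues(X)
  tS <- (0:139) * 2.2
  # drift at a DCT frequency is removed exactly
  inBasis <- cos(pi * (2 * (0:139) + 1) * 2 / (2 * 140))
  expect_lt(max(abs(lm.fit(Xm, inBasis)$residuals)), 1e-10)
  # an off-basis slow sine loses most of its variance (finite-window
  # leakage keeps the projection from being exact)
  drift <- sin(2 * pi * tS / 400)
  resid <- lm.fit(Xm, drift)$residuals
  expect_lt(sd(resid) / sd(drift), 0.2)
})

test_that("OLS recovers noiseless planted amplitudes and leaves orthogonal residuals", {
  d <- tinyDesign()
  grid <- tinyGrid()
  lab <- labeledTrials(d, quickProfile(noise = 0, errorRate = 0))
  # cI and cC effects planted at the same site so the contrast there is
  # their amplitude difference
  tmpl <- effectTemplate(data.frame(
    name = c("r1", "r2"), x = 0, y = 0, z = -5, radius_mm = 6,
    condition = c("cI", "cC"), amplitude = 1))
  amps <- c(cC = 0.4, cI = 1.0, iC = 0.5, iI = 0.8)
  bold <- simulateBoldRun(lab, d, grid, tmpl, amps,
                          noise = list(sd = 0, ar1 = 0, smoothFwhmMm = 0))
  X <- buildDesignMatrix(lab, d)
  fit <- fitGLM(bold, X, grid)
  vox1 <- nearestVoxel(grid, c(0, 0, -5))
  expect_equal(unname(coef(fit)["run1_cI", vox1]), 1.0, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["run1_cC", vox1]), 0.4, tolerance = 1e-6)
  # contrast equals the planted difference at the cI region centre
  cmap <- contrastMap(fit, contrastSpec("conflict_resolution"))
  expect_equal(statValues(cmap)[vox1], 1.0 - 0.4, tolerance = 1e-6)
  # residual orthogonality on a noisy fit
  bold2 <- bold + array(rnorm(length(bold)), dim(bold))
  fit2 <- fitGLM(bold2, X, grid)
  Y <- t(matrix(bold2, prod(gridDims(grid)), dim(bold2)[4]))
  R <- Y - designValues(X) %*% coef(fit2)
  expect_lt(max(abs(crossprod(designValues(X), R))) / max(abs(Y)), 1e-8)
})

test_that("toy orthogonal design gives projection betas and exact residual variance", {
  X0 <- cbind(a = rep(c(1, -1), 10), b = rep(c(1, 1, -1, -1), 5))
  Xd <- new("DesignMatrix", values = X0, trMs = 2200, hpfCutoffS = 128,
            runIndex = rep(1L, 20), absent = character())
  y <- matrix(rnorm(20), 20, 1)
  g1 <- acquisitionGrid(c(1L, 1L, 1L))
  fit <- fitGLM(y, Xd, g1)
  expect_equal(unname(coef(fit)[, 1]),
               c(sum(X0[, 1] * y) / 20, sum(X0[, 2] * y) / 20),
               tolerance = 1e-12)
  # pure-noise residual variance is close to the noise variance
  set.seed(2)
  yN <- matrix(rnorm(20 * 2000), 20)
  fitN <- fitGLM(yN, Xd, acquisitionGrid(c(2000L, 1L, 1L)))
  expect_equal(mean(residVar(fitN)), 1, tolerance = 0.05)
})

test_that("rank-deficient designs and absent contrast conditions are rejected", {
  X0 <- cbind(a = rep(1, 10), b = rep(1, 10))
  Xd <- new("DesignMatrix", values = X0, trMs = 2200, hpfCutoffS = 128,
            runIndex = rep(1L, 10), absent = character())
  expect_error(fitGLM(matrix(rnorm(10), 10, 1), Xd,
                      acquisitionGrid(c(1L, 1L, 1L))), "collinear")
  # a design lacking iC events omits the column and records it
  d <- tinyDesign()
  lab <- oneEventTrials(c(0, 20000, 40000), c(TRUE, FALSE, FALSE))
  X <- buildDesignMatrix(lab, d)
  expect_true("run1_iC" %in% absentConditions(X))
  bold <- matrix(rnorm(40), 40, 1)
  fit <- fitGLM(bold, X, acquisitionGrid(c(1L, 1L, 1L)))
  expect_error(contrastMap(fit, contrastSpec(weights = c(iC = 1, cC = -1))),
               "absent")
})

test_that("all-zero weights give an all-zero map; equal amplitudes a ~zero map", {
  d <- tinyDesign()
  lab <- labeledTrials(d, quickProfile(noise = 0, errorRate = 0))
  grid <- tinyGrid()
  tmpl <- effectTemplate(data.frame(name = "r", x = 0, y = 0, z = 0,
                                    radius_mm = 8, condition = "iI",
                                    amplitude = 1))
  bold <- simulateBoldRun(lab, d, grid, tmpl,
                          c(cC = 0.5, cI = 0.7, iC = 0.5, iI = 0.7),
                          noise = list(sd = 0, ar1 = 0, smoothFwhmMm = 0))
  X <- buildDesignMatrix(lab, d)
  fit <- fitGLM(bold, X, grid)
  zmap <- contrastMap(fit, contrastSpec(weights = c(cI = 0, cC = 0)))
  expect_true(all(statValues(zmap) == 0))
})
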