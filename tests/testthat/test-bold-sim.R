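test_that("FFT Gaussian smoothing matches direct convolution on a small array", {
  set.seed(1)
  d <- c(7, 6, 5)
  x <- array(rnorm(prod(d)), d)
  fwhm <- 6; vs <- c(3, 3, 3.5)
  sm <- gaussianSmooth3D(x, fwhm, vs)
  # brute-force truncated-Gaussian convolution with the same support
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vs
  pad <- pmax(1, ceiling(4 * sigma))
  w1 <- function(s, p) { k <- exp(-(-p:p)^2 / (2 * s^2)); k / sum(k) }
  kx <- w1(sigma[1], pad[1]); ky <- w1(sigma[2], pad[2]); kz <- w1(sigma[3], pad[3])
  ref <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0
    for (a in -pad[1]:pad[1]) for (b in -pad[2]:pad[2]) for (cc in -pad[3]:pad[3]) {
      ii <- i + a; jj <- j + b; kk <- k + cc
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 && kk <= d[3])
        acc <- acc + x[ii, jj, kk] * kx[a + pad[1] + 1] * ky[b + pad[2] + 1] *
          kz[cc + pad[3] + 1]
    }
    ref[i, j, k] <- acc
  }
  # the FFT kernel keeps the full (wrapped, zero-padded) Gaussian support
  # while the reference truncates at 4 sigma, so agreement is to the
  # truncated tail mass, not machine precision
  expect_equal(sm, ref, tolerance = 1e-5)
  expect_identical(gaussianSmooth3D(x, 0, vs), x)
})

test_that("noiseless BOLD at a planted voxel equals amplitude times the regressor", {
  d <- tinyDesign()
  grid <- tinyGrid()
  lab <- labeledTrials(d, quickProfile(noise = 0, errorRate = 0))
  tmpl <- effectTemplate(data.frame(name = "r", x = 0, y = 0, z = 0,
                                    radius_mm = 8, condition = "cI",
                                    amplitude = 1))
  bold <- simulateBoldRun(lab, d, grid, tmpl, c(cI = 0.7),
                          noise = list(sd = 0, ar1 = 0, smoothFwhmMm = 0))
  X <- buildDesignMatrix(lab, d)
  reg <- designValues(X)[, "run1_cI"]
  ctr <- nearestVoxel(grid, c(0, 0, 0))
  series <- matrix(bold, prod(gridDims(grid)))[ctr, ]
  expect_equal(series, 0.7 * reg, tolerance = 1e-12)
  # a voxel far from the sphere carries no signal
  far <- nearestVoxel(grid, c(12, 12, 8))
  expect_true(all(matrix(bold, prod(gridDims(grid)))[far, ] == 0))
})

test_that("noise has the requested lag-1 autocorrelation and marginal SD", {
  d <- taskDesign(nRuns = 1L)          # 140 volumes
  grid <- tinyGrid()
  lab <- labeledTrials(d)
  tmpl <- effectTemplate(data.frame(name = character(), x = numeric(),
                                    y = numeric(), z = numeric(),
                                    radius_mm = numeric(),
                                    condition = character(),
                                    amplitude = numeric()))
  bold <- simulateBoldRun(lab, d, grid, tmpl, c(cI = 0),
                          noise = list(sd = 1, ar1 = 0.3, smoothFwhmMm = 0),
                          seed = 4)
  m <- matrix(bold, prod(gridDims(grid)))
  ac1 <- mean(apply(m[1:50, ], 1, function(x) cor(x[-1], x[-length(x)])))
  expect_lt(abs(ac1 - 0.3), 0.1)
  expect_equal(sd(as.numeric(m)), 1, tolerance = 1e-6)
})

test_that("regions outside the grid are rejected by name", {
  d <- tinyDesign()
  grid <- tinyGrid()
  lab <- labeledTrials(d)
  tmpl <- effectTemplate(data.frame(name = "lost", x = 500, y = 0, z = 0,
                                    radius_mm = 5, condition = "cI",
                                    amplitude = 1))
  expect_error(simulateBoldRun(lab, d, grid, tmpl, c(cI = 1)), "lost")
})

test_that("BOLD simulation is deterministic in its seed", {
  d <- tinyDesign()
  grid <- tinyGrid()
  lab <- labeledTrials(d)
  tmpl <- defaultEffectTemplate(centerMm = c(0, 0, 0), radiusMm = 8)
  args <- list(lab, d, grid, tmpl, c(cC = .5, cI = 1, iC = .5, iI = .8))
  b1 <- do.call(simulateBoldRun, c(args, list(seed = 11)))
  b2 <- do.call(simulateBoldRun, c(args, list(seed = 11)))
  b3 <- do.call(simulateBoldRun, c(args, list(seed = 12)))
  expect_identical(b1, b2)
  expect_false(identical(b1, b3))
})
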