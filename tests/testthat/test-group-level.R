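test_that("connected-component labelling matches a flood-fill oracle", {
  set.seed(5)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:5) {
      m <- array(runif(6 * 6 * 4) < 0.3, c(6, 6, 4))
      got <- sort(labelClusters(m, conn)$sizes)
      expect_equal(got, sort(floodFillSizes(m, conn)))
    }
  }
})

test_that("corner-touching cubes merge only under 26-connectivity", {
  m <- array(FALSE, c(8, 8, 8))
  m[1:3, 1:3, 1:3] <- TRUE
  m[4:6, 4:6, 4:6] <- TRUE      # shares only the corner (3,3,3)-(4,4,4)
  expect_length(labelClusters(m, 6)$sizes, 2)
  expect_length(labelClusters(m, 18)$sizes, 2)
  expect_length(labelClusters(m, 26)$sizes, 1)
})

test_that("cluster tables report planted cubes with size, peak and direction", {
  grid <- acquisitionGrid(c(12L, 12L, 10L))
  stat <- array(0, gridDims(grid))
  stat[4:8, 4:8, 3:7] <- 5                      # 125 suprathreshold voxels
  stat[6, 6, 5] <- 7                            # peak
  map <- statMap(stat, dof = 90, kind = "group_t", grid = grid)
  tab <- clusterTable(map, voxelP = 0.025, kStar = 30)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size_vox, 125)
  expect_equal(tab$peak_stat, 7)
  expect_equal(unlist(tab[, c("peak_x", "peak_y", "peak_z")], use.names = FALSE),
               as.numeric(voxelToMm(grid, c(6, 6, 5))))
  # sign symmetry: the negated map appears as a negative-direction cluster
  nmap <- statMap(-stat, dof = 90, kind = "group_t", grid = grid)
  ntab <- clusterTable(nmap, voxelP = 0.025, kStar = 30)
  expect_equal(ntab$direction, "negative")
  expect_equal(ntab$size_vox, tab$size_vox)
  expect_equal(ntab$peak_stat, -tab$peak_stat)
  # all-subthreshold map -> empty table
  expect_equal(nrow(clusterTable(statMap(array(0.5, gridDims(grid)), 90,
                                         "group_t", grid),
                                 kStar = 5)), 0)
  # the extent threshold filters small clusters
  expect_equal(nrow(clusterTable(map, kStar = 126)), 0)
})

test_that("group t-test with covariates is calibrated under the null", {
  set.seed(8)
  grid <- acquisitionGrid(c(10L, 10L, 5L))
  n <- 40
  coh <- data.frame(group = rep(c("stutter", "control"), each = 20),
                    age_yr = rnorm(n, 25, 8), sex = sample(c("M", "F"), n, TRUE),
                    iq = rnorm(n, 110, 12), rt_interference_obs = rnorm(n, 60, 15))
  maps <- matrix(rnorm(n * 500), n, 500)
  sm <- groupTTestCovariates(maps, coh, grid = grid)
  expect_equal(dof(sm), n - 6)
  p <- 2 * pt(-abs(statValues(sm)), dof(sm))
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
  ks <- ks.test(as.numeric(p), "punif")$statistic
  expect_lt(unname(ks), 0.08)
})

test_that("a covariate fully explaining a spurious difference collapses the group t", {
  set.seed(9)
  n <- 60
  confound <- c(rnorm(30, 1), rnorm(30, -1))   # differs by group
  maps <- matrix(confound + rnorm(n, 0, 0.1), n, 50)
  coh <- data.frame(group = rep(c("stutter", "control"), each = 30),
                    conf = confound)
  grid <- acquisitionGrid(c(50L, 1L, 1L))
  raw <- groupTTestCovariates(maps, coh, covariates = character(), grid = grid)
  adj <- groupTTestCovariates(maps, coh, covariates = "conf", grid = grid)
  expect_gt(mean(abs(statValues(raw))), 5)
  expect_lt(mean(abs(statValues(adj))), 2)
})

test_that("planted group differences are detected at the peak voxel", {
  set.seed(10)
  grid <- acquisitionGrid(c(6L, 6L, 4L))
  nvox <- prod(gridDims(grid))
  hits <- 0L
  for (s in 1:20) {
    maps <- matrix(rnorm(98 * nvox), 98, nvox)
    maps[1:46, 50] <- maps[1:46, 50] + 0.8    # d = 0.8 at voxel 50
    coh <- data.frame(group = rep(c("stutter", "control"), c(46, 52)),
                      age_yr = rnorm(98, 24, 11), sex = sample(c("M", "F"), 98, TRUE),
                      iq = rnorm(98, 112, 14), rt_interference_obs = rnorm(98, 60, 20))
    sm <- groupTTestCovariates(maps, coh, grid = grid)
    p50 <- 2 * pt(-abs(statValues(sm)[50]), dof(sm))
    hits <- hits + (p50 < 0.025)
  }
  # per-voxel power for d = 0.8 at n = 46 + 52 is ~0.95
  expect_gte(hits, 17)
})

test_that("severity correlation recovers exact, null and planted couplings", {
  set.seed(11)
  grid <- acquisitionGrid(c(5L, 5L, 4L))
  nvox <- prod(gridDims(grid))
  sev <- rnorm(46)
  # affine image of severity -> r = 1 at every voxel
  maps <- outer(sev, rep(2, nvox)) + 3
  sm <- severityCorrelation(maps, sev, grid)
  expect_equal(as.numeric(statValues(sm)), rep(1, nvox), tolerance = 1e-10)
  # independent severity -> mean r near 0
  maps2 <- matrix(rnorm(46 * nvox), 46)
  sm2 <- severityCorrelation(maps2, sev, grid)
  expect_lt(abs(mean(statValues(sm2))), 0.08)
  # planted negative coupling recovered in sign at the planted voxel
  maps3 <- maps2; maps3[, 7] <- -0.5 * sev + rnorm(46, 0, 0.5)
  sm3 <- severityCorrelation(maps3, sev, grid)
  expect_lt(statValues(sm3)[7], -0.4)
  # missing severity dropped, zero variance rejected
  sevNA <- sev; sevNA[1:3] <- NA
  expect_message(severityCorrelation(maps2, sevNA, grid), "dropping 3")
  expect_error(severityCorrelation(maps2, rep(1, 46), grid), "zero variance")
})

test_that("Monte-Carlo extent threshold is reproducible and monotone in voxel p", {
  grid <- acquisitionGrid(c(12L, 12L, 8L), voxelSizeMm = c(3.75, 3.75, 3.5))
  mask <- brainMask(grid)
  a <- monteCarloClusterThreshold(grid, mask, voxelP = 0.025, nIter = 150,
                                  fwhmMm = 8, seed = 21)
  b <- monteCarloClusterThreshold(grid, mask, voxelP = 0.025, nIter = 150,
                                  fwhmMm = 8, seed = 21)
  expect_identical(a$kStar, b$kStar)
  strict <- monteCarloClusterThreshold(grid, mask, voxelP = 0.001,
                                       nIter = 150, fwhmMm = 8, seed = 21)
  expect_lte(strict$kStar, a$kStar)
  # the empirical null respects its own definition
  expect_lte(mean(a$nullMaxSizes >= a$kStar), 0.05)
  expect_error(monteCarloClusterThreshold(grid, mask, nIter = 50), "nIter")
  expect_error(monteCarloClusterThreshold(grid, mask, nIter = 100,
                                          alpha = 0.001), "resolution")
})
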