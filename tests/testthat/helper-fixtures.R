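# shared fixtures for the test suite; everything is generated in code

quickProfile <- function(base = 500, interference = 60, adaptation = 25,
                         noise = 40, errorRate = 0.05) {
  list(rt_base_ms = base, rt_interference_ms = interference,
       rt_adaptation_ms = adaptation, rt_noise_sd_ms = noise,
       error_rate = errorRate)
}

# a small fast design: 1 run, 12 trials, short run
tinyDesign <- function(nRuns = 1L)
  taskDesign(nRuns = nRuns, trialsPerRun = 12L, nCongruentPerRun = 6L,
             nIncongruentPerRun = 6L, isiMinMs = 2000, isiMaxMs = 4000,
             volumesPerRun = 40L)

tinyGrid <- function() acquisitionGrid(c(8L, 8L, 6L), trMs = 2200)

# labeled trials for one subject under a given profile
labeledTrials <- function(design = tinyDesign(), profile = quickProfile(),
                          seedT = 1, seedB = 2, ...) {
  tr <- makeTrialSequence(design, seedT)
  classifyTrials(tr, simulateBehavior(tr, profile, seedB, ...))
}

# linear index of the voxel whose centre is nearest an MNI mm coordinate
nearestVoxel <- function(grid, mm) {
  d <- gridDims(grid)
  ijk <- pmin(pmax(round(mmToVoxel(grid, mm)), 1), matrix(d, 1))
  as.integer((ijk[3] - 1) * d[1] * d[2] + (ijk[2] - 1) * d[1] + ijk[1])
}

# independent recursive flood-fill connected components (oracle for
# labelClusters); small inputs only
floodFillSizes <- function(mask, connectivity = 18) {
  d <- dim(mask)
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nn <- rowSums(abs(o))
  o <- switch(as.character(connectivity),
              "6" = o[nn == 1, , drop = FALSE],
              "18" = o[nn > 0 & nn <= 2, , drop = FALSE],
              "26" = o[nn > 0, , drop = FALSE])
  seen <- array(FALSE, d)
  sizes <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; sz <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; sz <- sz + 1L
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(o))) {
        nb <- co + o[r, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- (nb[3] - 1L) * d[1] * d[2] + (nb[2] - 1L) * d[1] + nb[1]
        if (mask[li] && !seen[li]) { seen[li] <- TRUE; queue <- c(queue, li) }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

# independent mixed-ANOVA oracle: stratum-wise projections on difference
# scores, no shared code with rmAnovaRT
oracleRmAnova <- function(cm) {
  n <- nrow(cm); g <- factor(cm$group)
  cells <- as.matrix(cm[, c("cC", "cI", "iC", "iI")])
  m <- rowMeans(cells)
  s <- list(
    pre = (cells[, "iC"] + cells[, "iI"] - cells[, "cC"] - cells[, "cI"]) / 2,
    cur = (cells[, "cI"] + cells[, "iI"] - cells[, "cC"] - cells[, "iC"]) / 2,
    pc  = (cells[, "cC"] - cells[, "cI"] - cells[, "iC"] + cells[, "iI"]) / 2)
  out <- list(group = anova(lm(m ~ g))["g", "F value"])
  for (nm in names(s)) {
    fit <- lm(s[[nm]] ~ g)
    rss <- sum(resid(fit)^2)
    out[[nm]] <- c(main = (sum(s[[nm]])^2 / n) / (rss / (n - 2)),
                   int = anova(fit)["g", "F value"])
  }
  out
}
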