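#' Gaussian-smooth a 3D volume by FFT convolution
#'
#' Separable Gaussian smoothing implemented as one 3D FFT convolution with
#' zero padding (4 sigma on each side), so there is no wrap-around. A kernel
#' FFT can be precomputed with [smoothingKernel()] and reused across many
#' volumes.
#'
#' @param x 3D numeric array.
#' @param fwhmMm Full width at half maximum in mm (scalar).
#' @param voxelSizeMm Voxel sizes in mm, length 3.
#' @param kernel Optional precomputed kernel from [smoothingKernel()].
#' @return The smoothed array, same dimensions as `x`.
#' @export
gaussianSmooth3D <- function(x, fwhmMm, voxelSizeMm, kernel = NULL) {
  if (is.null(kernel)) kernel <- smoothingKernel(dim(x), fwhmMm, voxelSizeMm)
  if (fwhmMm <= 0) return(x)
  pd <- kernel$pdims; pad <- kernel$pad; d <- dim(x)
  xp <- array(0, pd)
  xp[pad[1] + 1:d[1], pad[2] + 1:d[2], pad[3] + 1:d[3]] <- x
  s <- Re(stats::fft(stats::fft(xp) * kernel$fK, inverse = TRUE)) / prod(pd)
  s[pad[1] + 1:d[1], pad[2] + 1:d[2], pad[3] + 1:d[3]]
}

#' @rdname gaussianSmooth3D
#' @param dims Volume dimensions the kernel will be applied to.
#' @export
smoothingKernel <- function(dims, fwhmMm, voxelSizeMm) {
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm
  if (fwhmMm <= 0)
    return(list(pdims = dims, pad = c(0L, 0L, 0L), fK = NULL, sigmaVox = sigma))
  pad <- pmax(1L, ceiling(4 * sigma))
  pd <- dims + 2L * pad
  g1 <- function(n, s) {
    x <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1L)))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(outer(g1(pd[1], sigma[1]), g1(pd[2], sigma[2])), g1(pd[3], sigma[3]))
  list(pdims = pd, pad = pad, fK = stats::fft(array(K, pd)), sigmaVox = sigma)
}

#' Ellipsoidal acquisition-like brain mask
#'
#' An axis-aligned ellipsoid centred in the grid. The default semi-axes are
#' 15/16 of the half-dimensions, which on the full 64 x 64 x 34 acquisition
#' matrix gives ~60,000 in-mask voxels -- a brain-sized field of view for
#' the null simulations.
#'
#' @param grid An [AcquisitionGrid-class].
#' @param semiAxesVox Optional ellipsoid semi-axes in voxels, length 3;
#'   default `15/16 * dims/2`.
#' @return Logical 3D array.
#' @export
#' @examples
#' sum(brainMask(fullGrid()))   # ~60,000
brainMask <- function(grid, semiAxesVox = NULL) {
  d <- grid@dims
  if (is.null(semiAxesVox)) semiAxesVox <- (15 / 16) * d / 2
  ctr <- (d + 1) / 2
  i <- (seq_len(d[1]) - ctr[1]) / semiAxesVox[1]
  j <- (seq_len(d[2]) - ctr[2]) / semiAxesVox[2]
  k <- (seq_len(d[3]) - ctr[3]) / semiAxesVox[3]
  arr <- outer(outer(i^2, j^2, "+"), k^2, "+")
  arr <= 1
}

# linear voxel indices whose centres lie within radiusMm of centerMm
.sphereVoxels <- function(grid, centerMm, radiusMm) {
  d <- grid@dims
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  mm <- voxelToMm(grid, ijk)
  dist2 <- (mm[, 1] - centerMm[1])^2 + (mm[, 2] - centerMm[2])^2 +
    (mm[, 3] - centerMm[3])^2
  which(dist2 <= radiusMm^2)
}

#' Simulate one 4D BOLD run with planted condition effects
#'
#' Forward model: for every template region, voxels inside the sphere gain
#' `amplitude x subjectAmplitude[condition] x` (HRF-convolved condition
#' regressor sampled at the TR grid). Noise is temporally AR(1), spatially
#' Gaussian-smoothed white noise, rescaled so its marginal standard
#' deviation equals `noise$sd`.
#'
#' @param labeled Labeled trials for **one run** (from [classifyTrials()]).
#' @param design A [TaskDesign-class].
#' @param grid An [AcquisitionGrid-class].
#' @param template An [EffectTemplate-class].
#' @param amplitudes Named numeric vector of per-condition subject
#'   amplitudes (signal units), e.g. `c(cC = 0.5, cI = 1, iC = 0.5, iI = 0.8)`.
#' @param noise List with `sd` (signal units), `ar1` (lag-1 coefficient) and
#'   `smoothFwhmMm`; default `list(sd = 1, ar1 = 0.3, smoothFwhmMm = 8)`.
#' @param hrf An [HRFSpec-class], default `hrfSpec()`.
#' @param seed Integer seed.
#' @return 4D array (x, y, z, volume), `volumesPerRun` volumes.
#' @export
simulateBoldRun <- function(labeled, design, grid, template, amplitudes,
                            noise = list(sd = 1, ar1 = 0.3, smoothFwhmMm = 8),
                            hrf = hrfSpec(), seed = 1) {
  stopifnot(is(design, "TaskDesign"), is(grid, "AcquisitionGrid"),
            is(template, "EffectTemplate"))
  run <- unique(labeled$run_index)
  if (length(run) != 1L)
    .fail("simulateBoldRun expects the trials of exactly one run")
  d <- grid@dims; nV <- design@volumesPerRun
  kernel <- canonicalHRF(hrf)
  trS <- design@trMs / 1000
  durS <- design@stimDurationMs / 1000
  vol <- array(0, c(d, nV))
  dim(vol) <- c(prod(d), nV)
  regs <- regions(template)
  for (ri in seq_len(nrow(regs))) {
    cond <- regs$condition[ri]
    vox <- .sphereVoxels(grid, c(regs$x[ri], regs$y[ri], regs$z[ri]),
                         regs$radius_mm[ri])
    if (!length(vox))
      .fail("template region '%s' lies entirely outside the grid", regs$name[ri])
    amp <- regs$amplitude[ri] *
      (if (cond %in% names(amplitudes)) amplitudes[[cond]] else 0)
    if (amp == 0) next
    on <- labeled$onset_ms[labeled$condition == cond] / 1000
    if (!length(on)) next
    reg <- .convolveEvents(on, durS, nV, trS, kernel, hrf@dtS)
    vol[vox, ] <- vol[vox, ] + amp * rep(reg, each = length(vox))
  }
  if (noise$sd > 0) {
    sk <- smoothingKernel(d, noise$smoothFwhmMm, grid@voxelSizeMm)
    eps <- withSeed(seed, {
      e <- array(stats::rnorm(prod(d) * nV), c(d, nV))
      if (noise$smoothFwhmMm > 0)
        for (tt in seq_len(nV))
          e[, , , tt] <- gaussianSmooth3D(e[, , , tt], noise$smoothFwhmMm,
                                          grid@voxelSizeMm, sk)
      e
    })
    dim(eps) <- c(prod(d), nV)
    if (noise$ar1 != 0)
      eps <- t(stats::filter(t(eps), noise$ar1, method = "recursive"))
    eps <- eps * (noise$sd / stats::sd(as.numeric(eps)))
    vol <- vol + eps
  }
  dim(vol) <- c(d, nV)
  vol
}
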