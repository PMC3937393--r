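#' Seed-sphere region definitions
#'
#' @param name Region label.
#' @param centerMm MNI mm coordinate, length 3.
#' @param radiusMm Sphere radius in mm, default 8.
#' @return A one-row data.frame (`name`, `x`, `y`, `z`, `radius_mm`).
#' @details `defaultROISet()` returns the anterior-cingulate seed
#'   (-6, 28, 31) and the four dorsolateral-prefrontal seeds at the
#'   reported activation foci (BA46 -48,30,16; BA44 -54,12,15;
#'   BA8 -46,10,40; BA45 -53,23,14), all 8 mm spheres.
#' @export
roiSpec <- function(name, centerMm, radiusMm = 8) {
  if (radiusMm <= 0) .fail("radiusMm must be positive")
  data.frame(name = name, x = centerMm[1], y = centerMm[2], z = centerMm[3],
             radius_mm = radiusMm)
}

#' @rdname roiSpec
#' @export
defaultROISet <- function() {
  rbind(
    roiSpec("ACC", c(-6, 28, 31)),
    roiSpec("DLPFC_BA46", c(-48, 30, 16)),
    roiSpec("DLPFC_BA44", c(-54, 12, 15)),
    roiSpec("DLPFC_BA8", c(-46, 10, 40)),
    roiSpec("DLPFC_BA45", c(-53, 23, 14)))
}

#' Extract the mean time series of a seed sphere
#'
#' Averages, per volume, all voxels whose centres lie within `radius_mm` of
#' the ROI centre (Euclidean distance in mm), then demeans per run.
#'
#' @param bold 4D array (x, y, z, volume) for one run.
#' @param roi One-row data.frame from [roiSpec()].
#' @param grid The [AcquisitionGrid-class].
#' @param demean Subtract the run mean, default TRUE.
#' @return Numeric vector, one value per volume; attribute `"n_voxels"`
#'   records the sphere size.
#' @export
extractROITimeseries <- function(bold, roi, grid, demean = TRUE) {
  vox <- .sphereVoxels(grid, c(roi$x, roi$y, roi$z), roi$radius_mm)
  if (!length(vox))
    .fail("ROI '%s' does not intersect the grid", roi$name)
  d <- dim(bold)
  m <- matrix(bold, prod(d[1:3]), d[4])
  ts_ <- colMeans(m[vox, , drop = FALSE])
  if (demean) ts_ <- ts_ - mean(ts_)
  attr(ts_, "n_voxels") <- length(vox)
  ts_
}

# remove mean and linear trend from a series
.detrend <- function(x) {
  t_ <- seq_along(x)
  stats::lm.fit(cbind(1, t_), x)$residuals
}

#' Granger Causality Index of series A on series B
#'
#' Fits, on the same T - p samples, the restricted autoregression of `B` on
#' its own `p` past values and the full autoregression adding the `p` past
#' values of `A` (both with intercept, ordinary least squares), and returns
#' `GCI = 1 - var(eAB) / var(eB)`: the proportional reduction in prediction
#' error variance of B when A's past is added. For nested in-sample OLS fits
#' the index lies in `[0, 1)`; a perfectly predictable B (zero full-model
#' residual variance) returns 1 with a flag.
#'
#' @param a,b Numeric series of equal length (the putative cause `a`).
#' @param order AR order p, default 1.
#' @param detrend Remove per-series mean and linear trend first, default TRUE.
#' @return List with `gci`, `varRestricted`, `varFull`, `order`, and
#'   `perfect` (TRUE when the full model is exact).
#' @export
#' @examples
#' set.seed(1)
#' a <- rnorm(140); b <- 0.6 * c(0, a[-140]) + rnorm(140)
#' grangerCausalityIndex(a, b)$gci > grangerCausalityIndex(b, a)$gci
grangerCausalityIndex <- function(a, b, order = 1L, detrend = TRUE) {
  p <- as.integer(order)
  T_ <- length(b)
  if (length(a) != T_) .fail("series must have equal length")
  if (T_ <= 2 * (2 * p + 1)) .fail("series too short for AR order %d", p)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    .fail("constant series: GCI undefined")
  if (detrend) { a <- .detrend(a); b <- .detrend(b) }
  y <- b[(p + 1):T_]
  lagMat <- function(x) sapply(seq_len(p), function(l) x[(p + 1 - l):(T_ - l)])
  Br <- cbind(1, lagMat(b))
  Bf <- cbind(Br, lagMat(a))
  er <- stats::lm.fit(Br, y)$residuals
  ef <- stats::lm.fit(Bf, y)$residuals
  vr <- mean(er^2); vf <- mean(ef^2)
  if (vr == 0) .fail("restricted model has zero residual variance")
  perfect <- vf < .Machine$double.eps * max(1, mean(y^2))
  list(gci = 1 - vf / vr, varRestricted = vr, varFull = vf, order = p,
       perfect = perfect)
}

#' Average GCI across runs for one subject
#'
#' Runs are fitted separately and the indices averaged; series are never
#' concatenated across run boundaries (which would create spurious lag
#' transitions).
#'
#' @param runsA,runsB Lists of per-run series for the cause and effect ROI.
#' @param order AR order, default 1.
#' @return Mean GCI across runs.
#' @export
gciAcrossRuns <- function(runsA, runsB, order = 1L) {
  stopifnot(length(runsA) == length(runsB))
  mean(vapply(seq_along(runsA), function(r)
    grangerCausalityIndex(runsA[[r]], runsB[[r]], order)$gci, numeric(1)))
}

# rank-sum z with tie correction (no continuity correction)
.rankSumZ <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  tieAdj <- sum(tapply(r, r, length)^3 - tapply(r, r, length))
  sig2 <- n1 * n2 / 12 * ((N + 1) - tieAdj / (N * (N - 1)))
  z <- (R1 - mu) / sqrt(sig2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Group statistics for per-subject Granger causality indices
#'
#' Within each group: one-sample t-test of the indices against zero, with
#' Bonferroni adjustment over `nTests` directed ROI pairs (default 8: four
#' pairs x two directions). Between groups: rank-sum statistic standardised
#' to a z value (tie-corrected) with its two-sided normal p.
#'
#' @param gci1,gci2 Per-subject GCI values for the two groups.
#' @param nTests Number of tests for the Bonferroni adjustment, default 8.
#' @return data.frame with per-group mean, SD, raw and Bonferroni p, and
#'   columns `z` and `p_between` for the group comparison.
#' @export
groupGCIStats <- function(gci1, gci2, nTests = 8) {
  if (length(gci1) < 2L || length(gci2) < 2L)
    .fail("each group needs at least two subjects")
  within <- function(g) {
    tt <- stats::t.test(g, mu = 0)
    c(mean = mean(g), sd = stats::sd(g), p = tt$p.value,
      p_bonferroni = min(1, tt$p.value * nTests))
  }
  w1 <- within(gci1); w2 <- within(gci2)
  rs <- .rankSumZ(gci1, gci2)
  data.frame(
    group = c("group1", "group2"),
    mean = c(w1["mean"], w2["mean"]), sd = c(w1["sd"], w2["sd"]),
    p = c(w1["p"], w2["p"]),
    p_bonferroni = c(w1["p_bonferroni"], w2["p_bonferroni"]),
    z = rs$z, p_between = rs$p, row.names = NULL)
}
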