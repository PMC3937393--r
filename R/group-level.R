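#' Covariate-adjusted two-sample test on subject contrast maps
#'
#' Per voxel, fits `contrast ~ intercept + group + covariates` by ordinary
#' least squares across subjects and returns the t statistic of the group
#' coefficient (group coded stutter = 1, control = 0, so positive t means
#' stutterers > controls); dof = n - p. Subjects missing a covariate are
#' dropped with a warning; collinear predictors are rejected.
#'
#' @param maps Subjects x voxels matrix of contrast estimates (rows aligned
#'   with `cohort` rows).
#' @param cohort Cohort data.frame; `group` plus the covariate columns.
#' @param covariates Character vector of cohort column names to adjust for;
#'   default `c("age_yr", "sex", "iq", "rt_interference_obs")`. `sex` is
#'   coded 0/1.
#' @param grid The [AcquisitionGrid-class] of the maps.
#' @return A [StatMap-class] of kind `"group_t"`.
#' @export
groupTTestCovariates <- function(maps, cohort,
                                 covariates = c("age_yr", "sex", "iq",
                                                "rt_interference_obs"),
                                 grid) {
  if (nrow(maps) != nrow(cohort))
    .fail("maps rows (%d) must match cohort rows (%d)", nrow(maps), nrow(cohort))
  X <- cbind(intercept = 1,
             group = as.numeric(cohort$group == "stutter"))
  for (cv in covariates) {
    if (!cv %in% names(cohort)) .fail("missing covariate column '%s'", cv)
    v <- cohort[[cv]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  keep <- stats::complete.cases(X)
  if (any(!keep)) {
    warning(sprintf("dropping %d subject(s) with missing covariates",
                    sum(!keep)))
    X <- X[keep, , drop = FALSE]; maps <- maps[keep, , drop = FALSE]
  }
  if (min(table(X[, "group"])) < 2L) .fail("need >= 2 subjects per group")
  tmap <- .lmTStat(X, maps, "group")
  statMap(array(tmap$t, grid@dims), dof = tmap$dof, kind = "group_t",
          grid = grid)
}

# vectorised OLS t statistic for one named coefficient; Y is n x voxels
.lmTStat <- function(X, Y, coefName) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    .fail("collinear predictors: %s",
          paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  dofv <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dofv
  XtXinv <- chol2inv(chol(crossprod(X)))
  cidx <- match(coefName, colnames(X))
  se <- sqrt(sigma2 * XtXinv[cidx, cidx])
  list(t = as.numeric(beta[cidx, ] / se), dof = dofv)
}

#' Voxelwise severity correlation within the stuttering group
#'
#' Pearson correlation, across stutterers, between each voxel's contrast
#' estimate and the severity z-score. Subjects with missing severity are
#' dropped (mirroring missing severity ratings in real cohorts). The raw
#' r map is returned; `adjust = TRUE` partials the default covariates out
#' of both sides first.
#'
#' @param maps Subjects x voxels matrix (stutterers only, aligned with
#'   `severity`).
#' @param severity Numeric severity z-scores, NA allowed (dropped).
#' @param grid The [AcquisitionGrid-class].
#' @param adjust Partial out covariates first (needs `cohort`), default FALSE.
#' @param cohort,covariates Used only when `adjust = TRUE`.
#' @return A [StatMap-class] of kind `"severity_r"` with dof = n - 2 (the
#'   dof of the t transform `t = r sqrt((n-2)/(1-r^2))`).
#' @export
severityCorrelation <- function(maps, severity, grid, adjust = FALSE,
                                cohort = NULL,
                                covariates = c("age_yr", "sex", "iq")) {
  keep <- !is.na(severity)
  if (sum(keep) < nrow(maps))
    message(sprintf("dropping %d subject(s) with missing severity",
                    sum(!keep)))
  maps <- maps[keep, , drop = FALSE]; severity <- severity[keep]
  if (stats::sd(severity) == 0) .fail("severity has zero variance")
  if (adjust) {
    if (is.null(cohort)) .fail("adjust = TRUE requires 'cohort'")
    Z <- cbind(1, as.matrix(
      data.frame(lapply(cohort[keep, covariates, drop = FALSE], function(v)
        if (is.character(v) || is.factor(v)) as.numeric(factor(v)) - 1 else v))))
    qrZ <- qr(Z)
    severity <- stats::lm.fit(Z, severity)$residuals
    maps <- maps - Z %*% qr.coef(qrZ, maps)
  }
  s <- scale(severity)[, 1]
  M <- scale(maps)
  M[is.na(M)] <- 0  # zero-variance voxels get r = 0
  r <- as.numeric(crossprod(M, s)) / (length(s) - 1)
  statMap(array(r, grid@dims), dof = length(s) - 2, kind = "severity_r",
          grid = grid)
}

# half-neighbourhood offsets for 6/18/26 connectivity (deduplicated)
.connOffsets <- function(connectivity) {
  o <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nn <- rowSums(abs(o))
  o <- switch(as.character(connectivity),
              "6" = o[nn == 1, , drop = FALSE],
              "18" = o[nn > 0 & nn <= 2, , drop = FALSE],
              "26" = o[nn > 0, , drop = FALSE],
              .fail("connectivity must be 6, 18 or 26"))
  keep <- o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0)))
  o[keep, , drop = FALSE]
}

#' Label connected suprathreshold components in a 3D volume
#'
#' Union-find labelling of the `TRUE` voxels of a logical array under 6-,
#' 18- or 26-neighbourhood connectivity.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 18).
#' @return A list with `labels` (integer array, 0 = background) and `sizes`
#'   (integer vector of component sizes, in label order).
#' @export
labelClusters <- function(mask, connectivity = 18) {
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, d)
  if (!length(idx)) return(list(labels = labels, sizes = integer(0)))
  offs <- .connOffsets(connectivity)
  n <- length(idx)
  lut <- integer(prod(d)); lut[idx] <- seq_len(n)
  co <- arrayInd(idx, d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (r in seq_len(nrow(offs))) {
    ni <- co[, 1] + offs[r, 1]; nj <- co[, 2] + offs[r, 2]
    nk <- co[, 3] + offs[r, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nidx <- (nk[ok] - 1L) * (d[1] * d[2]) + (nj[ok] - 1L) * d[1] + ni[ok]
    nb <- lut[nidx]
    src <- which(ok)[nb > 0L]; dst <- nb[nb > 0L]
    for (e in seq_along(src)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab <- match(roots, unique(roots))
  labels[idx] <- lab
  list(labels = labels, sizes = tabulate(lab))
}

#' Monte-Carlo cluster-extent threshold for familywise error control
#'
#' Simulates null statistic maps -- white Gaussian noise on the grid,
#' smoothed to `fwhmMm`, restricted to the mask and standardised -- applies
#' the two-sided voxelwise threshold `voxelP`, and records the maximum
#' suprathreshold cluster size per iteration. The extent threshold `kStar`
#' is the smallest cluster size whose exceedance probability under the null
#' is at most `alpha`.
#'
#' @param grid An [AcquisitionGrid-class].
#' @param mask Logical 3D array; default [brainMask()] of the grid.
#' @param voxelP Two-sided voxelwise p threshold, default 0.025.
#' @param alpha Familywise cluster-level alpha, default 0.05.
#' @param nIter Number of null iterations (>= 100), default 1000.
#' @param fwhmMm Gaussian smoothness of the null fields in mm, default 8.
#' @param connectivity Cluster connectivity, default 18.
#' @param seed Integer seed; the same seed reproduces `kStar`.
#' @return List with `kStar`, `nullMaxSizes` (length `nIter`), and the
#'   configuration.
#' @export
monteCarloClusterThreshold <- function(grid, mask = NULL, voxelP = 0.025,
                                       alpha = 0.05, nIter = 1000,
                                       fwhmMm = 8, connectivity = 18,
                                       seed = 1) {
  stopifnot(is(grid, "AcquisitionGrid"))
  if (voxelP <= 0 || voxelP >= 1 || alpha <= 0 || alpha >= 1)
    .fail("voxelP and alpha must lie in (0, 1)")
  if (nIter < 100) .fail("nIter must be >= 100")
  if (alpha < 1 / nIter)
    .fail("alpha below the 1/nIter resolution; increase nIter")
  if (is.null(mask)) mask <- brainMask(grid)
  if (!any(mask)) .fail("mask is empty")
  d <- grid@dims
  sk <- smoothingKernel(d, fwhmMm, grid@voxelSizeMm)
  thr <- stats::qnorm(1 - voxelP / 2)
  midx <- which(mask)
  mx <- withSeed(seed, {
    vapply(seq_len(nIter), function(it) {
      z <- array(stats::rnorm(prod(d)), d)
      if (fwhmMm > 0) z <- gaussianSmooth3D(z, fwhmMm, grid@voxelSizeMm, sk)
      v <- z[midx]
      v <- (v - mean(v)) / stats::sd(v)
      supra <- array(FALSE, d)
      supra[midx[abs(v) > thr]] <- TRUE
      cl <- labelClusters(supra, connectivity)
      if (length(cl$sizes)) max(cl$sizes) else 0L
    }, integer(1))
  })
  ks <- sort(unique(c(mx, max(mx) + 1L)))
  kStar <- min(ks[vapply(ks, function(k) mean(mx >= k) <= alpha, logical(1))])
  list(kStar = as.integer(kStar), nullMaxSizes = mx,
       config = list(voxelP = voxelP, alpha = alpha, nIter = nIter,
                     fwhmMm = fwhmMm, connectivity = connectivity,
                     maskVoxels = length(midx), seed = seed))
}

#' Corrected cluster table from a statistic map
#'
#' Thresholds the map at the two-sided voxelwise `voxelP` (Student t for
#' `group_t`/`contrast` maps, via the r-to-t transform for `severity_r`
#' maps), labels connected components separately for positive and negative
#' effects, keeps components of at least `kStar` voxels, and reports each
#' with its size, peak statistic and peak MNI coordinate.
#'
#' @param map A [StatMap-class].
#' @param voxelP Two-sided voxelwise p threshold, default 0.025.
#' @param kStar Extent threshold in voxels.
#' @param connectivity Cluster connectivity, default 18.
#' @param mask Optional logical array restricting the search.
#' @return data.frame with columns `kind`, `direction`, `size_vox`,
#'   `peak_x`, `peak_y`, `peak_z`, `peak_stat`; zero rows when nothing
#'   survives.
#' @export
clusterTable <- function(map, voxelP = 0.025, kStar = 30, connectivity = 18,
                         mask = NULL) {
  stopifnot(is(map, "StatMap"))
  stat <- map@statistic
  if (map@kind == "severity_r") {
    r <- pmin(pmax(stat, -0.999999), 0.999999)
    tstat <- r * sqrt(map@dof / (1 - r^2))
  } else tstat <- stat
  if (!is.null(mask)) tstat[!mask] <- 0
  tcrit <- stats::qt(1 - voxelP / 2, df = map@dof)
  rows <- list()
  for (dir in c("positive", "negative")) {
    supra <- if (dir == "positive") tstat > tcrit else tstat < -tcrit
    cl <- labelClusters(supra, connectivity)
    for (lab in which(cl$sizes >= kStar)) {
      vox <- which(cl$labels == lab)
      vals <- stat[vox]
      pk <- vox[which.max(abs(vals))]
      mm <- voxelToMm(map@grid, arrayInd(pk, dim(stat)))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = map@kind, direction = dir, size_vox = cl$sizes[lab],
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        peak_stat = stat[pk])
    }
  }
  if (!length(rows))
    return(data.frame(kind = character(), direction = character(),
                      size_vox = integer(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      peak_stat = numeric()))
  out <- do.call(rbind, rows)
  out[order(-out$size_vox), , drop = FALSE]
}
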