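#' Sample the canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; d1/s1, s1) - ratio * g(t; d2/s2, s2)`, where `g` is the gamma
#' density with shape `delay/dispersion` and scale `dispersion`. The kernel
#' is sampled on `[0, kernelLengthS]` at step `dtS` and normalised to unit
#' peak, so a regressor convolved with it carries amplitudes in signal units.
#'
#' @param spec An [HRFSpec-class]; default `hrfSpec()` (6, 16, 1, 1, 1/6, 32 s).
#' @return Numeric vector of kernel samples; attribute `"times"` holds the
#'   sample times in seconds.
#' @export
#' @examples
#' h <- canonicalHRF()
#' attr(h, "times")[which.max(h)]   # peak near 5 s
canonicalHRF <- function(spec = hrfSpec()) {
  stopifnot(is(spec, "HRFSpec"))
  validObject(spec)
  t <- seq(0, spec@kernelLengthS, by = spec@dtS)
  h <- stats::dgamma(t, shape = spec@peakDelayS / spec@peakDispersionS,
                     scale = spec@peakDispersionS) -
    spec@undershootRatio *
      stats::dgamma(t, shape = spec@undershootDelayS / spec@undershootDispersionS,
                    scale = spec@undershootDispersionS)
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

# HRF-convolved regressor for a set of events, sampled at volume times.
# onsets/durations in seconds; volumes at t = 0, TR, 2 TR, ...
.convolveEvents <- function(onsetsS, durationS, nVolumes, trS, hrf, dtS) {
  nHi <- ceiling(nVolumes * trS / dtS) + length(hrf)
  box <- numeric(nHi)
  for (o in onsetsS) {
    i0 <- floor(o / dtS) + 1L
    i1 <- min(nHi, floor((o + durationS) / dtS))
    if (i1 >= i0) box[i0:i1] <- box[i0:i1] + 1
  }
  conv <- stats::convolve(box, rev(hrf), type = "open") * dtS
  volIdx <- round(seq(0, by = trS, length.out = nVolumes) / dtS) + 1L
  conv[volIdx]
}

# Discrete-cosine high-pass basis: K = floor(2 * N * TR / cutoff) components
# (SPM convention, constant excluded).
.dctBasis <- function(nVolumes, trS, cutoffS) {
  K <- floor(2 * nVolumes * trS / cutoffS)
  if (K < 1L) return(matrix(numeric(0), nVolumes, 0))
  i <- seq_len(nVolumes) - 1L
  sapply(seq_len(K), function(k)
    cos(pi * (2 * i + 1) * k / (2 * nVolumes)))
}

#' Build a first-level design matrix
#'
#' Each condition (cC, cI, iC, iI, run_initial, nuisance) present in a run
#' contributes one regressor: a boxcar train at the stimulus onsets with the
#' stimulus duration, convolved with the canonical HRF and sampled at the
#' volume acquisition times. Runs are concatenated; condition regressors are
#' zero outside their run. Each run additionally receives a discrete-cosine
#' high-pass basis (periods >= `hpfCutoffS`) and a constant. Conditions with
#' no events in a run are omitted and recorded.
#'
#' @param labeled Labeled trial data.frame from [classifyTrials()].
#' @param design A [TaskDesign-class] (supplies TR, volumes and stimulus
#'   duration).
#' @param hrf An [HRFSpec-class], default `hrfSpec()`.
#' @param hpfCutoffS High-pass cutoff period in seconds, default 128.
#' @return A [DesignMatrix-class].
#' @export
buildDesignMatrix <- function(labeled, design, hrf = hrfSpec(),
                              hpfCutoffS = 128) {
  stopifnot(is(design, "TaskDesign"))
  kernel <- canonicalHRF(hrf)
  trS <- design@trMs / 1000
  nV <- design@volumesPerRun
  durS <- design@stimDurationMs / 1000
  conds <- c("cC", "cI", "iC", "iI", "run_initial", "nuisance")
  runs <- sort(unique(labeled$run_index))
  blocks <- list(); names_ <- character(); absent <- character()
  for (r in runs) {
    tr_ <- labeled[labeled$run_index == r, ]
    cols <- list()
    for (cc in conds) {
      on <- tr_$onset_ms[tr_$condition == cc] / 1000
      if (!length(on)) {
        if (cc %in% c("cC", "cI", "iC", "iI"))
          absent <- c(absent, sprintf("run%d_%s", r, cc))
        next
      }
      cols[[sprintf("run%d_%s", r, cc)]] <-
        .convolveEvents(on, durS, nV, trS, kernel, hrf@dtS)
    }
    dct <- .dctBasis(nV, trS, hpfCutoffS)
    if (ncol(dct))
      for (k in seq_len(ncol(dct)))
        cols[[sprintf("run%d_dct%d", r, k)]] <- dct[, k]
    cols[[sprintf("run%d_constant", r)]] <- rep(1, nV)
    blocks[[as.character(r)]] <- do.call(cbind, cols)
  }
  nTot <- length(runs) * nV
  allNames <- unlist(lapply(blocks, colnames))
  X <- matrix(0, nTot, length(allNames),
              dimnames = list(NULL, allNames))
  runIndex <- integer(nTot)
  for (bi in seq_along(runs)) {
    rows <- (bi - 1L) * nV + seq_len(nV)
    X[rows, colnames(blocks[[bi]])] <- blocks[[bi]]
    runIndex[rows] <- runs[bi]
  }
  new("DesignMatrix", values = X, trMs = design@trMs,
      hpfCutoffS = hpfCutoffS, runIndex = runIndex, absent = absent)
}

#' Fit per-voxel ordinary least squares
#'
#' @param bold 4D numeric array (x, y, z, volume) or a volumes x voxels
#'   matrix.
#' @param X A [DesignMatrix-class].
#' @param grid The [AcquisitionGrid-class] of the data (required when `bold`
#'   is a matrix; inferred from the array dimensions otherwise).
#' @return A [GLMFit-class] with betas (regressors x voxels), per-voxel
#'   residual variance and residual dof.
#' @export
fitGLM <- function(bold, X, grid = NULL) {
  stopifnot(is(X, "DesignMatrix"))
  if (length(dim(bold)) == 4L) {
    d <- dim(bold)
    if (is.null(grid)) grid <- acquisitionGrid(d[1:3])
    Y <- t(matrix(bold, prod(d[1:3]), d[4]))
  } else {
    if (is.null(grid)) .fail("grid is required when bold is a matrix")
    Y <- bold
  }
  Xm <- X@values
  if (nrow(Y) != nrow(Xm))
    .fail("volume count (%d) does not match design rows (%d)",
          nrow(Y), nrow(Xm))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrX$pivot[(qrX$rank + 1L):ncol(Xm)]]
    .fail("design matrix is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  resid <- Y - Xm %*% beta
  dof <- nrow(Xm) - qrX$rank
  residVar <- colSums(resid^2) / dof
  rownames(beta) <- colnames(Xm)
  new("GLMFit", beta = beta, residVar = as.numeric(residVar), dof = dof,
      grid = grid)
}

#' Contrast weights for the two effects of interest
#'
#' `conflict_resolution` is cI - cC (conflict after a low-conflict context);
#' `context_adaptation` is iI - cI (the Gratton effect). Weights are placed
#' on the per-run condition columns and averaged over the runs in which both
#' conditions are present.
#'
#' @param name `"conflict_resolution"` or `"context_adaptation"`, or a
#'   custom named condition-weight vector via `weights`.
#' @param weights Optional named numeric vector of condition weights (names
#'   among cC, cI, iC, iI), overriding `name`.
#' @return A named list with `name` and `weights`.
#' @export
contrastSpec <- function(name = c("conflict_resolution", "context_adaptation"),
                         weights = NULL) {
  if (is.null(weights)) {
    name <- match.arg(name)
    weights <- switch(name,
      conflict_resolution = c(cI = 1, cC = -1),
      context_adaptation = c(iI = 1, cI = -1))
  }
  list(name = if (is.character(name)) name[1] else "custom",
       weights = weights)
}

#' Compute a voxelwise contrast map from a GLM fit
#'
#' @param fit A [GLMFit-class].
#' @param spec A contrast from [contrastSpec()].
#' @return A [StatMap-class] of kind `"contrast"` holding the per-voxel
#'   contrast estimate (weighted sum of betas, averaged across runs).
#' @export
contrastMap <- function(fit, spec) {
  rn <- rownames(fit@beta)
  w <- numeric(length(rn)); names(w) <- rn
  for (cond in names(spec$weights)) {
    cols <- grep(sprintf("^run[0-9]+_%s$", cond), rn, value = TRUE)
    if (!length(cols))
      .fail("contrast '%s' references condition '%s' absent from the design",
            spec$name, cond)
    w[cols] <- spec$weights[[cond]] / length(cols)
  }
  est <- as.numeric(crossprod(fit@beta, w))
  statMap(array(est, fit@grid@dims), dof = fit@dof, kind = "contrast",
          grid = fit@grid)
}
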