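#' Default cohort parameters
#'
#' Covariate distributions follow the reported sample: stutterers age
#' 24.0 +/- 11.0 yr, controls 23.1 +/- 11.5 yr; WASI IQ 108.2 vs 115.5
#' (reported +/- values are standard errors; SDs are SEM * sqrt(N): 14.3 and
#' 15.1); 63% / 64% male; 22% of stutterers medicated, 5/46 with a comorbid
#' diagnosis. Behavioral parameters give a ~60 ms congruency interference
#' and a ~25 ms sequence-adaptation effect over a 40 ms trial-level noise
#' SD. BOLD effect amplitudes encode a conflict effect (cI > cC) and an
#' adaptation effect (iI < cI) shared by both groups; `groupDelta` (added to
#' the named conditions for stutterers) and `severityBeta` (coupling of the
#' stutterer cI amplitude to the severity z-score) default to 0.
#'
#' @return Named list of parameter lists (`covariates`, `behavior`,
#'   `effects`).
#' @export
defaultCohortParams <- function() {
  list(
    covariates = list(
      ageMean = c(stutter = 24.0, control = 23.1),
      ageSD = c(stutter = 11.0, control = 11.5),
      iqMean = c(stutter = 108.2, control = 115.5),
      iqSD = c(stutter = 14.3, control = 15.1),
      maleProp = c(stutter = 0.63, control = 0.64),
      medicatedProp = 0.22, comorbidProp = 5 / 46),
    behavior = list(
      rtBaseMean = 500, rtBaseSD = 60,
      rtInterferenceMean = 60, rtInterferenceSD = 15,
      rtAdaptationMean = 25, rtAdaptationSD = 10,
      rtNoiseSD = 40, errorRate = 0.05),
    effects = list(
      base = c(cC = 0.5, cI = 1.0, iC = 0.55, iI = 0.8),
      betweenSubjectSD = 0.25,
      groupDelta = c(cC = 0, cI = 0, iC = 0, iI = 0),
      severityBeta = 0))
}

#' Generate a two-group synthetic cohort with known ground truth
#'
#' Draws subject profiles (group, age, sex, IQ, medication, comorbidity,
#' behavioral parameters, per-condition BOLD amplitudes) for `nStutter`
#' stutterers and `nControl` fluent controls. Stutterers receive a standard
#' normal severity z-score (controls: missing); a nonzero `severityBeta` in
#' `params$effects` couples the stutterer cI amplitude to severity, and
#' `groupDelta` shifts stutterer amplitudes to plant group differences.
#' The cohort is a pure function of (parameters, seed), and each subject's
#' draws come from a subject-specific derived seed, so enlarging the cohort
#' leaves existing subjects unchanged.
#'
#' @param nStutter,nControl Group sizes; defaults 46 and 52.
#' @param params Parameter list as from [defaultCohortParams()]; partial
#'   lists are merged over the defaults.
#' @param seed Integer seed.
#' @return A data.frame of subject profiles with columns `subject_id`,
#'   `group`, `age_yr`, `sex`, `iq`, `severity_z`, `medicated`, `comorbid`,
#'   `rt_base_ms`, `rt_interference_ms`, `rt_adaptation_ms`,
#'   `rt_noise_sd_ms`, `error_rate`, `amp_cC`, `amp_cI`, `amp_iC`, `amp_iI`.
#' @export
#' @examples
#' coh <- generateCohort(46, 52, seed = 1)
#' table(coh$group); all(is.na(coh$severity_z[coh$group == "control"]))
generateCohort <- function(nStutter = 46L, nControl = 52L,
                           params = defaultCohortParams(), seed = 1) {
  if (nStutter < 1L || nControl < 1L) .fail("group sizes must be >= 1")
  def <- defaultCohortParams()
  for (top in names(def))
    for (nm in names(def[[top]]))
      if (is.null(params[[top]][[nm]])) params[[top]][[nm]] <- def[[top]][[nm]]
  cv <- params$covariates; bh <- params$behavior; ef <- params$effects
  groups <- rep(c("stutter", "control"), c(nStutter, nControl))
  one <- function(i) {
    g <- groups[i]
    withSeed(deriveSeed(seed, "cohort", i), {
      sev <- if (g == "stutter") stats::rnorm(1) else NA_real_
      amps <- ef$base + stats::rnorm(4, 0, ef$betweenSubjectSD)
      names(amps) <- names(ef$base)
      if (g == "stutter") {
        amps <- amps + ef$groupDelta[names(amps)]
        amps["cI"] <- amps["cI"] + ef$severityBeta * sev
      }
      data.frame(
        subject_id = sprintf("sub%03d", i), group = g,
        age_yr = max(5, stats::rnorm(1, cv$ageMean[[g]], cv$ageSD[[g]])),
        sex = if (stats::runif(1) < cv$maleProp[[g]]) "M" else "F",
        iq = stats::rnorm(1, cv$iqMean[[g]], cv$iqSD[[g]]),
        severity_z = sev,
        medicated = g == "stutter" && stats::runif(1) < cv$medicatedProp,
        comorbid = g == "stutter" && stats::runif(1) < cv$comorbidProp,
        rt_base_ms = max(250, stats::rnorm(1, bh$rtBaseMean, bh$rtBaseSD)),
        rt_interference_ms = stats::rnorm(1, bh$rtInterferenceMean,
                                          bh$rtInterferenceSD),
        rt_adaptation_ms = stats::rnorm(1, bh$rtAdaptationMean,
                                        bh$rtAdaptationSD),
        rt_noise_sd_ms = bh$rtNoiseSD, error_rate = bh$errorRate,
        amp_cC = amps[["cC"]], amp_cI = amps[["cI"]],
        amp_iC = amps[["iC"]], amp_iI = amps[["iI"]])
    })
  }
  out <- do.call(rbind, lapply(seq_along(groups), one))
  rownames(out) <- NULL
  out
}

#' Per-condition amplitude vector of one cohort row
#'
#' @param profile One row of the cohort data.frame.
#' @return Named numeric vector `c(cC, cI, iC, iI)`.
#' @export
subjectAmplitudes <- function(profile) {
  c(cC = profile$amp_cC, cI = profile$amp_cI,
    iC = profile$amp_iC, iI = profile$amp_iI)
}
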