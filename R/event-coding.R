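#' Flag reaction-time outliers
#'
#' Default rule: a trial is an outlier when its RT is below `floorMs`
#' (anticipatory response) or above the subject's mean plus `sdMult` standard
#' deviations, both computed over correct, non-omitted trials. With fewer
#' than three correct trials the ceiling rule is skipped (no stable SD) and
#' only the floor rule applies, with a warning.
#'
#' @param behavior Behavioral data.frame with `rt_ms`, `correct`, `omitted`.
#' @param floorMs Lower RT bound in ms, default 200.
#' @param sdMult Multiplier for the SD ceiling, default 3.
#' @return Logical vector of outlier flags, one per trial (FALSE for omitted
#'   trials, which carry no RT).
#' @export
flagRTOutliers <- function(behavior, floorMs = 200, sdMult = 3) {
  rt <- behavior$rt_ms
  use <- behavior$correct & !behavior$omitted & !is.na(rt)
  out <- rep(FALSE, nrow(behavior))
  out[!is.na(rt) & rt < floorMs] <- TRUE
  if (sum(use) >= 3) {
    ceiling_ <- mean(rt[use]) + sdMult * sd(rt[use])
    out[!is.na(rt) & rt > ceiling_] <- TRUE
  } else {
    warning("fewer than 3 correct trials: SD ceiling rule skipped")
  }
  out
}

#' Classify trials into sequence-dependent conditions
#'
#' Labels every trial with one of `cC`, `cI`, `iC`, `iI`, `run_initial` or
#' `nuisance`. The first letter encodes the congruency of the *preceding
#' stimulus* (c/i), the second the current stimulus (C/I). Incorrect,
#' omitted and RT-outlier trials become `nuisance`; the first trial of each
#' run becomes `run_initial`. Preceding congruency is taken from the
#' preceding stimulus regardless of whether that trial was answered
#' correctly: the stimulus, not the response, carries the conflict context.
#'
#' @param trials Trial data.frame (columns `run_index`, `congruent`, ...).
#' @param behavior Behavioral data.frame aligned row-by-row with `trials`
#'   (columns `rt_ms`, `correct`, `omitted`). May be the same data.frame.
#' @param outlierFloorMs,outlierSdMult Passed to [flagRTOutliers()].
#' @return The trials data.frame with behavioral columns plus `rt_outlier`
#'   and `condition` (factor).
#' @export
#' @examples
#' tr <- makeTrialSequence(taskDesign(nRuns = 1L), seed = 1)
#' p <- list(rt_base_ms = 500, rt_interference_ms = 60, rt_adaptation_ms = 25,
#'           rt_noise_sd_ms = 40, error_rate = 0)
#' lab <- classifyTrials(tr, simulateBehavior(tr, p, seed = 2))
#' table(lab$condition)
classifyTrials <- function(trials, behavior, outlierFloorMs = 200,
                           outlierSdMult = 3) {
  if (nrow(trials) != nrow(behavior))
    .fail("trials and behavior have different numbers of rows (%d vs %d)",
          nrow(trials), nrow(behavior))
  keyCols <- intersect(c("run_index", "trial_index"), names(behavior))
  for (k in keyCols) {
    bad <- which(trials[[k]] != behavior[[k]])
    if (length(bad))
      .fail("trials and behavior are misaligned at row %d (%s differs)",
            bad[1], k)
  }
  out <- trials
  for (col in c("rt_ms", "correct", "omitted", "rt_floored"))
    if (col %in% names(behavior)) out[[col]] <- behavior[[col]]
  out$rt_outlier <- flagRTOutliers(out, outlierFloorMs, outlierSdMult)
  n <- nrow(out)
  firstOfRun <- !duplicated(out$run_index)
  prevCongr <- c(NA, out$congruent[-n])
  cond <- ifelse(prevCongr, "c", "i")
  cond <- paste0(cond, ifelse(out$congruent, "C", "I"))
  cond[firstOfRun] <- "run_initial"
  bad <- !out$correct | out$omitted | out$rt_outlier
  cond[bad & !firstOfRun] <- "nuisance"
  out$condition <- factor(cond, levels = c("cC", "cI", "iC", "iI",
                                           "run_initial", "nuisance"))
  out
}

#' Per-subject behavioral summary and the RT-interference covariate
#'
#' @param labeled Labeled trial data.frame from [classifyTrials()].
#' @return A list with `cell_means` (named mean RT for cC/cI/iC/iI over
#'   correct non-nuisance trials), `accuracy` (named accuracy by current
#'   congruency), and `rt_interference_ms`.
#' @export
behavioralSummary <- function(labeled) {
  ok <- labeled$correct & !labeled$omitted & !labeled$rt_outlier
  cells <- c("cC", "cI", "iC", "iI")
  cm <- vapply(cells, function(cc)
    mean(labeled$rt_ms[ok & labeled$condition == cc]), numeric(1))
  acc <- c(congruent = mean(labeled$correct[labeled$congruent]),
           incongruent = mean(labeled$correct[!labeled$congruent]))
  list(cell_means = cm, accuracy = acc,
       rt_interference_ms = rtInterference(labeled))
}

#' RT interference: incongruent minus congruent mean reaction time
#'
#' Computed over all correct, non-omitted trials, grouped by the *current*
#' stimulus congruency.
#'
#' @param labeled Labeled (or at least behavioral) trial data.frame with
#'   columns `congruent`, `rt_ms`, `correct`, `omitted`.
#' @return RT interference in ms.
#' @export
rtInterference <- function(labeled) {
  ok <- labeled$correct & !labeled$omitted & !is.na(labeled$rt_ms)
  inc <- labeled$rt_ms[ok & !labeled$congruent]
  con <- labeled$rt_ms[ok & labeled$congruent]
  if (!length(inc) || !length(con))
    .fail("need at least one correct trial of each congruency")
  mean(inc) - mean(con)
}
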