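#' Generate a pseudorandom counterbalanced Simon-task trial sequence
#'
#' Produces, for each run, a pseudorandom ordering of congruent and
#' incongruent arrow trials with left/right direction counterbalanced within
#' each congruency class (counts differ by at most 1), uniform ISI jitter on
#' `[isiMinMs, isiMaxMs]`, and onsets spaced by stimulus duration plus ISI.
#' A trial is congruent when the arrow points toward the side of the screen
#' on which it appears.
#'
#' ISI draws are rejection-sampled so the realised trial train (including the
#' trailing fixation interval) fits inside the run; designs that cannot fit
#' even at minimal jitter are rejected with the index of the first
#' overflowing trial.
#'
#' @param design A [TaskDesign-class].
#' @param seed Integer seed; the same seed reproduces the identical sequence.
#' @return A data.frame of trials with columns `run_index`, `trial_index`,
#'   `onset_ms`, `direction`, `position`, `isi_ms`, `congruent`.
#' @export
#' @examples
#' tr <- makeTrialSequence(taskDesign(), seed = 1)
#' table(tr$run_index, tr$congruent)
makeTrialSequence <- function(design, seed) {
  stopifnot(is(design, "TaskDesign"))
  validObject(design)
  runMs <- design@trMs * design@volumesPerRun
  # infeasible even at minimal jitter: name the first trial that overflows
  offsets <- seq_len(design@trialsPerRun) *
    (design@stimDurationMs + design@isiMinMs)
  if (any(offsets > runMs)) {
    first <- which(offsets > runMs)[1]
    .fail("task does not fit in the run even at minimal ISI: trial %d ends at %.0f ms but the run lasts %.0f ms",
          first, offsets[first], runMs)
  }
  withSeed(seed, {
    out <- lapply(seq_len(design@nRuns), function(r)
      .makeRun(design, r, runMs))
    do.call(rbind, out)
  })
}

.makeRun <- function(design, runIndex, runMs) {
  nC <- design@nCongruentPerRun
  nI <- design@nIncongruentPerRun
  n <- nC + nI
  congr <- sample(rep(c(TRUE, FALSE), times = c(nC, nI)))
  # counterbalance direction within each congruency class (|L - R| <= 1)
  dirFor <- function(k) sample(rep(c("left", "right"),
                                   times = c(ceiling(k / 2), floor(k / 2))))
  direction <- character(n)
  direction[congr] <- dirFor(nC)
  direction[!congr] <- dirFor(nI)
  position <- ifelse(congr, direction,
                     ifelse(direction == "left", "right", "left"))
  # rejection-sample the jitter until the train (with trailing ISI) fits
  for (attempt in 1:1000) {
    isi <- runif(n, design@isiMinMs, design@isiMaxMs)
    total <- n * design@stimDurationMs + sum(isi)
    if (total <= runMs) break
    if (attempt == 1000)
      .fail("could not draw an ISI schedule that fits run %d", runIndex)
  }
  onset <- c(0, cumsum(design@stimDurationMs + isi))[seq_len(n)]
  data.frame(run_index = runIndex, trial_index = seq_len(n),
             onset_ms = onset, direction = direction, position = position,
             isi_ms = isi, congruent = congr)
}

#' Simulate button-press behavior for a trial sequence
#'
#' Reaction times follow an additive model:
#' `rt = base + interference * [incongruent] - adaptation * [incongruent and
#' previous incongruent] + N(0, noiseSd)`. Responses are incorrect with
#' probability `errorRate` and omitted with probability `omissionRate`,
#' independently per trial. Generated RTs below `rtFloorMs` are truncated to
#' the floor and flagged.
#'
#' @param trials Trial data.frame from [makeTrialSequence()].
#' @param profile A one-row data.frame (or list) with fields `rt_base_ms`,
#'   `rt_interference_ms`, `rt_adaptation_ms`, `rt_noise_sd_ms`, `error_rate`.
#' @param seed Integer seed.
#' @param omissionRate Probability a trial receives no response, default 0.
#' @param rtFloorMs Truncation floor for generated RTs, default 150 ms.
#' @return The trials data.frame with added columns `rt_ms` (NA when
#'   omitted), `correct` (FALSE when omitted), `omitted`, `rt_floored`.
#' @export
#' @examples
#' tr <- makeTrialSequence(taskDesign(nRuns = 1L), seed = 1)
#' p <- list(rt_base_ms = 500, rt_interference_ms = 60, rt_adaptation_ms = 25,
#'           rt_noise_sd_ms = 40, error_rate = 0.05)
#' b <- simulateBehavior(tr, p, seed = 2)
simulateBehavior <- function(trials, profile, seed, omissionRate = 0,
                             rtFloorMs = 150) {
  need <- c("rt_base_ms", "rt_interference_ms", "rt_adaptation_ms",
            "rt_noise_sd_ms", "error_rate")
  miss <- setdiff(need, names(profile))
  if (length(miss)) .fail("profile lacks fields: %s", paste(miss, collapse = ", "))
  if (profile$error_rate < 0 || profile$error_rate >= 1)
    .fail("error_rate must lie in [0, 1)")
  if (profile$rt_noise_sd_ms < 0) .fail("rt_noise_sd_ms must be >= 0")
  n <- nrow(trials)
  firstOfRun <- !duplicated(trials$run_index)
  prevIncong <- c(FALSE, !trials$congruent[-n]) & !firstOfRun
  withSeed(seed, {
    rt <- profile$rt_base_ms +
      profile$rt_interference_ms * as.numeric(!trials$congruent) -
      profile$rt_adaptation_ms * as.numeric(!trials$congruent & prevIncong) +
      rnorm(n, 0, profile$rt_noise_sd_ms)
    floored <- rt < rtFloorMs
    rt[floored] <- rtFloorMs
    correct <- runif(n) >= profile$error_rate
    omitted <- runif(n) < omissionRate
    rt[omitted] <- NA_real_
    correct[omitted] <- FALSE
    out <- trials
    out$rt_ms <- rt
    out$correct <- correct
    out$omitted <- omitted
    out$rt_floored <- floored & !omitted
    out
  })
}
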