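#' Default end-to-end pipeline configuration
#'
#' A desk-scale configuration: the full three-run task design, the
#' left-frontal 24 x 24 x 12 grid, the default effect template and ROI set,
#' and the reported group sizes (46 stutterers, 52 controls). `nRunsImaging`
#' controls how many of the task runs are simulated as BOLD (behavioral
#' analysis always uses all runs); the default 1 keeps a full-cohort run in
#' the minutes range.
#'
#' @param nStutter,nControl Group sizes.
#' @param nRunsImaging Runs simulated as BOLD per subject, default 1.
#' @return Nested configuration list understood by [runPipeline()].
#' @export
defaultPipelineConfig <- function(nStutter = 46L, nControl = 52L,
                                  nRunsImaging = 1L) {
  list(
    nStutter = nStutter, nControl = nControl,
    cohortParams = defaultCohortParams(),
    design = list(),                     # args to taskDesign()
    grid = list(dims = c(24L, 24L, 12L), voxelSizeMm = c(3.75, 3.75, 3.5),
                originMm = c(-20, 20, 25), trMs = 2200),
    template = regions(defaultEffectTemplate()),
    nRunsImaging = nRunsImaging,
    noise = list(sd = 1, ar1 = 0.3, smoothFwhmMm = 8),
    firstLevel = list(hpfCutoffS = 128, outlierFloorMs = 200,
                      outlierSdMult = 3),
    group = list(covariates = c("age_yr", "sex", "iq", "rt_interference_obs"),
                 voxelP = 0.025, alpha = 0.05, nIter = 1000,
                 connectivity = 18, fwhmMm = 8),
    roiSet = defaultROISet(),
    gciOrder = 1L)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Entries present in the file override the defaults from
#' [defaultPipelineConfig()]; `template` and `roiSet` may be given as lists
#' of records.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]) &&
        !is.data.frame(cfg[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  for (nm in c("template", "roiSet"))
    if (!is.data.frame(cfg[[nm]])) cfg[[nm]] <- do.call(rbind,
      lapply(cfg[[nm]], as.data.frame))
  cfg
}

# simulate + label + summarise one subject's behavior over the full design
.subjectBehavior <- function(profile, design, seed, i, firstLevel) {
  trials <- makeTrialSequence(design, deriveSeed(seed, "trials", i))
  beh <- simulateBehavior(trials, profile, deriveSeed(seed, "behavior", i))
  labeled <- classifyTrials(trials, beh, firstLevel$outlierFloorMs,
                            firstLevel$outlierSdMult)
  list(labeled = labeled, summary = behavioralSummary(labeled))
}

# simulate BOLD and compute both contrast maps for one subject
.subjectFirstLevel <- function(labeled, profile, design, grid, template,
                               noise, seed, i, nRunsImaging, hpfCutoffS) {
  dsub <- taskDesign(nRuns = nRunsImaging,
                     trialsPerRun = design@trialsPerRun,
                     nCongruentPerRun = design@nCongruentPerRun,
                     nIncongruentPerRun = design@nIncongruentPerRun,
                     stimDurationMs = design@stimDurationMs,
                     isiMinMs = design@isiMinMs, isiMaxMs = design@isiMaxMs,
                     trMs = design@trMs, volumesPerRun = design@volumesPerRun)
  sub <- labeled[labeled$run_index <= nRunsImaging, ]
  amps <- subjectAmplitudes(profile)
  runs <- sort(unique(sub$run_index))
  boldRuns <- lapply(runs, function(r)
    simulateBoldRun(sub[sub$run_index == r, ], dsub, grid, template, amps,
                    noise, seed = deriveSeed(seed, "bold", i * 100L + r)))
  bold <- array(unlist(boldRuns), c(gridDims(grid),
                                    length(runs) * dsub@volumesPerRun))
  X <- buildDesignMatrix(sub, dsub, hpfCutoffS = hpfCutoffS)
  fit <- fitGLM(bold, X, grid)
  list(
    conflict = statValues(contrastMap(fit, contrastSpec("conflict_resolution"))),
    adaptation = statValues(contrastMap(fit, contrastSpec("context_adaptation"))),
    boldRuns = boldRuns)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates the cohort, labels trials, runs the behavioral analysis
#' (mixed ANOVA, adaptation t-test, accuracy tests), simulates BOLD and fits
#' the first-level GLM per subject, performs covariate-adjusted group
#' inference with Monte-Carlo cluster-extent correction for both contrasts,
#' the severity correlation, and the seed-sphere Granger-causality analysis,
#' and writes all reports to `outDir`.
#'
#' @param config Configuration list from [defaultPipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outDir Output directory (created if needed).
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param writeNifti Also write group statistic maps as NIfTI-1, default TRUE.
#' @param verbose Print stage progress, default TRUE.
#' @return Invisibly, a list with `cohort`, `anova`, `adaptationT`,
#'   `accuracyT`, `groupMaps`, `clusterTables`, `severityMap`,
#'   `severityTable`, `gciReport`, `kStar` and `manifest`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir, seed = 1,
                        writeNifti = TRUE, verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  design <- do.call(taskDesign, config$design)
  grid <- acquisitionGrid(config$grid$dims, config$grid$voxelSizeMm,
                          config$grid$originMm, config$grid$trMs)
  template <- effectTemplate(config$template)

  say("cohort: %d + %d subjects", config$nStutter, config$nControl)
  cohort <- generateCohort(config$nStutter, config$nControl,
                           config$cohortParams, seed = seed)
  n <- nrow(cohort)

  say("behavior: %d subjects x %d runs", n, nRuns(design))
  beh <- lapply(seq_len(n), function(i)
    tryCatch(.subjectBehavior(cohort[i, ], design, seed, i, config$firstLevel),
             error = function(e) .fail("behavior stage failed for %s: %s",
                                       cohort$subject_id[i], conditionMessage(e))))
  cohort$rt_interference_obs <-
    vapply(beh, function(b) b$summary$rt_interference_ms, numeric(1))
  cellMeans <- data.frame(
    subject = cohort$subject_id, group = cohort$group,
    t(vapply(beh, function(b) b$summary$cell_means, numeric(4))))
  anova <- rmAnovaRT(cellMeans)
  adaptT <- pairedTTestAdaptation(cellMeans$cI, cellMeans$iI)
  accdf <- data.frame(group = cohort$group,
    congruent = vapply(beh, function(b) b$summary$accuracy[["congruent"]],
                       numeric(1)),
    incongruent = vapply(beh, function(b) b$summary$accuracy[["incongruent"]],
                         numeric(1)))
  accT <- accuracyGroupTest(accdf)

  say("first level: %d subjects, %d imaging run(s) each", n,
      config$nRunsImaging)
  nvox <- prod(gridDims(grid))
  conflict <- matrix(NA_real_, n, nvox)
  adaptation <- matrix(NA_real_, n, nvox)
  gciPairs <- NULL
  roiNames <- config$roiSet$name
  gciSubject <- list()
  for (i in seq_len(n)) {
    fl <- tryCatch(
      .subjectFirstLevel(beh[[i]]$labeled, cohort[i, ], design, grid,
                         template, config$noise, seed, i,
                         config$nRunsImaging, config$firstLevel$hpfCutoffS),
      error = function(e) .fail("first-level stage failed for %s: %s",
                                cohort$subject_id[i], conditionMessage(e)))
    conflict[i, ] <- fl$conflict
    adaptation[i, ] <- fl$adaptation
    # ROI series per run, then directed GCIs ACC <-> each DLPFC seed
    series <- lapply(fl$boldRuns, function(b)
      lapply(seq_len(nrow(config$roiSet)), function(rr)
        extractROITimeseries(b, config$roiSet[rr, ], grid)))
    # first ROI is the ACC seed; all others are paired against it
    g <- list()
    for (rr in seq(2, nrow(config$roiSet))) {
      A <- lapply(series, `[[`, 1); B <- lapply(series, `[[`, rr)
      g[[paste0(roiNames[1], "->", roiNames[rr])]] <-
        gciAcrossRuns(A, B, config$gciOrder)
      g[[paste0(roiNames[rr], "->", roiNames[1])]] <-
        gciAcrossRuns(B, A, config$gciOrder)
    }
    gciSubject[[i]] <- unlist(g)
  }
  gciMat <- do.call(rbind, gciSubject)

  say("group level: Monte-Carlo extent threshold (%d iterations)",
      config$group$nIter)
  mask <- brainMask(grid)
  mc <- monteCarloClusterThreshold(grid, mask, config$group$voxelP,
                                   config$group$alpha, config$group$nIter,
                                   config$group$fwhmMm,
                                   config$group$connectivity,
                                   seed = deriveSeed(seed, "mc"))
  groupMaps <- list(
    conflict_resolution = groupTTestCovariates(conflict, cohort,
                                               config$group$covariates, grid),
    context_adaptation = groupTTestCovariates(adaptation, cohort,
                                              config$group$covariates, grid))
  clusterTables <- lapply(groupMaps, clusterTable,
                          voxelP = config$group$voxelP, kStar = mc$kStar,
                          connectivity = config$group$connectivity,
                          mask = mask)
  stut <- cohort$group == "stutter"
  sevMap <- severityCorrelation(conflict[stut, , drop = FALSE],
                                cohort$severity_z[stut], grid)
  sevTable <- clusterTable(sevMap, config$group$voxelP, mc$kStar,
                           config$group$connectivity, mask)

  say("connectivity: group statistics for %d directed pairs", ncol(gciMat))
  gciReport <- do.call(rbind, lapply(colnames(gciMat), function(dir_) {
    st <- groupGCIStats(gciMat[stut, dir_], gciMat[!stut, dir_],
                        nTests = ncol(gciMat))
    data.frame(direction = dir_,
               stutter_mean = st$mean[1], stutter_sd = st$sd[1],
               stutter_p = st$p[1], stutter_p_bonf = st$p_bonferroni[1],
               control_mean = st$mean[2], control_sd = st$sd[2],
               control_p = st$p[2], control_p_bonf = st$p_bonferroni[2],
               z = st$z[1], p_between = st$p_between[1])
  }))

  # ---- outputs ----
  wt <- function(x, f) utils::write.table(x, file.path(outDir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  writeParticipantsTsv(cohort, file.path(outDir, "participants.tsv"))
  wt(anova, "behavior_anova.tsv")
  wt(data.frame(test = "iI_vs_cI_paired_t", t = adaptT$t, df = adaptT$df,
                p = adaptT$p), "behavior_adaptation_t.tsv")
  wt(accT, "behavior_accuracy_t.tsv")
  for (nm in names(clusterTables)) wt(clusterTables[[nm]],
                                      sprintf("clusters_%s.tsv", nm))
  wt(sevTable, "clusters_severity.tsv")
  wt(gciReport, "gci_report.tsv")
  jsonlite::write_json(
    list(kStar = mc$kStar, config = mc$config,
         nullQuantiles = as.list(stats::quantile(mc$nullMaxSizes,
                                                 c(.5, .9, .95, .99)))),
    file.path(outDir, "cluster_correction.json"), auto_unbox = TRUE)
  if (writeNifti)
    for (nm in names(groupMaps))
      writeBoldNifti(statValues(groupMaps[[nm]]), grid,
                     file.path(outDir, sprintf("group_t_%s.nii.gz", nm)))
  cfgTmp <- tempfile(); saveRDS(config, cfgTmp)
  manifest <- list(seed = seed, configMd5 = unname(tools::md5sum(cfgTmp)),
                   nSubjects = n, kStar = mc$kStar,
                   packageVersion =
                     as.character(utils::packageVersion("simonfmri")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  unlink(cfgTmp)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort = cohort, anova = anova, adaptationT = adaptT,
                 accuracyT = accT, conflictMaps = conflict,
                 adaptationMaps = adaptation, groupMaps = groupMaps,
                 clusterTables = clusterTables, severityMap = sevMap,
                 severityTable = sevTable, gciReport = gciReport,
                 kStar = mc$kStar, manifest = manifest))
}
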