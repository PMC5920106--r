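#' Assemble a pipeline configuration
#'
#' Bundles the simulation, preprocessing and analysis parameters of a full
#' run. Any field can be overridden from a YAML/JSON file via
#' \code{\link{readPipelineConfig}}.
#'
#' @param sim a \code{\link{SimConfig}}, or NULL when \code{epochsPath} points
#'   at previously written epoch containers.
#' @param epochsPath directory of per-subject epoch containers (alternative
#'   to \code{sim}).
#' @param threshold epoch-rejection threshold, microvolts.
#' @param filterLow,filterHigh,filterOrder ERP-branch Butterworth band.
#' @param splineM,splineLambda,splineNLegendre spherical-spline parameters.
#' @param interpolateBad channel labels to spherically interpolate.
#' @param p1Search (ms, ms) P1 search window relative to target.
#' @param p1Window P1 amplitude window width, ms.
#' @param erpBaseline (ms, ms) pre-target baseline for the ERP branch.
#' @param band (Hz, Hz) analysis band.
#' @param pretargetWindow (ms, ms) relative to target for the band average.
#' @param tfrBaseline (ms, ms) pre-cue percent-change baseline.
#' @param restrictBand decompose only band frequencies and ROI channels
#'   (cuts memory/time; set FALSE for full time-frequency maps).
#' @param nPerm cluster-test permutations.
#' @param nBoot bootstrap draws.
#' @param alpha significance level.
#' @param seed seed for the resampling stages.
#' @param outDir optional output directory; when set, intermediates and the
#'   report are persisted there.
#' @param verbose print per-stage progress lines.
#' @return a list of class "pipelineConfig".
#' @export
pipelineConfig <- function(sim = simConfig(), epochsPath = NULL,
                           threshold = 75, filterLow = 0.05, filterHigh = 25,
                           filterOrder = 1, splineM = 4, splineLambda = 1e-5,
                           splineNLegendre = 50, interpolateBad = character(),
                           p1Search = c(70, 150), p1Window = 30,
                           erpBaseline = c(-200, 0), band = c(8, 14),
                           pretargetWindow = c(-500, 0),
                           tfrBaseline = c(-400, -100), restrictBand = TRUE,
                           nPerm = 10000, nBoot = 20000, alpha = 0.05,
                           seed = 1, outDir = NULL, verbose = FALSE) {
  cfg <- list(sim = sim, epochsPath = epochsPath, threshold = threshold,
              filterLow = filterLow, filterHigh = filterHigh,
              filterOrder = filterOrder, splineM = splineM,
              splineLambda = splineLambda,
              splineNLegendre = splineNLegendre,
              interpolateBad = interpolateBad, p1Search = p1Search,
              p1Window = p1Window, erpBaseline = erpBaseline, band = band,
              pretargetWindow = pretargetWindow, tfrBaseline = tfrBaseline,
              restrictBand = restrictBand, nPerm = nPerm, nBoot = nBoot,
              alpha = alpha, seed = seed, outDir = outDir, verbose = verbose)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys \code{sim}, \code{preprocess} and \code{analysis} hold the
#' generator fields (by \code{\link{simConfig}} argument name), the
#' preprocessing fields and the analysis fields; all are optional and
#' unspecified values keep their defaults.
#'
#' @param path a .yaml/.yml or .json file.
#' @return a "pipelineConfig" list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  simArgs <- raw$sim
  if (!is.null(simArgs)) {
    known <- names(formals(simConfig))
    bad <- setdiff(names(simArgs), known)
    if (length(bad)) stop("unknown sim fields: ", paste(bad, collapse = ", "))
    sim <- do.call(simConfig, simArgs)
  } else sim <- simConfig()
  args <- c(raw$preprocess, raw$analysis,
            raw[setdiff(names(raw), c("sim", "preprocess", "analysis"))])
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, c(list(sim = sim), args))
}

.stageLog <- function(verbose, stage, subject, msg) {
  if (verbose)
    message(sprintf("[%s] subject %s: %s", stage, subject, msg))
}

.configHash <- function(cfg) {
  ser <- jsonlite::serializeJSON(cfg[setdiff(names(cfg),
                                             c("outDir", "verbose"))])
  f <- tempfile(); on.exit(unlink(f))
  writeLines(ser, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, then per subject: amplitude-threshold
#' rejection, optional channel interpolation, surface Laplacian, and two
#' branches -- a filtered/baselined ERP branch feeding grand-average and
#' single-trial P1 quantification, and an unfiltered spectral branch feeding
#' Morlet power, percent change and the alpha-band time course. Across
#' subjects: cluster-corrected permutation tests of the pre-target band time
#' course (left and right), 2x2 repeated-measures ANOVAs (condition x
#' hemisphere) for mean pre-target alpha and P1 amplitude, paired t simple
#' effects, and Spearman/bootstrap correlation of the per-subject alpha and
#' P1 condition effects. Deterministic given the config (including seeds).
#'
#' @param config a "pipelineConfig" (see \code{\link{pipelineConfig}}) or a
#'   path to a YAML/JSON config file.
#' @return a list of class "runReport"; see the package vignette.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  verbose <- isTRUE(config$verbose)

  if (!is.null(config$epochsPath)) {
    dirs <- list.dirs(config$epochsPath, recursive = FALSE)
    if (!length(dirs)) stop("no epoch containers under ", config$epochsPath)
    cohort <- list(epochs = lapply(dirs, readEpochs), truth = NULL)
  } else {
    cohort <- generateCohort(config$sim)
  }
  nSub <- length(cohort$epochs)
  mon <- montage(cohort$epochs[[1L]])
  grp <- channelGroups(mon)
  if (!all(c("leftPosterior", "rightPosterior") %in% names(grp)))
    stop("montage must define leftPosterior and rightPosterior groups")
  hemis <- c("leftPosterior", "rightPosterior")
  roi <- unlist(grp[hemis], use.names = FALSE)

  family <- buildWaveletFamily(sampleRate = sampleRate(cohort$epochs[[1L]]))
  bandFreqs <- family@frequencies[family@frequencies >= config$band[1L] &
                                    family@frequencies <= config$band[2L]]
  conds <- c("trained", "untrained")

  trialCounts <- data.frame(subject = integer(), before = integer(),
                            after = integer())
  rejLogs <- list()
  erpWaves <- list()    # [[subj]][[hemi]][[cond]] data.frame
  bandTCs <- list()     # [[subj]][[hemi]][[cond]] numeric time course
  peakTables <- list()
  tcTime <- NULL

  for (s in seq_len(nSub)) {
    ep <- cohort$epochs[[s]]
    subj <- unique(trialInfo(ep)$subject)[1L]
    nBefore <- nTrials(ep)
    rej <- tryCatch(rejectEpochs(ep, config$threshold),
                    error = function(e)
                      stop("stage reject, subject ", subj, ": ",
                           conditionMessage(e), call. = FALSE))
    .stageLog(verbose, "reject", subj,
              sprintf("%d -> %d trials", nBefore, nTrials(rej$epochs)))
    rejLogs[[s]] <- rej$log
    ep <- rej$epochs
    trialCounts <- rbind(trialCounts,
                         data.frame(subject = subj, before = nBefore,
                                    after = nTrials(ep)))
    if (length(config$interpolateBad))
      ep <- interpolateChannels(ep, config$interpolateBad, config$splineM,
                                config$splineLambda, config$splineNLegendre)
    ep <- applyLaplacian(ep, config$splineM, config$splineLambda,
                         config$splineNLegendre)

    # ERP branch: filtered, pre-target baselined
    erp <- bandpassFilter(ep, config$filterLow, config$filterHigh,
                          config$filterOrder)
    erp <- baselineSubtract(erp, config$erpBaseline, reference = "target")
    erpWaves[[s]] <- lapply(setNames(hemis, hemis), function(h)
      lapply(setNames(conds, conds), function(cc) averageErp(erp, h, cc)))
    peakTables[[s]] <- do.call(rbind, lapply(hemis, function(h) {
      tab <- singleTrialPeaks(erp, h, config$p1Search)
      tab$hemisphere <- h
      tab
    }))

    # spectral branch: unfiltered
    tfr <- tfDecompose(ep, family,
                     channels = if (config$restrictBand) roi else NULL,
                     frequencies = if (config$restrictBand) bandFreqs else NULL)
    tfr <- percentChange(tfr, config$tfrBaseline, scope = "common")
    cueWin <- config$pretargetWindow + targetTime(ep)
    bandTCs[[s]] <- lapply(setNames(hemis, hemis), function(h) {
      tc <- bandTimecourse(tfr, config$band, grp[[h]])
      idx <- .timeIndex(tfrTime(tfr), cueWin)
      fSel <- which(tfr@frequencies >= config$band[1L] &
                      tfr@frequencies <= config$band[2L])
      if (any(tfr@edgeFlags[fSel, idx]))
        stop("pre-target window overlaps edge-flagged samples; enlarge epoch")
      sel <- trialInfo(ep)$condition
      out <- lapply(setNames(conds, conds), function(cc)
        colMeans(tc[sel == cc, idx, drop = FALSE]))
      out
    })
    if (is.null(tcTime)) tcTime <- tfrTime(tfr)[.timeIndex(tfrTime(tfr),
                                                           cueWin)] -
        targetTime(ep)
    .stageLog(verbose, "spectral", subj, "band time course done")
  }

  # grand-average P1 peak per hemisphere (conditions pooled)
  tt <- targetTime(cohort$epochs[[1L]])
  grand <- lapply(setNames(hemis, hemis), function(h) {
    amp <- Reduce(`+`, lapply(seq_len(nSub), function(s)
      (erpWaves[[s]][[h]]$trained$amplitude +
         erpWaves[[s]][[h]]$untrained$amplitude) / 2)) / nSub
    data.frame(time_ms = erpWaves[[1L]][[h]]$trained$time_ms, amplitude = amp)
  })
  peakLat <- vapply(hemis, function(h)
    findGrandPeak(grand[[h]], config$p1Search, tt), numeric(1))

  # per-subject window amplitudes (mean of the condition waveform in the
  # 30 ms window centered on that hemisphere's grand-average peak)
  winAmp <- expand.grid(subject = seq_len(nSub), hemisphere = hemis,
                        condition = conds, stringsAsFactors = FALSE)
  winAmp$amplitude <- mapply(function(s, h, cc) {
    wf <- erpWaves[[s]][[h]][[cc]]
    win <- peakLat[[h]] + c(-1, 1) * config$p1Window / 2 + tt
    mean(wf$amplitude[.timeIndex(wf$time_ms, win)])
  }, winAmp$subject, winAmp$hemisphere, winAmp$condition)

  # cluster tests on the pre-target band time course, per hemisphere
  clusterRes <- lapply(setNames(hemis, hemis), function(h) {
    A <- do.call(rbind, lapply(bandTCs, function(x) x[[h]]$trained))
    B <- do.call(rbind, lapply(bandTCs, function(x) x[[h]]$untrained))
    clusterPermutationPaired(A, B, nPerm = config$nPerm,
                             alpha = config$alpha, seed = config$seed,
                             time = tcTime)
  })

  # subject effect table: pre-target alpha and P1 modulations per hemisphere
  effectTable <- do.call(rbind, lapply(seq_len(nSub), function(s) {
    do.call(rbind, lapply(hemis, function(h) {
      aT <- mean(bandTCs[[s]][[h]]$trained)
      aU <- mean(bandTCs[[s]][[h]]$untrained)
      pT <- winAmp$amplitude[winAmp$subject == s & winAmp$hemisphere == h &
                               winAmp$condition == "trained"]
      pU <- winAmp$amplitude[winAmp$subject == s & winAmp$hemisphere == h &
                               winAmp$condition == "untrained"]
      data.frame(subject = s, hemisphere = h, alphaTrained = aT,
                 alphaUntrained = aU, alphaMod = aT - aU,
                 p1Trained = pT, p1Untrained = pU, p1Mod = pT - pU)
    }))
  }))

  # 2x2 RM-ANOVAs (condition x hemisphere) and paired-t simple effects
  mkAnova <- function(valueCol) {
    long <- rbind(
      data.frame(subject = effectTable$subject, A = "trained",
                 B = effectTable$hemisphere,
                 value = effectTable[[paste0(valueCol, "Trained")]]),
      data.frame(subject = effectTable$subject, A = "untrained",
                 B = effectTable$hemisphere,
                 value = effectTable[[paste0(valueCol, "Untrained")]]))
    rmAnova2x2(long)
  }
  anovaAlpha <- mkAnova("alpha")
  anovaP1 <- mkAnova("p1")
  simpleEffects <- do.call(rbind, lapply(hemis, function(h) {
    sub <- effectTable[effectTable$hemisphere == h, ]
    tA <- pairedT(sub$alphaTrained, sub$alphaUntrained)
    tP <- pairedT(sub$p1Trained, sub$p1Untrained)
    data.frame(hemisphere = h, measure = c("alpha", "p1"),
               t = c(tA$t, tP$t), df = c(tA$df, tP$df), p = c(tA$p, tP$p))
  }))

  # across-subject correlation of the two condition effects
  modL <- effectTable[effectTable$hemisphere == "leftPosterior", ]
  modR <- effectTable[effectTable$hemisphere == "rightPosterior", ]
  corr <- list(
    left = spearmanBootstrap(modL$alphaMod, modL$p1Mod, config$nBoot,
                             seed = config$seed),
    right = spearmanBootstrap(modR$alphaMod, modR$p1Mod, config$nBoot,
                              seed = config$seed))
  corrDiff <- correlationDifference(modL$alphaMod, modL$p1Mod, modR$p1Mod,
                                    config$nBoot, seed = config$seed)
  corr$left$boot <- NULL; corr$right$boot <- NULL; corrDiff$boot <- NULL

  truthBlock <- NULL
  if (!is.null(cohort$truth)) {
    truthBlock <- list(
      truth = cohort$truth,
      alphaModVsTruth = .spearman(cohort$truth$true_alpha_effect,
                                  modL$alphaMod),
      p1ModVsTruth = .spearman(cohort$truth$true_p1_effect, modL$p1Mod))
  }

  report <- list(
    configHash = .configHash(config),
    seed = config$seed,
    nSubjects = nSub,
    trialCounts = trialCounts,
    rejectionLog = do.call(rbind, rejLogs),
    grandAverage = grand,
    p1PeakLatency = peakLat,
    p1Window = lapply(peakLat, function(p) p + c(-1, 1) * config$p1Window / 2),
    windowAmplitudes = winAmp,
    singleTrialPeaks = do.call(rbind, peakTables),
    bandTimecourseTime = tcTime,
    bandTimecourses = do.call(rbind, lapply(seq_len(nSub), function(s)
      do.call(rbind, lapply(hemis, function(h)
        do.call(rbind, lapply(conds, function(cc)
          data.frame(subject = s, hemisphere = h, condition = cc,
                     time_ms = tcTime,
                     value = bandTCs[[s]][[h]][[cc]]))))))),
    clusterTests = clusterRes,
    anovaAlpha = anovaAlpha,
    anovaP1 = anovaP1,
    simpleEffects = simpleEffects,
    effectTable = effectTable,
    correlations = corr,
    correlationDifference = corrDiff,
    groundTruth = truthBlock)
  class(report) <- "runReport"
  if (!is.null(config$outDir)) writeRunReport(report, config$outDir)
  report
}

#' @export
print.runReport <- function(x, ...) {
  cat("== alphaP1 run report ==\n")
  cat(sprintf("subjects: %d   config hash: %s\n", x$nSubjects, x$configHash))
  cat(sprintf("P1 grand-average peak: left %g ms, right %g ms\n",
              x$p1PeakLatency[["leftPosterior"]],
              x$p1PeakLatency[["rightPosterior"]]))
  for (h in names(x$clusterTests)) {
    cl <- clusters(x$clusterTests[[h]])
    sig <- cl[cl$significant, , drop = FALSE]
    cat(sprintf("%s: %d significant cluster(s)%s\n", h, nrow(sig),
                if (nrow(sig)) paste0(" [",
                  paste(sprintf("%g..%g ms (p=%.4g)", sig$start_ms,
                                sig$end_ms, sig$p), collapse = "; "), "]")
                else ""))
  }
  cat("simple effects (paired t):\n")
  print(x$simpleEffects, row.names = FALSE)
  cat(sprintf("alpha-P1 correlation: left rho=%.3f (p=%.3g, CI %.2f..%.2f), right rho=%.3f (p=%.3g)\n",
              x$correlations$left$rho, x$correlations$left$p,
              x$correlations$left$ci[1L], x$correlations$left$ci[2L],
              x$correlations$right$rho, x$correlations$right$p))
  cat(sprintf("correlation difference: %.3f (CI %.2f..%.2f, p=%.3g)\n",
              x$correlationDifference$deltaRho,
              x$correlationDifference$ci[1L], x$correlationDifference$ci[2L],
              x$correlationDifference$p))
  invisible(x)
}

#' Persist the tabular parts of a run report
#'
#' Writes CSV tables (rejection log, window amplitudes, single-trial peaks,
#' subject effect table, ground truth when simulated) and a JSON summary
#' (clusters, ANOVA tables, correlations, seeds, config hash).
#'
#' @param report a "runReport".
#' @param dir output directory (created if needed).
#' @return dir, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(report$rejectionLog, "rejection_log.csv")
  wcsv(report$bandTimecourses, "band_timecourses.csv")
  ga <- do.call(rbind, lapply(names(report$grandAverage), function(h)
    data.frame(hemisphere = h, report$grandAverage[[h]])))
  wcsv(ga, "grand_average_erp.csv")
  wcsv(report$windowAmplitudes, "p1_window_amplitudes.csv")
  wcsv(report$singleTrialPeaks, "single_trial_peaks.csv")
  wcsv(report$effectTable, "subject_effects.csv")
  if (!is.null(report$groundTruth))
    wcsv(report$groundTruth$truth, "ground_truth.csv")
  summ <- list(
    configHash = report$configHash, seed = report$seed,
    nSubjects = report$nSubjects, p1PeakLatency = as.list(report$p1PeakLatency),
    clusters = lapply(report$clusterTests, function(ct)
      list(threshold = ct@threshold, null95 = ct@null95, nPerm = ct@nPerm,
           exact = ct@exact, clusters = clusters(ct))),
    anovaAlpha = report$anovaAlpha, anovaP1 = report$anovaP1,
    simpleEffects = report$simpleEffects,
    correlations = report$correlations,
    correlationDifference = report$correlationDifference)
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
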