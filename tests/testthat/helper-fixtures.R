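# shared fixtures: the scaled-down study conditions used across the suite
# (10-channel posterior montage, 250 Hz, short epochs around the cue-target
# interval). The vignette documents these problem sizes.

roiMontage <- function() {
  mon <- standardMontage()
  roi <- unlist(posteriorGroups(), use.names = FALSE)
  idx <- match(roi, channelLabels(mon))
  Montage(channelLabels(mon)[idx], channelPositions(mon)[idx, ],
          posteriorGroups())
}

scaledSimConfig <- function(seed = 1, ...) {
  args <- list(nSubjects = 16, trialsPerCondition = 20, sampleRate = 250,
               epochSpan = c(750, 400), seed = seed, montage = roiMontage())
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}

# a tiny noise-free single-subject set with a known P1, for ERP tests
p1OnlyConfig <- function(seed = 1, sampleRate = 500, p1BaseAmp = 1, ...) {
  scaledSimConfig(seed = seed, nSubjects = 1, trialsPerCondition = 3,
                  sampleRate = sampleRate, noiseScale = 0, alphaBaseAmp = 0,
                  alphaBackgroundAmp = 0, p1BaseAmp = p1BaseAmp, p1Effect = 0,
                  p1EffectSD = 0, alphaEffect = 0, alphaEffectSD = 0, ...)
}

# per-subject condition-mean alpha band time courses over the pre-target
# window, computed through the spectral branch of the pipeline
spectralBandTimecourses <- function(cohort, pretarget = c(-500, 0),
                                    band = c(8, 14)) {
  fam <- buildWaveletFamily(sampleRate = sampleRate(cohort$epochs[[1L]]))
  bandF <- fam@frequencies[fam@frequencies >= band[1L] &
                             fam@frequencies <= band[2L]]
  grp <- posteriorGroups()
  lapply(cohort$epochs, function(ep) {
    ep <- rejectEpochs(ep, 75)$epochs
    ep <- applyLaplacian(ep)
    tfr <- tfDecompose(ep, fam, channels = unlist(grp), frequencies = bandF)
    tfr <- percentChange(tfr, c(-400, -100))
    cueWin <- pretarget + targetTime(ep)
    cond <- trialInfo(ep)$condition
    idx <- which(tfrTime(tfr) >= cueWin[1L] & tfrTime(tfr) <= cueWin[2L])
    out <- lapply(grp, function(g) {
      tc <- bandTimecourse(tfr, band, g)
      list(trained = colMeans(tc[cond == "trained", idx, drop = FALSE]),
           untrained = colMeans(tc[cond == "untrained", idx, drop = FALSE]))
    })
    out$time <- tfrTime(tfr)[idx] - targetTime(ep)
    out
  })
}

clusterTestFromTCs <- function(tcs, hemi, nPerm = 1000, seed = 1) {
  A <- do.call(rbind, lapply(tcs, function(x) x[[hemi]]$trained))
  B <- do.call(rbind, lapply(tcs, function(x) x[[hemi]]$untrained))
  clusterPermutationPaired(A, B, nPerm = nPerm, seed = seed,
                           time = tcs[[1L]]$time)
}
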