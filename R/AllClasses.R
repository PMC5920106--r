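#' @import methods
NULL

#' Electrode montage with named channel groups
#'
#' A \code{Montage} holds extended 10--20 channel labels, their 3-D positions
#' on the unit sphere, and named channel groups (by default the left and right
#' occipito-parietal clusters used for both the P1 and the alpha analyses).
#'
#' @slot labels character vector of channel labels.
#' @slot positions numeric matrix (channels x 3) of unit-norm positions;
#'   rows are named by channel.
#' @slot groups named list of character vectors; each element is a channel
#'   group (e.g. \code{leftPosterior}, \code{rightPosterior}).
#' @export
setClass("Montage",
  representation(labels = "character", positions = "matrix", groups = "list"))

setValidity("Montage", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate channel labels")
  if (!is.numeric(object@positions) || ncol(object@positions) != 3L ||
      nrow(object@positions) != n)
    msg <- c(msg, "positions must be a numeric channels x 3 matrix")
  else {
    nrm <- sqrt(rowSums(object@positions^2))
    if (any(abs(nrm - 1) > 1e-4))
      msg <- c(msg, "positions must have unit norm")
  }
  for (g in names(object@groups)) {
    if (!all(object@groups[[g]] %in% object@labels))
      msg <- c(msg, sprintf("group '%s' names channels absent from montage", g))
  }
  if (length(object@groups) >= 2L) {
    all_members <- unlist(object@groups, use.names = FALSE)
    if (anyDuplicated(all_members))
      msg <- c(msg, "channel groups must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Epoched multichannel EEG
#'
#' The central container: a trials x channels x samples tensor with sampling
#' metadata, a per-trial label table, a montage, and a unit tag that flips
#' from microvolts to microvolts per square centimetre exactly once, when the
#' surface Laplacian is applied.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot sampleRate sampling rate in Hz.
#' @slot time numeric vector of sample times in ms relative to cue onset.
#' @slot targetTime target onset time in ms relative to cue onset.
#' @slot trials data.frame with one row per trial: \code{subject},
#'   \code{condition} ("trained"/"untrained"), \code{trialType}, \code{kept}.
#' @slot montage a \code{\link{Montage}}.
#' @slot units "uV" before the Laplacian, "uV.cm2" after.
#' @export
setClass("EpochSet",
  representation(data = "array", sampleRate = "numeric", time = "numeric",
                 targetTime = "numeric", trials = "data.frame",
                 montage = "Montage", units = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array (trials x channels x samples)")
  if (d[2L] != length(object@montage@labels))
    msg <- c(msg, "channel dimension does not match montage")
  if (d[3L] != length(object@time))
    msg <- c(msg, "sample dimension does not match time axis")
  if (d[1L] != nrow(object@trials))
    msg <- c(msg, "trial dimension does not match trial table")
  if (length(object@time) >= 2L) {
    dt <- diff(object@time)
    step <- 1000 / object@sampleRate
    if (any(dt <= 0)) msg <- c(msg, "time axis must be strictly increasing")
    else if (any(abs(dt - step) > 1e-6 * step))
      msg <- c(msg, "time axis must be uniform with step 1000/sampleRate")
  }
  if (!object@units %in% c("uV", "uV.cm2"))
    msg <- c(msg, "units must be 'uV' or 'uV.cm2'")
  if (!all(c("subject", "condition", "kept") %in% names(object@trials)))
    msg <- c(msg, "trial table needs columns subject, condition, kept")
  if (length(msg)) msg else TRUE
})

#' Morlet wavelet family
#'
#' Complex Morlet kernels on a uniform frequency grid with a linearly
#' increasing cycle count. Kernels are odd-length, centered, unit-energy, and
#' truncated where the Gaussian envelope falls below 1e-4 of its maximum.
#'
#' @slot frequencies center frequencies in Hz (uniform grid).
#' @slot cycles cycles per wavelet, affine along the frequency list.
#' @slot sampleRate sampling rate in Hz.
#' @slot kernels list of complex vectors, one per frequency.
#' @export
setClass("WaveletFamily",
  representation(frequencies = "numeric", cycles = "numeric",
                 sampleRate = "numeric", kernels = "list"))

setValidity("WaveletFamily", function(object) {
  msg <- character()
  f <- object@frequencies
  if (length(f) != length(object@cycles) || length(f) != length(object@kernels))
    msg <- c(msg, "frequencies, cycles and kernels must have equal length")
  if (length(f) >= 2L) {
    st <- diff(f)
    if (any(st <= 0) || any(abs(st - st[1L]) > 1e-9))
      msg <- c(msg, "frequencies must be strictly increasing on a uniform grid")
  }
  if (any(lengths(object@kernels) %% 2L == 0L))
    msg <- c(msg, "kernels must be odd-length")
  en <- vapply(object@kernels, function(k) sum(Mod(k)^2), numeric(1))
  if (any(abs(en - 1) > 1e-6))
    msg <- c(msg, "kernels must be unit-energy")
  if (length(msg)) msg else TRUE
})

#' Time-frequency power
#'
#' Power tensor (trials x channels x frequencies x times) in raw signal-squared
#' units or percent signal change relative to a pre-cue baseline. Samples whose
#' wavelet support extends past the epoch edge are flagged per frequency.
#'
#' @slot power numeric 4-d array (trials x channels x frequencies x times).
#' @slot channels character, channel labels of dimension 2.
#' @slot frequencies numeric, Hz.
#' @slot time numeric, ms relative to cue onset.
#' @slot units "raw" or "pct".
#' @slot baseline numeric length-2 baseline window (ms relative to cue) when
#'   units are "pct"; \code{NA} otherwise.
#' @slot edgeFlags logical matrix (frequencies x times), TRUE where the kernel
#'   overhangs the epoch edge.
#' @export
setClass("TFRPower",
  representation(power = "array", channels = "character",
                 frequencies = "numeric", time = "numeric", units = "character",
                 baseline = "numeric", edgeFlags = "matrix"))

setValidity("TFRPower", function(object) {
  msg <- character()
  d <- dim(object@power)
  if (length(d) != 4L) return("power must be a 4-d array")
  if (d[2L] != length(object@channels)) msg <- c(msg, "channel dim mismatch")
  if (d[3L] != length(object@frequencies)) msg <- c(msg, "frequency dim mismatch")
  if (d[4L] != length(object@time)) msg <- c(msg, "time dim mismatch")
  if (!object@units %in% c("raw", "pct")) msg <- c(msg, "units must be 'raw' or 'pct'")
  if (object@units == "raw" && any(object@power < 0, na.rm = TRUE))
    msg <- c(msg, "raw power must be non-negative")
  if (!all(dim(object@edgeFlags) == d[3:4]))
    msg <- c(msg, "edgeFlags must be frequencies x times")
  if (length(msg)) msg else TRUE
})

#' Cluster-corrected paired permutation test result
#'
#' Per-timepoint paired t statistics, maximal supra-threshold runs (clusters),
#' and the permutation null distribution of maximum cluster sizes.
#'
#' @slot tStat per-timepoint paired t statistic.
#' @slot time time axis in ms.
#' @slot threshold cluster-forming t threshold (two-tailed critical value).
#' @slot clusters data.frame: start_ms, end_ms, size, sign, p, significant.
#' @slot nullSizes integer vector of per-permutation maximum run lengths.
#' @slot null95 95th percentile of \code{nullSizes}.
#' @slot nPerm number of permutations used.
#' @slot exact TRUE when all sign flips were enumerated.
#' @export
setClass("ClusterTestResult",
  representation(tStat = "numeric", time = "numeric", threshold = "numeric",
                 clusters = "data.frame", nullSizes = "numeric",
                 null95 = "numeric", nPerm = "numeric", exact = "logical"))

setValidity("ClusterTestResult", function(object) {
  if (length(object@tStat) != length(object@time))
    return("tStat and time must align")
  TRUE
})

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-EEG generator: epoch geometry, 1/f background
#' noise, an ongoing posterior alpha oscillation whose pre-target amplitude is
#' elevated on meaning-trained trials, a target-locked P1 deflection whose
#' amplitude is elevated on meaning-trained trials, the across-subject
#' correlation between the two condition effects, and artifact injection.
#'
#' See \code{\link{simConfig}} for field semantics and defaults.
#'
#' @export
setClass("SimConfig",
  representation(
    nSubjects = "numeric", trialsPerCondition = "numeric",
    sampleRate = "numeric", epochSpan = "numeric", cueToTarget = "numeric",
    noiseExponent = "numeric", noiseScale = "numeric",
    spatialMixing = "numeric",
    alphaFreq = "numeric", alphaBaseAmp = "numeric",
    alphaBackgroundAmp = "numeric", alphaBackgroundTopography = "numeric",
    alphaEffect = "numeric", alphaEffectSD = "numeric",
    alphaEffectWindow = "numeric", alphaTopography = "numeric",
    p1Latency = "numeric", p1Width = "numeric", p1BaseAmp = "numeric",
    p1Effect = "numeric", p1EffectSD = "numeric", p1Topography = "numeric",
    effectCorr = "numeric", artifactRate = "numeric", cueResponse = "logical",
    seed = "numeric", montage = "Montage"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1 || object@trialsPerCondition < 1)
    msg <- c(msg, "counts must be >= 1")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (length(object@epochSpan) != 2L || any(object@epochSpan <= 0))
    msg <- c(msg, "epochSpan must give positive (ms before cue, ms after target)")
  w <- object@alphaEffectWindow
  if (length(w) != 2L || w[1L] >= w[2L])
    msg <- c(msg, "alphaEffectWindow must be an increasing (ms, ms) pair")
  else if (w[2L] > 0 || w[1L] < -(object@epochSpan[1L] + object@cueToTarget))
    msg <- c(msg, "alphaEffectWindow must lie within the pre-target epoch")
  if (object@spatialMixing < 0)
    msg <- c(msg, "spatialMixing must be >= 0")
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must be in [0, 1]")
  if (abs(object@effectCorr) > 1) msg <- c(msg, "effectCorr must be in [-1, 1]")
  if (object@alphaFreq < 8 || object@alphaFreq > 14)
    msg <- c(msg, "alphaFreq must lie in the 8-14 Hz band")
  nch <- length(object@montage@labels)
  if (length(object@alphaTopography) != nch ||
      length(object@p1Topography) != nch ||
      length(object@alphaBackgroundTopography) != nch)
    msg <- c(msg, "topography gain vectors must have one entry per channel")
  if (length(msg)) msg else TRUE
})
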