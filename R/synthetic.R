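#' Configure the synthetic-EEG generator
#'
#' Builds a \code{\link{SimConfig}} describing a cohort of epoched EEG with
#' known injected effects: 1/f ("pink") background noise, an ongoing posterior
#' alpha oscillation whose amplitude is raised on meaning-trained trials inside
#' a pre-target window, a target-locked Gaussian P1 deflection whose amplitude
#' is raised on meaning-trained trials, and a configurable across-subject
#' correlation between the per-subject alpha and P1 condition effects.
#'
#' Per-subject effect sizes are drawn from a bivariate normal distribution
#' with means \code{alphaEffect}/\code{p1Effect}, standard deviations
#' \code{alphaEffectSD}/\code{p1EffectSD} and correlation \code{effectCorr}.
#'
#' @param nSubjects number of subjects in the cohort.
#' @param trialsPerCondition trials per meaning condition per subject.
#' @param sampleRate sampling rate, Hz.
#' @param epochSpan c(ms before cue onset, ms after target onset), positive.
#' @param cueToTarget cue-to-target interval in ms (150 ms cue + 167 ms mask
#'   + 700 ms blank = 1017 ms).
#' @param noiseExponent spectral slope beta of the 1/f^beta background.
#' @param noiseScale background noise RMS per channel, microvolts.
#' @param spatialMixing angular scale (radians) of inter-channel noise
#'   correlation: per-sample noise is mixed across channels with a Gaussian
#'   great-circle kernel of this width (rows renormalized so the per-channel
#'   RMS stays \code{noiseScale}). 0 disables mixing. Scalp EEG background is
#'   spatially coherent; without mixing the surface Laplacian would treat the
#'   background as implausibly focal.
#' @param alphaFreq alpha frequency in Hz; must lie in 8-14.
#' @param alphaBaseAmp amplitude (microvolts) of the modulated, left-posterior
#'   alpha source carrying the condition effect.
#' @param alphaBackgroundAmp amplitude (microvolts) of an ongoing bilateral
#'   posterior alpha rhythm with no condition dependence. Posterior alpha is
#'   bilateral in real recordings; its presence also keeps the Laplacian
#'   surround of the left source from dominating right-channel band power.
#' @param alphaBackgroundTopography per-channel gain of the background
#'   rhythm; default a broad bilateral occipito-parietal field.
#' @param alphaEffect mean fractional pre-target alpha-amplitude increase on
#'   meaning-trained trials.
#' @param alphaEffectSD across-subject SD of the alpha effect.
#' @param alphaEffectWindow (ms, ms) relative to target onset in which the
#'   alpha effect applies; edges are ramped with a 50 ms cosine taper.
#' @param alphaTopography per-channel gain of the alpha source; default a
#'   smooth gain field concentrated on the left posterior cluster.
#' @param p1Latency P1 peak latency, ms post-target.
#' @param p1Width Gaussian SD of the P1 deflection, ms.
#' @param p1BaseAmp P1 amplitude on meaning-untrained trials, microvolts.
#' @param p1Effect mean additive P1 amplitude increase on trained trials.
#' @param p1EffectSD across-subject SD of the P1 effect.
#' @param p1Topography per-channel gain of the P1 source; default a smooth
#'   bilateral occipito-parietal field.
#' @param effectCorr target across-subject correlation between the alpha and
#'   P1 effects, in [-1, 1].
#' @param artifactRate per-epoch probability of an injected high-amplitude
#'   transient (200 ms, +/-100 microvolt square pulse).
#' @param cueResponse also add a cue-locked P1-like deflection (no condition
#'   effect); off by default.
#' @param seed RNG seed for the cohort.
#' @param montage the \code{\link{Montage}} to simulate.
#' @return a validated \code{\link{SimConfig}}.
#' @export
simConfig <- function(nSubjects = 16, trialsPerCondition = 20,
                      sampleRate = 500, epochSpan = c(1500, 1500),
                      cueToTarget = 1017, noiseExponent = 1, noiseScale = 10,
                      spatialMixing = 0.5,
                      alphaFreq = 10, alphaBaseAmp = 4,
                      alphaBackgroundAmp = 10,
                      alphaBackgroundTopography = NULL,
                      alphaEffect = 0.5, alphaEffectSD = 0.35,
                      alphaEffectWindow = c(-480, -250),
                      alphaTopography = NULL,
                      p1Latency = 115, p1Width = 15, p1BaseAmp = 4,
                      p1Effect = 1.2, p1EffectSD = 0.5, p1Topography = NULL,
                      effectCorr = 0, artifactRate = 0, cueResponse = FALSE,
                      seed = 1, montage = standardMontage()) {
  if (length(alphaEffectWindow) != 2L ||
      alphaEffectWindow[1L] >= alphaEffectWindow[2L])
    stop("alphaEffectWindow must be an increasing (ms, ms) pair")
  if (is.null(alphaTopography)) {
    # focal left-posterior source; gains below 2% are zeroed so channels far
    # from the source carry none of the (multiplicative) condition effect
    alphaTopography <- .gaussianTopography(montage, "leftPosterior",
                                           sigma = 0.35)
    alphaTopography[alphaTopography < 0.02] <- 0
  }
  if (is.null(p1Topography))
    p1Topography <- pmax(
      .gaussianTopography(montage, "leftPosterior", sigma = 0.6),
      .gaussianTopography(montage, "rightPosterior", sigma = 0.6))
  if (is.null(alphaBackgroundTopography))
    alphaBackgroundTopography <- pmax(
      .gaussianTopography(montage, "leftPosterior", sigma = 0.6),
      .gaussianTopography(montage, "rightPosterior", sigma = 0.6))
  new("SimConfig", nSubjects = nSubjects,
      trialsPerCondition = trialsPerCondition, sampleRate = sampleRate,
      epochSpan = epochSpan, cueToTarget = cueToTarget,
      noiseExponent = noiseExponent, noiseScale = noiseScale,
      spatialMixing = spatialMixing,
      alphaFreq = alphaFreq, alphaBaseAmp = alphaBaseAmp,
      alphaBackgroundAmp = alphaBackgroundAmp,
      alphaBackgroundTopography = alphaBackgroundTopography,
      alphaEffect = alphaEffect, alphaEffectSD = alphaEffectSD,
      alphaEffectWindow = alphaEffectWindow,
      alphaTopography = alphaTopography, p1Latency = p1Latency,
      p1Width = p1Width, p1BaseAmp = p1BaseAmp, p1Effect = p1Effect,
      p1EffectSD = p1EffectSD, p1Topography = p1Topography,
      effectCorr = effectCorr, artifactRate = artifactRate,
      cueResponse = cueResponse, seed = seed, montage = montage)
}

#' Smooth Gaussian gain field on the scalp
#'
#' Unit-peak gain that falls off as a Gaussian in great-circle angle from the
#' centroid of a montage channel group; useful for building source
#' topographies for the generator.
#'
#' @param montage a \code{\link{Montage}}.
#' @param group group name whose centroid anchors the field.
#' @param sigma angular width in radians.
#' @param floor gains below this are set exactly to zero (0 keeps all).
#' @return named per-channel gain vector.
#' @export
gaussianTopography <- function(montage, group, sigma = 0.5, floor = 0) {
  g <- .gaussianTopography(montage, group, sigma)
  g[g < floor] <- 0
  g
}

# smooth unit-peak gain field: Gaussian in great-circle angle from the
# centroid of a montage group (or of all channels if the group is absent)
.gaussianTopography <- function(montage, group, sigma = 0.5) {
  pos <- channelPositions(montage)
  if (group %in% names(channelGroups(montage))) {
    idx <- .resolveGroup(montage, group)
  } else idx <- seq_len(nrow(pos))
  ctr <- colMeans(pos[idx, , drop = FALSE])
  ctr <- ctr / sqrt(sum(ctr^2))
  ang <- acos(pmin(1, pmax(-1, drop(pos %*% ctr))))
  g <- exp(-ang^2 / (2 * sigma^2))
  names(g) <- channelLabels(montage)
  g
}

# purpose codes for the per-subject RNG streams
.STREAM <- c(noise = 1L, effects = 2L, artifacts = 3L)

.subjectSeed <- function(seed, subjectIndex, purpose) {
  as.integer((abs(seed) * 48271 + subjectIndex * 9973 +
                .STREAM[[purpose]]) %% 2147483629)
}

# N x M matrix of 1/f^beta noise columns with RMS `scale`, generated by
# spectrum-shaping white Gaussian noise; shaped at the next power-of-two
# length (fast mixed-radix FFT) and truncated to n
.pinkNoiseMatrix <- function(n, m, beta, scale) {
  if (scale == 0) return(matrix(0, n, m))
  if (beta == 0) return(matrix(stats::rnorm(n * m), n, m) * scale)
  nfft <- 2^ceiling(log2(n))
  w <- matrix(stats::rnorm(nfft * m), nfft, m)
  fw <- stats::mvfft(w)
  k <- seq_len(nfft) - 1L
  f <- pmin(k, nfft - k)       # folded frequency index (cycles per record)
  s <- c(0, f[-1L]^(-beta / 2))
  y <- Re(stats::mvfft(fw * s, inverse = TRUE)) / nfft
  y[seq_len(n), , drop = FALSE] * scale / sqrt(sum(s^2) / nfft)
}

# cosine-tapered indicator of [w1, w2] ms with `ramp` ms edges
.taperedWindow <- function(time, window, ramp = 50) {
  w <- numeric(length(time))
  core <- time >= window[1L] & time <= window[2L]
  w[core] <- 1
  up <- time > window[1L] - ramp & time < window[1L]
  w[up] <- 0.5 * (1 - cos(pi * (time[up] - (window[1L] - ramp)) / ramp))
  dn <- time > window[2L] & time < window[2L] + ramp
  w[dn] <- 0.5 * (1 + cos(pi * (time[dn] - window[2L]) / ramp))
  w
}

#' Draw a subject's true condition effects
#'
#' Deterministic given (config seed, subject index): the per-subject alpha and
#' P1 effects come from the subject's own "effects" RNG stream so that the
#' same subject can be regenerated in isolation.
#'
#' @param config a \code{\link{SimConfig}}.
#' @param subjectIndex subject number (1-based).
#' @return list with \code{alpha} and \code{p1} effect values.
#' @export
subjectEffects <- function(config, subjectIndex) {
  set.seed(.subjectSeed(config@seed, subjectIndex, "effects"))
  z <- stats::rnorm(2)
  rho <- config@effectCorr
  list(alpha = config@alphaEffect + config@alphaEffectSD * z[1L],
       p1 = config@p1Effect +
         config@p1EffectSD * (rho * z[1L] + sqrt(1 - rho^2) * z[2L]))
}

#' Generate one subject's epoched EEG
#'
#' Each epoch is the sum of 1/f^beta background noise, an ongoing alpha
#' oscillation with random per-trial phase (amplitude raised by the subject's
#' alpha effect on trained trials inside the tapered effect window), a
#' target-locked Gaussian P1 deflection (amplitude raised by the subject's P1
#' effect on trained trials), and optional square-pulse artifacts. The result
#' is deterministic given (config seed, subject index).
#'
#' @param config a \code{\link{SimConfig}}.
#' @param subjectIndex subject number (1-based, <= nSubjects).
#' @param effects optional list(alpha=, p1=) of true effects; when NULL they
#'   are drawn via \code{\link{subjectEffects}}.
#' @return an \code{\link{EpochSet}} (units microvolts) whose trial table
#'   carries the condition labels and injected-artifact flags.
#' @export
generateSubject <- function(config, subjectIndex, effects = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (subjectIndex < 1 || subjectIndex > config@nSubjects)
    stop("subjectIndex out of range")
  if (is.null(effects)) effects <- subjectEffects(config, subjectIndex)

  fs <- config@sampleRate
  dt <- 1000 / fs
  tTarget <- config@cueToTarget
  time <- seq(-config@epochSpan[1L], tTarget + config@epochSpan[2L], by = dt)
  n <- length(time)
  nch <- length(config@montage@labels)
  ntr <- 2L * config@trialsPerCondition
  cond <- rep(c("trained", "untrained"), times = config@trialsPerCondition)
  ttype <- rep_len(c("identical", "same-object-different-location",
                     "different-object"), ntr)

  # noise stream: pink background + per-trial alpha phases
  set.seed(.subjectSeed(config@seed, subjectIndex, "noise"))
  noise <- .pinkNoiseMatrix(n, ntr * nch, config@noiseExponent,
                            config@noiseScale)
  phases <- stats::runif(ntr, 0, 2 * pi)
  phasesBg <- stats::runif(ntr, 0, 2 * pi)
  mixK <- NULL
  if (config@spatialMixing > 0 && nch > 1L) {
    pos <- channelPositions(config@montage)
    cosang <- tcrossprod(pos)
    cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
    K <- exp(-acos(cosang)^2 / (2 * config@spatialMixing^2))
    mixK <- K / sqrt(rowSums(K^2))      # per-channel RMS preserved
  }

  # condition-dependent alpha envelope and P1 template
  w <- .taperedWindow(time, config@alphaEffectWindow + tTarget, ramp = 50)
  gaussP1 <- exp(-(time - (tTarget + config@p1Latency))^2 /
                   (2 * config@p1Width^2))
  cueP1 <- if (config@cueResponse)
    exp(-(time - config@p1Latency)^2 / (2 * config@p1Width^2)) else NULL

  data <- array(0, dim = c(ntr, nch, n))
  topoA <- config@alphaTopography
  topoP <- config@p1Topography
  for (tr in seq_len(ntr)) {
    trained <- cond[tr] == "trained"
    ampA <- config@alphaBaseAmp *
      (1 + (if (trained) effects$alpha else 0) * w)
    sig <- ampA * sin(2 * pi * config@alphaFreq * time / 1000 + phases[tr])
    sigBg <- config@alphaBackgroundAmp *
      sin(2 * pi * config@alphaFreq * time / 1000 + phasesBg[tr])
    ampP <- config@p1BaseAmp + if (trained) effects$p1 else 0
    sig2 <- ampP * gaussP1
    if (!is.null(cueP1)) sig2 <- sig2 + config@p1BaseAmp * cueP1
    cols <- (tr - 1L) * nch + seq_len(nch)
    ntr_noise <- if (is.null(mixK)) t(noise[, cols])
                 else mixK %*% t(noise[, cols])
    data[tr, , ] <- ntr_noise + outer(topoA, sig) +
      outer(config@alphaBackgroundTopography, sigBg) + outer(topoP, sig2)
  }

  # artifact stream: 200 ms +/-100 uV square pulses
  artifact <- rep(FALSE, ntr)
  if (config@artifactRate > 0) {
    set.seed(.subjectSeed(config@seed, subjectIndex, "artifacts"))
    hit <- stats::runif(ntr) < config@artifactRate
    durSamp <- max(1L, round(200 / dt))
    for (tr in which(hit)) {
      ch <- sample.int(nch, 1L)
      start <- sample.int(max(1L, n - durSamp), 1L)
      sgn <- sample(c(-1, 1), 1L)
      data[tr, ch, start:(start + durSamp - 1L)] <-
        data[tr, ch, start:(start + durSamp - 1L)] + sgn * 100
      artifact[tr] <- TRUE
    }
  }

  trials <- data.frame(subject = subjectIndex, condition = cond,
                       trialType = ttype, kept = TRUE, artifact = artifact,
                       stringsAsFactors = FALSE)
  EpochSet(data, fs, time, tTarget, trials, config@montage, units = "uV")
}

#' Generate a cohort with ground truth
#'
#' Draws per-subject alpha and P1 effects from a bivariate normal with
#' correlation \code{effectCorr}, generates each subject's epochs, and records
#' the true draws.
#'
#' @param config a \code{\link{SimConfig}}.
#' @return list with \code{epochs} (list of \code{\link{EpochSet}}) and
#'   \code{truth} (data.frame: subject, true_alpha_effect, true_p1_effect,
#'   seed).
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  eff <- lapply(seq_len(config@nSubjects),
                function(i) subjectEffects(config, i))
  epochs <- lapply(seq_len(config@nSubjects), function(i)
    generateSubject(config, i, effects = eff[[i]]))
  truth <- data.frame(
    subject = seq_len(config@nSubjects),
    true_alpha_effect = vapply(eff, `[[`, numeric(1), "alpha"),
    true_p1_effect = vapply(eff, `[[`, numeric(1), "p1"),
    seed = config@seed)
  list(epochs = epochs, truth = truth)
}
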