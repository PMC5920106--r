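#' Build a Morlet wavelet family
#'
#' Complex Morlet kernels on a uniform frequency grid (default 3-50 Hz in
#' 1.6 Hz steps, i.e. 30 centers 3.0, 4.6, ..., 49.4) with the cycle count
#' increasing linearly along the list from 3 at the lowest to 10 at the
#' highest frequency. Kernels are centered, odd-length, truncated where the
#' Gaussian envelope falls below 1e-4 of its maximum, and unit-energy
#' normalized (any fixed normalization cancels in percent change).
#'
#' @param fmin,fmax,step frequency grid in Hz.
#' @param cyclesRange c(cycles at fmin, cycles at fmax).
#' @param sampleRate sampling rate in Hz; must exceed 2*fmax.
#' @return a \code{\link{WaveletFamily}}.
#' @export
buildWaveletFamily <- function(fmin = 3, fmax = 50, step = 1.6,
                               cyclesRange = c(3, 10), sampleRate = 500) {
  freqs <- seq(fmin, fmax, by = step)
  if (sampleRate <= 2 * max(freqs))
    stop("sampling rate must exceed twice the maximum frequency")
  cycles <- seq(cyclesRange[1L], cyclesRange[2L], length.out = length(freqs))
  kernels <- mapply(function(f, nc) {
    sigma <- nc / (2 * pi * f)                       # seconds
    half <- ceiling(sigma * sqrt(-2 * log(1e-4)) * sampleRate)
    t <- (-half:half) / sampleRate
    env <- exp(-t^2 / (2 * sigma^2))
    k <- env * exp(2i * pi * f * t)
    k / sqrt(sum(Mod(k)^2))
  }, freqs, cycles, SIMPLIFY = FALSE)
  new("WaveletFamily", frequencies = freqs, cycles = cycles,
      sampleRate = sampleRate, kernels = kernels)
}

setMethod("show", "WaveletFamily", function(object) {
  f <- object@frequencies
  cat(sprintf("WaveletFamily: %d frequencies %g..%g Hz, cycles %g..%g @ %g Hz\n",
              length(f), f[1L], f[length(f)], object@cycles[1L],
              object@cycles[length(object@cycles)], object@sampleRate))
})

#' Morlet time-frequency decomposition
#'
#' Convolves every trial x channel series with each wavelet (frequency-domain
#' multiplication with linear zero padding, mathematically equivalent to
#' direct time-domain convolution) and squares the magnitude of the complex
#' result. Samples within half a kernel length of the epoch edges are flagged
#' per frequency.
#'
#' @param epochs an \code{\link{EpochSet}} (unfiltered branch).
#' @param family a \code{\link{WaveletFamily}} at the epoch sampling rate.
#' @param channels channel labels or group name to decompose (default all).
#' @param frequencies subset of center frequencies to compute (default all).
#' @return a raw-power \code{\link{TFRPower}}.
#' @export
tfDecompose <- function(epochs, family, channels = NULL, frequencies = NULL) {
  if (abs(family@sampleRate - sampleRate(epochs)) > 1e-9)
    stop("wavelet family sampling rate does not match the epochs")
  chIdx <- if (is.null(channels)) seq_along(channelLabels(montage(epochs)))
           else .resolveGroup(montage(epochs), channels)
  fIdx <- if (is.null(frequencies)) seq_along(family@frequencies)
          else {
    m <- match(frequencies, family@frequencies)
    if (anyNA(m)) stop("requested frequencies not in the family")
    m
  }
  d <- epochs@data[, chIdx, , drop = FALSE]
  dm <- dim(d)
  n <- dm[3L]
  maxK <- max(lengths(family@kernels[fIdx]))
  if (maxK > n)
    warning("kernel longer than epoch at ",
            sum(lengths(family@kernels[fIdx]) > n),
            " frequencies; whole rows edge-flagged")
  nfft <- 2^ceiling(log2(n + maxK - 1L))
  # samples x (trials*channels), one forward FFT shared by all frequencies
  x <- t(matrix(d, dm[1L] * dm[2L], n))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  pow <- array(NA_real_, dim = c(dm[1L], dm[2L], length(fIdx), n))
  edge <- matrix(FALSE, length(fIdx), n)
  for (j in seq_along(fIdx)) {
    k <- family@kernels[[fIdx[j]]]
    K <- length(k)
    half <- (K - 1L) %/% 2L
    FK <- stats::fft(c(k, rep(0 + 0i, nfft - K)))
    y <- stats::mvfft(X * FK, inverse = TRUE) / nfft
    # centered ("same") alignment of the full linear convolution
    seg <- y[half + seq_len(n), , drop = FALSE]
    pow[, , j, ] <- array(t(Mod(seg)^2), dim = c(dm[1L], dm[2L], n))
    ed <- rep(FALSE, n)
    if (half > 0) {
      ed[seq_len(min(half, n))] <- TRUE
      ed[seq.int(max(1L, n - half + 1L), n)] <- TRUE
    }
    edge[j, ] <- ed | K > n
  }
  new("TFRPower", power = pow,
      channels = channelLabels(montage(epochs))[chIdx],
      frequencies = family@frequencies[fIdx], time = epochTime(epochs),
      units = "raw", baseline = NA_real_, edgeFlags = edge)
}

#' @describeIn TFRPower the power array
#' @param x a TFRPower.
#' @export
setMethod("tfrPower", "TFRPower", function(x) x@power)

#' @describeIn TFRPower center frequencies (Hz)
#' @export
setMethod("tfrFrequencies", "TFRPower", function(x) x@frequencies)

#' @describeIn TFRPower time axis (ms relative to cue)
#' @export
setMethod("tfrTime", "TFRPower", function(x) x@time)

setMethod("show", "TFRPower", function(object) {
  d <- dim(object@power)
  cat(sprintf("TFRPower [%s]: %d trials x %d channels x %d freqs x %d times\n",
              object@units, d[1L], d[2L], d[3L], d[4L]))
  if (object@units == "pct")
    cat(sprintf("  baseline %g..%g ms (cue-relative, common across trials)\n",
                object@baseline[1L], object@baseline[2L]))
})

#' Percent signal change from a pre-cue baseline
#'
#' Per channel and frequency, the baseline B is the mean raw power over the
#' baseline window across ALL trials of all conditions (common baseline, so
#' the between-condition ordering of raw power is preserved at every time
#' point); the output is 100 * (P - B) / B. Per-condition baselining is
#' available for sensitivity analysis.
#'
#' @param tfr a raw-power \code{\link{TFRPower}}.
#' @param baseline (ms, ms) relative to cue onset, before the cue.
#' @param scope "common" (default) or "per-condition"; the latter requires
#'   \code{conditions}.
#' @param conditions per-trial condition labels (only for "per-condition").
#' @return a percent-change \code{\link{TFRPower}}.
#' @export
percentChange <- function(tfr, baseline = c(-400, -100),
                          scope = c("common", "per-condition"),
                          conditions = NULL) {
  scope <- match.arg(scope)
  if (tfr@units != "raw") stop("percentChange expects raw power")
  if (baseline[2L] > 0)
    stop("baseline window must precede cue onset")
  idx <- .timeIndex(tfr@time, baseline)
  if (!length(idx)) stop("baseline window contains no samples")
  d <- dim(tfr@power)
  norm <- function(sub) {              # sub: trials x ch x freq x time
    B <- colMeans(aperm(sub[, , , idx, drop = FALSE],
                        c(1L, 4L, 2L, 3L)), dims = 2L)
    if (any(B <= 0)) {
      bad <- which(B <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-positive baseline power at channel %s, %.1f Hz",
                   tfr@channels[bad[1L]], tfr@frequencies[bad[2L]]))
    }
    100 * sweep(sweep(sub, c(2L, 3L), B, "-"), c(2L, 3L), B, "/")
  }
  out <- tfr@power
  if (scope == "common") {
    out <- norm(tfr@power)
  } else {
    if (is.null(conditions) || length(conditions) != d[1L])
      stop("per-condition baselining needs per-trial condition labels")
    for (cc in unique(conditions)) {
      sel <- conditions == cc
      out[sel, , , ] <- norm(tfr@power[sel, , , , drop = FALSE])
    }
  }
  new("TFRPower", power = out, channels = tfr@channels,
      frequencies = tfr@frequencies, time = tfr@time, units = "pct",
      baseline = as.numeric(baseline), edgeFlags = tfr@edgeFlags)
}

#' Alpha-band time course
#'
#' Mean over the frequencies whose centers lie in the closed band (with the
#' default 3 + 1.6 k grid and band 8-14 Hz these are 9.4, 11.0 and 12.6 Hz)
#' and over the channels of a group. Optionally reduces to a scalar mean over
#' a time window.
#'
#' @param tfr a \code{\link{TFRPower}}.
#' @param band (Hz, Hz), inclusive.
#' @param group channel labels (must be among the decomposed channels).
#' @param window optional (ms, ms) cue-relative window; when given, the
#'   per-trial time courses are averaged over it, and the window is required
#'   to be free of edge-flagged samples at every band frequency.
#' @return trials x times matrix (attribute \code{time_ms}), or per-trial
#'   scalars when \code{window} is given.
#' @export
bandTimecourse <- function(tfr, band = c(8, 14), group, window = NULL) {
  fSel <- which(tfr@frequencies >= band[1L] & tfr@frequencies <= band[2L])
  if (!length(fSel)) stop("no wavelet centers inside the band")
  chSel <- match(group, tfr@channels)
  if (anyNA(chSel))
    stop("channels not decomposed: ",
         paste(group[is.na(chSel)], collapse = ", "))
  sub <- tfr@power[, chSel, fSel, , drop = FALSE]
  tc <- colMeans(aperm(sub, c(2L, 3L, 1L, 4L)), dims = 2L)
  attr(tc, "time_ms") <- tfr@time
  if (is.null(window)) return(tc)
  idx <- .timeIndex(tfr@time, window)
  if (!length(idx)) stop("window contains no samples")
  if (any(tfr@edgeFlags[fSel, idx]))
    stop("analysis window overlaps edge-flagged samples; enlarge the epoch")
  rowMeans(tc[, idx, drop = FALSE])
}
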