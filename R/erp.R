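# per-trial waveform averaged over a channel group: trials x samples matrix
.groupWaveforms <- function(epochs, group) {
  idx <- .resolveGroup(montage(epochs), group)
  d <- epochs@data[, idx, , drop = FALSE]
  colMeans(aperm(d, c(2L, 1L, 3L)))        # mean over channels
}

#' Condition-averaged ROI waveform
#'
#' Averages over trials of a condition and over the channels of a group
#' (order immaterial for means).
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param group channel-group name (e.g. "leftPosterior") or channel labels.
#' @param condition condition label to select; NULL pools all trials.
#' @return data.frame with \code{time_ms} and \code{amplitude}.
#' @export
averageErp <- function(epochs, group, condition = NULL) {
  keep <- if (is.null(condition)) rep(TRUE, nTrials(epochs))
          else trialInfo(epochs)$condition == condition
  if (!any(keep))
    stop("no trials in condition '", condition, "'")
  wf <- .groupWaveforms(subsetTrials(epochs, keep), group)
  data.frame(time_ms = epochTime(epochs), amplitude = colMeans(wf))
}

#' Grand-average P1 peak latency
#'
#' Latency of the maximum sample of a (pooled-conditions) grand-average
#' waveform within the search window; ties break toward the earlier latency.
#' A flat waveform yields a degenerate-peak warning and the window midpoint.
#'
#' @param waveform data.frame(time_ms, amplitude) on the cue-relative axis.
#' @param search (ms, ms) search window relative to target onset.
#' @param targetTime target onset in ms relative to cue onset.
#' @return peak latency in ms relative to target onset.
#' @export
findGrandPeak <- function(waveform, search = c(70, 150), targetTime) {
  idx <- .timeIndex(waveform$time_ms, search + targetTime)
  if (!length(idx)) stop("waveform does not cover the search window")
  amp <- waveform$amplitude[idx]
  if (diff(range(amp)) == 0) {
    warning("flat waveform in search window; returning window midpoint")
    return(mean(search))
  }
  waveform$time_ms[idx[which.max(amp)]] - targetTime
}

#' Mean amplitude in a fixed window
#'
#' Mean of the condition-averaged group waveform over a window of given width
#' centered on a peak latency; one scalar per call (callers loop over
#' subject x condition x hemisphere).
#'
#' @param epochs an \code{\link{EpochSet}} (one subject).
#' @param group channel group name or labels.
#' @param condition condition label (NULL pools).
#' @param center window center in ms relative to target onset.
#' @param width window width in ms (default 30).
#' @return mean amplitude over the window.
#' @export
windowAmplitude <- function(epochs, group, condition = NULL, center,
                            width = 30) {
  wf <- averageErp(epochs, group, condition)
  win <- center + c(-1, 1) * width / 2 + targetTime(epochs)
  if (win[1L] < min(wf$time_ms) || win[2L] > max(wf$time_ms))
    stop("amplitude window extends past the epoch")
  idx <- .timeIndex(wf$time_ms, win)
  mean(wf$amplitude[idx])
}

# strict interior local maxima of a numeric vector (greater than both
# neighbours); returns indices into v
.localMaxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
}

#' Single-trial P1 peaks
#'
#' For each trial's group-averaged waveform, finds local maxima (samples
#' strictly greater than both neighbours) strictly inside the search window
#' and records the largest-amplitude one; trials without any local maximum are
#' flagged undetected (window endpoints are not eligible peaks).
#'
#' @param epochs an \code{\link{EpochSet}} (one subject).
#' @param group channel group name or labels.
#' @param search (ms, ms) window relative to target onset.
#' @return data.frame: trial, subject, condition, detected, amplitude,
#'   latency_ms (relative to target; NA when undetected).
#' @export
singleTrialPeaks <- function(epochs, group, search = c(70, 150)) {
  wf <- .groupWaveforms(epochs, group)
  time <- epochTime(epochs)
  tt <- targetTime(epochs)
  idx <- .timeIndex(time, search + tt)
  info <- trialInfo(epochs)
  n <- nrow(wf)
  amp <- lat <- rep(NA_real_, n)
  det <- logical(n)
  for (i in seq_len(n)) {
    seg <- wf[i, idx]
    pk <- .localMaxima(seg)
    # peaks must lie strictly inside the search window
    tpk <- time[idx[pk]] - tt
    pk <- pk[tpk > search[1L] & tpk < search[2L]]
    if (length(pk)) {
      best <- pk[which.max(seg[pk])]
      det[i] <- TRUE
      amp[i] <- seg[best]
      lat[i] <- time[idx[best]] - tt
    }
  }
  data.frame(trial = seq_len(n), subject = info$subject,
             condition = info$condition, detected = det, amplitude = amp,
             latency_ms = lat)
}
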